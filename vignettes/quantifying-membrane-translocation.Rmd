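---
title: "Quantifying tonicity-driven membrane protein translocation"
author: "rmequant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tonicity-driven membrane protein translocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmequant)
```

# The measurement problem

Aquaporin water channels such as AQP4 can relocalize from intracellular
vesicles to the plasma membrane within tens of seconds of a hypotonic
challenge. The observable in a confocal micrograph of a GFP-tagged protein
is a redistribution of fluorescence: a cell with most protein internal shows
diffuse cytoplasmic signal; a translocated cell shows a bright membrane ring.
This package quantifies that redistribution with the **relative membrane
expression** (RME) statistic, measures the accompanying cell swelling, fits
the kinetics of the change, quantifies the orthogonal biotinylation-ELISA
readout of surface expression, and applies the statistical decision rule
that labels a condition as translocating or not.

# The RME statistic

A line profile is drawn across a cell. Let $M$ be the membrane fluorescence
where the line crosses the plasma membrane (two crossings), $C$ the average
intracellular fluorescence, and $I_{\max}$ the maximum fluorescence of the
profile within the cell, all after subtracting the image background (the
intensity mode outside all cells). Then

$$\mathrm{RME} = 100\,\frac{M - C}{I_{\max}}.$$

A cell with protein evenly distributed between membrane and intracellular
compartments has $M = C$, hence RME 0; a cell with all protein at the
membrane has $C = 0$ and $M = I_{\max}$, hence RME 100. These two anchors
are definitional and the implementation is required to reproduce them on
noise-free synthetic cells (the test suite asserts RME $= 0$ exactly and
RME $\in [98, 100]$).

## Membrane detection

Profiles are sampled by bilinear interpolation at 0.5-pixel steps. The cell
crossing (span) comes from the cell mask. The entry and exit membrane peaks
are the highest local maxima within the outer 25 % of each end of the span;
the intracellular baseline is the median of the central 50 %; each membrane
*segment* is the contiguous run of samples around its peak with intensity at
least halfway from baseline to peak. On a flat profile (peak not above
baseline) the segment degenerates to the boundary sample and $M$ is set to
the baseline, so RME evaluates to 0 — this is what an even-distribution cell
produces.

## Why M is the peak height, not the segment mean

A natural alternative defines $M$ as the mean intensity over the half-height
segments. On any discretely rendered (or imaged) ring this cannot reach the
all-at-membrane anchor: the half-height segment necessarily includes
partial-coverage samples at 50–75 % of the peak, which dilute the segment
mean to roughly 85–93 % of $I_{\max}$, and the anchor RME 100 becomes
unattainable. Taking $M$ as the mean of the two crossing *peak heights*
restores the identity exactly — the profile maximum and the membrane peak
are the same sample when the protein is fully membrane-localized — at the
cost of slightly higher noise sensitivity, which the three-profiles-per-cell
and three-cells-per-image averaging absorbs. The segment-mean variant
remains available (`computeRme(..., mMethod = "segment")`); the half-height
segments are still computed and used to exclude membrane samples from $C$.

## The intracellular average C

$C$ averages the span samples excluding (i) the membrane segments, (ii) a
membrane-adjacent buffer (default 0.8 µm = ring thickness + one pixel) at
each end of the span, (iii) samples in the nucleus mask dilated by 2 px,
and (iv) ER-colocalized samples when ER exclusion is active. The buffer
matters for the even-distribution anchor: without it, partial-coverage
samples at the cell edge depress $C$ slightly and a perfectly even cell
reads RME ≈ 0.5 instead of 0. $I_{\max}$ is the per-profile maximum within
the span (not the image maximum): this is the only reading under which the
all-at-membrane anchor holds for cells of any brightness. RME is not
clamped; negative values (interior brighter than membrane) are reported
as-is and flagged.

## Profile placement

Line scans avoid the nucleus and perinuclear region. Placement is a
deterministic angle sweep (no randomness): `nLines` base angles at
$180/n$° spacing, each line through the cell centroid and extended 20 %
beyond the boundary on both sides. A candidate intersecting the nucleus
dilated by 2 px is first shifted to parallel chords just outside the
dilated nucleus; if no chord at that angle is admissible the angle advances
in 5° steps. Manual endpoints (e.g. transcribed from an annotated image)
can be passed directly to `sampleProfile()`.

## ER correction

Some tagged protein resides in the endoplasmic reticulum and inflates the
intracellular signal. When an ER-marker channel is present, an ER mask is
derived by Otsu thresholding of that channel within the cell and the
colocalized samples are excluded from $C$ (exclusion is robust to channel
gain differences; literal pixel-value subtraction would not be). On
synthetic scenes with 30 % of the intracellular signal in ER puncta the
correction changes the calculated RME by less than 10 % relative on
average, consistent with the magnitude this correction is expected to
have; individual cells fluctuate around that bound.

# Cell swelling

Cells are segmented by global Otsu thresholding, hole filling and
8-connected component labelling, discarding particles below 50 px.
Segmentation prefers the membrane-dye channel (it marks transfected and
non-transfected cells alike; thresholding the ring and filling its hole
recovers the footprint), falling back to the protein channel. Pre/post
frames are matched by greedy nearest-centroid pairing with a maximum
displacement of 25 % of the mean cell diameter; unmatched cells are dropped
with a warning. A cell is *transfected* when its mean protein intensity
strictly exceeds the background mode + 3 SD (ties break to non-transfected).
Percent area change is per-cell post/pre × 100 (100 = no change), averaged
within the transfected and non-transfected groups; the "increase" is the
mean − 100. Per-cell averaging (rather than pooled-pixel ratios) was chosen
as the reading most consistent with per-cell cross-sectional presentation.

# Translocation kinetics

`renderTimecourse()` renders frames at $t_k = k/\text{frameRate}$ with the
membrane fraction following first-order trafficking,
$f(t) = f_1 + (f_0 - f_1)e^{-t/\tau}$. `rmeTimeseries()` measures one RME
value per frame with placements fixed at frame 0 (rescaled radially when
the cell swells), and `fitTimescale()` estimates $\tau$.

Under the renderer's intensity model the noise-free RME is a Möbius
function of the membrane fraction,

$$\mathrm{RME}(f) = 100\,\frac{f}{f + (1-f)\rho}, \qquad
\rho = \frac{A_\text{ring}}{A_\text{uniform}},$$

with $\rho \approx 0.16$ for the default geometry. This map saturates: at a
realistic effect size (RME rising from ~28 to ~67) a plain single
exponential fitted to the RME trace recovers $\tau \approx 20$ s when the
underlying trafficking constant is 30 s — a 33 % bias, outside any
reasonable recovery tolerance. The headline $\tau$ therefore comes from
fitting the *saturating* model (the exponential in $f$-space composed with
the calibration above). $\rho$ is estimated from the frame-0 image geometry
(membrane-segment widths and mask areas) and held fixed, which removes most
of the residual bias; with no calibration available it is fitted as a
fourth parameter. The plain-exponential $\tau$ (`tauExp`) and the
model-free time to 90 % of the total change (`t90`) are reported alongside,
since "the response timescale" of a published trace may refer to either.
A series whose range does not exceed 3× the residual noise estimate returns
a flagged null fit (`response = FALSE`) — the behaviour of a
non-translocating control — rather than a number.

# Biotinylation ELISA

Surface proteins are biotinylated, captured, and read as absorbance at
450 nm; each lysate is loaded in triplicate at equal total protein. The
quantification is: per-lysate value = mean of its replicate wells − blank
mean (dedicated blank wells preferred, scalar fallback), optionally divided
by a per-lysate protein scale; per-condition level = mean over biological
repeats, SEM across repeats; negative blank-subtracted values are floored
at 0 with a warning. Fold changes are computed per-repeat-then-averaged
(repeats paired by index) with SEM across repeats — the default because it
respects the pairing of lysates processed together — and additionally as
the ratio of means with a first-order delta-method SEM.
Percent-of-reference is 100 · level / reference level. Buffer tonicity
matching is metadata only.

# Statistics and the translocation call

Paired t-tests compare the same cells before and after a tonicity change;
Welch unpaired t-tests compare different cells under different treatments;
multiple treatments are first gated by one-way repeated-measures ANOVA
(subject = experimental repeat; "multiple treatments of the same cells"
implies within-subject structure), falling back to ordinary one-way ANOVA
with a warning when unbalanced. Pairwise p-values are Bonferroni-corrected
with $m$ = the number of planned comparisons in the design ($m$ is printed
in the report footer for auditability), displayed rounded **up** to one
significant figure (0.00102 → 0.002), and significant at p < 0.05. All
tests are two-sided. Pairing is by experimental repeat (not by cell) by
default, matching $n$ = number of repeats.

A condition is called **Yes** (translocating) iff its hypotonic-vs-isotonic
paired test is significant after correction *and* the hypotonic mean
exceeds the isotonic mean; a significant decrease is called No and flagged
anomalous; when the ANOVA gate fails, every comparison is reported
non-significant and no row can be Yes. Degenerate zero-variance cases are
flagged: identical vectors give p = 1; a perfectly consistent nonzero shift
gives the limiting p = 0 with the `degenerate` flag set.

# The synthetic world

The generator renders what the quantification needs and no more: circular
cells (radius 8 µm) with a 0.6 µm membrane ring, a nucleus (3 µm) at 20 %
of cytoplasmic intensity (dim enough for placement to avoid, not pitch
black), optional Gaussian ER puncta (σ = 2 px), on a 128×128 px field at
0.2 µm/px, 16-bit-scale arbitrary units, background 10 a.u., total signal
2×10⁵ a.u. per cell. The tagged-protein model is *even-plus-ring*: a
uniform density carrying $(1-f)S$ over the whole footprint plus $f S$
uniformly on the ring, so $f = 0$ is exactly the even-distribution
reference state and $f = 1$ the all-membrane state. Partial-pixel coverage
uses 4× supersampling with block averaging. Noise is optional Poisson
followed by additive Gaussian, both off by default so the analytic anchors
are exact; "mild noise" in the recovery suites is Gaussian SD 2 a.u.
(SNR ≈ 20 at the cytoplasm). All randomness is seeded; no global RNG state
leaks.

Stated-world values mirror the published experiment: membrane fractions for
the isotonic and hypotonic states are obtained by inverting the published
RME levels (27.9 and 67.1) through the calibration
(`rmeToFraction(rme, cellRho(spec))`); swelling ratios are 1.45
(transfected) and 1.05 (non-transfected); ELISA truth uses a 2.7-fold
surface-expression increase with multiplicative CV 0.1, three biological
repeats and triplicate wells; time-lapse stacks run 120 s at 0.1 s⁻¹ with
τ = 30 s. The ER punctum count (30) is chosen so that puncta stay dimmer
than the membrane ring — the ER is a spread reticular network, and a
handful of bright blobs would corrupt the per-profile maximum in a way real
ER signal does not.

What the generator deliberately does **not** emulate: biological
repeat-to-repeat variability (SEMs in simulated reports reflect imaging
noise only and are unrealistically small), irregular cell shapes, membrane
ruffling, point-spread-function optics, photobleaching, z-structure, and
cell movement beyond radial swelling. A green recovery test therefore
establishes correctness of the estimators on their stated model, not
robustness to every property of real micrographs.

# Numerical choices and edge cases

- Coordinates are 0-based and pixel-centred; distances convert to µm via
  the pixel size. Profile steps are 0.5 px.
- Background is the intensity mode (unit-binned) outside all cells.
- Spans shorter than 8 samples are an error; empty cells
  ($I_{\max} \le 0$ after background subtraction) are an error; an ER mask
  covering the whole interior is an error (C undefined).
- Overlapping half-height segments are split at the intensity minimum
  between the peaks.
- Kinetic fits use L-BFGS-B with multistart; τ is initialized at the time
  of half-maximal change divided by ln 2.
- Cell labels are stable (sorted by centroid, row-major); matching is
  greedy closest-first.
- Derived seeds are kept below 2³¹ so R's integer RNG seeding never
  overflows.

# Limitations

The RME/fraction calibration assumes the even-plus-ring intensity model;
for real cells ρ must be estimated from the image (as `rmeTimeseries()`
does) and the τ estimate inherits its error, though the sensitivity is
mild. The ANOVA gate treats the repeat index as the subject; designs in
which repeats are not matched across conditions should use the unpaired
path. The TIFF adapter reads only the uncompressed little-endian grayscale
layout it writes — it is a data-exchange convenience, not a general TIFF
reader.
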