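# rmequant

Quantification of rapid, tonicity-driven relocalization of membrane proteins
(the motivating case is the astrocyte water channel aquaporin-4, AQP4)
between intracellular compartments and the plasma membrane, from confocal
fluorescence micrographs and cell-surface biotinylation ELISA plates.

When extracellular osmolality drops (hypotonic challenge, e.g. 340 →
85 mosm/kg H₂O), AQP4 translocates to the cell surface within tens of
seconds and the cell swells. This package implements the full quantification
chain used to measure that phenomenon:

- **Relative membrane expression (RME)** from line-scan intensity profiles
  across single cells:

  RME = 100 · (M − C) / I_max

  where *M* is the membrane fluorescence at the two crossings of the plasma
  membrane, *C* the average intracellular fluorescence and *I_max* the
  maximum intensity of the profile inside the cell (all background
  subtracted). A cell with protein evenly distributed between membrane and
  intracellular compartments has RME 0; a cell with 100 % of the protein at
  the membrane has RME 100. Optional exclusion of ER-colocalized signal
  (via an ER-marker channel) corrects *C*.
- **Cell swelling**: Otsu segmentation, hole filling, particle filtering,
  pre/post cell matching, and cross-sectional area change (post area as a
  percent of pre area; 100 = no change), split into transfected and
  non-transfected cells by the protein channel.
- **Translocation kinetics**: RME time series from time-lapse stacks with
  line placements fixed at frame 0, and least-squares estimation of the
  time constant τ of first-order trafficking, f(t) = f₁ + (f₀ − f₁)e^(−t/τ).
  Because RME is a ratio statistic it saturates in the membrane fraction,
  so the fit uses the saturating calibration RME = 100f/(f + (1 − f)ρ)
  (ρ estimated from the image geometry); the plain-exponential τ and a
  model-free time-to-90 % are also reported.
- **Biotinylation ELISA**: triplicate aggregation, blank subtraction, fold
  change versus a control tonicity and percent-of-wild-type normalization,
  with SEMs across biological repeats.
- **Decision rule**: one-way repeated-measures ANOVA gate, paired (or
  Welch unpaired) t-tests, Bonferroni correction with p-values displayed
  rounded *up* to one significant figure, significance at p < 0.05, and a
  per-condition translocation call: **Yes** iff the hypotonic-vs-isotonic
  paired test is significant *and* the hypotonic mean exceeds the isotonic
  mean.
- **Synthetic scenes**: a two-channel renderer (tagged protein +
  membrane dye, optional ER marker) with circular cells, membrane ring,
  dim nucleus, ER puncta, controllable membrane fraction, swelling and
  Poisson/Gaussian noise — every stage of the pipeline is testable against
  known ground truth without any external data.

## Worked example

Simulate a two-arm experiment (untreated control versus a fully inhibiting
treatment), quantify it end-to-end and print the report:

```r
library(rmequant)

rho <- cellRho(cellSpec(center = c(64, 64)))   # RME/fraction calibration
arms <- data.frame(
  label = c("Untreated control", "PKA inhibitor"),
  fIso  = rmeToFraction(28, rho),              # isotonic RME level ~28
  fHypo = c(rmeToFraction(78, rho),            # responds: RME ~78
            rmeToFraction(28, rho)),           # blocked: no change
  swelling = c(1.45, 1.03))
design <- experimentDesign(arms, nRepeats = 3L, nCells = 3L)
res <- runPipeline(design, seed = 1L)
res$report
```

```
Condition          Isotonic RME (+/- S.E.)  Hypotonic RME (+/- S.E.)  Mean % of area change (+/- S.E.)  Translocation
Untreated control  28.54 (0.10)             80.71 (0.15)*             144.68 (0.01)*                    Yes
PKA inhibitor      28.21 (0.41)             28.53 (0.25)              102.81 (0.00)                     No
Bonferroni m = 2; * p < 0.05 after correction
```

The control arm translocates (RME rises from ~28 to ~81, significant after
Bonferroni correction, cells swell by ~45 %); the inhibited arm does not
(RME flat, ~3 % swelling). The SEMs reflect only imaging noise — the
synthetic world has no biological repeat-to-repeat variability, so they are
much smaller than in real experiments.

Single stages are available directly: `renderScene()`, `rmeForScene()`,
`segmentCells()` / `matchCells()` / `measureSwelling()`,
`renderTimecourse()` / `rmeTimeseries()` / `fitTimescale()`,
`simulateElisaPlate()` / `quantifyPlate()` / `foldChange()`, and the
statistics (`pairedT()`, `unpairedT()`, `anovaGate()`, `bonferroni()`,
`buildReport()`). Images round-trip through plain multipage TIFF
(`writeScene()` / `readScene()`), plates through CSV.

## Acceptance script

`scripts/acceptance.R` regenerates, from scratch and with fresh synthetic
data, the quantities the pipeline is anchored to: the two definitional RME
anchors (even distribution → 0; all-membrane → 100), the recovered ELISA
fold change at a true 2.7-fold surface-expression increase, the recovered
percent area increases for transfected and non-transfected cells (true
45 % and 5 %), and the median fitted translocation time constant (true
30 s at a 0.1 s⁻¹ frame rate). Run it from the repository root against the
installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
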