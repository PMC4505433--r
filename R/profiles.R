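# Line-profile extraction and the relative membrane expression (RME)
# statistic: RME = 100 * (M - C) / Imax, where M is the membrane fluorescence
# at the two crossings, C the average intracellular fluorescence and Imax the
# maximum intensity of the profile within the cell; 0 = even distribution,
# 100 = fully membrane-localized.

PROFILE_STEP_PX <- 0.5   # sample spacing, pixels
MIN_SPAN_SAMPLES <- 8L

## ---------------------------------------------------------------------------
## profile placement
## ---------------------------------------------------------------------------

#' Place line profiles across a cell
#'
#' Chooses \code{nLines} straight lines crossing the cell at distinct angles
#' (deterministic angle sweep starting at 0 degrees in steps of
#' \code{180 / nLines}), each passing through the centroid region and extended
#' 20\% beyond the cell boundary on both sides. Any candidate that intersects
#' the nucleus dilated by 2 px (the perinuclear region) is rejected; the line
#' is first shifted to parallel chords on either side of the nucleus and, if
#' no chord is admissible, the angle is advanced in 5-degree steps.
#'
#' @param cellMask Logical matrix: the cell footprint (connected).
#' @param nucleusMask Logical matrix or NULL.
#' @param nLines Number of profiles (default 3, the sampling design used for
#'   the micrograph analysis: three profiles per cell).
#' @param minSamples Minimum in-cell samples per line (at 0.5 px spacing).
#' @param cellId Integer label used in error messages.
#' @return A list with one element per line: numeric \code{endpoints}
#'   (x0, y0, x1, y1) and the \code{angle} (degrees).
#' @export
placeProfiles <- function(cellMask, nucleusMask = NULL, nLines = 3L,
                          minSamples = 20L, cellId = 1L) {
    stopifnot(nLines >= 1L)
    ij <- which(cellMask, arr.ind = TRUE)
    if (nrow(ij) == 0L) stop("empty cell mask (cell ", cellId, ")")
    cx <- mean(ij[, 2] - 1); cy <- mean(ij[, 1] - 1)
    nucDil <- if (!is.null(nucleusMask) && any(nucleusMask))
        dilateDisk(nucleusMask, 2L) else NULL
    nucR <- if (!is.null(nucDil)) {
        nij <- which(nucDil, arr.ind = TRUE)
        ncx <- mean(nij[, 2] - 1); ncy <- mean(nij[, 1] - 1)
        max(sqrt((nij[, 2] - 1 - ncx)^2 + (nij[, 1] - 1 - ncy)^2))
    } else 0

    maskAt <- function(m, x, y) {
        r <- round(y) + 1; c <- round(x) + 1
        ok <- r >= 1 & r <= nrow(m) & c >= 1 & c <= ncol(m)
        out <- logical(length(x)); out[ok] <- m[cbind(r[ok], c[ok])]
        out
    }

    tryLine <- function(angleDeg, offset) {
        th <- angleDeg * pi / 180
        u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
        p <- c(cx, cy) + offset * v
        tmax <- max(dim(cellMask)) * 1.5
        ts <- seq(-tmax, tmax, by = 0.25)
        xs <- p[1] + ts * u[1]; ys <- p[2] + ts * u[2]
        inside <- maskAt(cellMask, xs, ys)
        if (!any(inside)) return(NULL)
        i0 <- which(inside)[1]; i1 <- rev(which(inside))[1]
        chord <- ts[i1] - ts[i0]
        if (chord / PROFILE_STEP_PX + 1 < minSamples) return(NULL)
        if (!is.null(nucDil)) {
            seg <- seq(i0, i1)
            if (any(maskAt(nucDil, xs[seg], ys[seg]))) return(NULL)
        }
        e0 <- ts[i0] - 0.2 * chord; e1 <- ts[i1] + 0.2 * chord
        a <- p + e0 * u; b <- p + e1 * u
        clamp <- function(q) c(min(max(q[1], 0), ncol(cellMask) - 1),
                               min(max(q[2], 0), nrow(cellMask) - 1))
        a <- clamp(a); b <- clamp(b)
        list(endpoints = c(a[1], a[2], b[1], b[2]), angle = angleDeg %% 180)
    }

    offsets <- if (is.null(nucDil)) 0 else {
        o <- nucR + 1
        c(0, o, -o, 1.5 * o, -1.5 * o)
    }
    lines <- list(); used <- numeric()
    for (k in seq_len(nLines)) {
        angle <- (k - 1) * 180 / nLines
        found <- NULL
        for (try in 0:35) {
            a <- (angle + 5 * try) %% 180
            if (any(abs(((a - used) %% 180 + 90) %% 180 - 90) < 1e-6)) next
            for (o in offsets) {
                found <- tryLine(a, o)
                if (!is.null(found)) break
            }
            if (!is.null(found)) break
        }
        if (is.null(found))
            stop("no admissible line placement for cell ", cellId,
                 " (nucleus covers the centroid region)")
        used <- c(used, found$angle)
        lines[[k]] <- found
    }
    lines
}

## ---------------------------------------------------------------------------
## profile sampling
## ---------------------------------------------------------------------------

#' Sample an intensity profile along a segment
#'
#' Bilinear interpolation at 0.5-pixel steps between two endpoints given in
#' 0-based, pixel-centred coordinates; positions are reported in micrometres.
#'
#' @param image Numeric matrix (one channel).
#' @param endpoints Numeric (x0, y0, x1, y1).
#' @param pixelSize Micrometres per pixel.
#' @param cellId Integer label stored in the profile.
#' @return A \linkS4class{LineProfile}.
#' @export
sampleProfile <- function(image, endpoints, pixelSize = 0.2, cellId = 1L) {
    stopifnot(length(endpoints) == 4L)
    a <- endpoints[1:2]; b <- endpoints[3:4]
    L <- sqrt(sum((b - a)^2))
    if (L == 0) stop("profile endpoints are identical")
    d <- seq(0, L, by = PROFILE_STEP_PX)
    xs <- a[1] + d / L * (b[1] - a[1])
    ys <- a[2] + d / L * (b[2] - a[2])
    new("LineProfile", endpoints = as.numeric(endpoints),
        positions = d * pixelSize,
        intensities = bilinearAt(image, xs, ys),
        cellId = as.integer(cellId))
}

## Sample positions of a profile in pixel coordinates (used for mask lookups).
profileXY <- function(profile) {
    a <- profile@endpoints[1:2]; b <- profile@endpoints[3:4]
    L <- sqrt(sum((b - a)^2))
    d <- seq(0, L, by = PROFILE_STEP_PX)
    list(x = a[1] + d / L * (b[1] - a[1]), y = a[2] + d / L * (b[2] - a[2]))
}

## Logical vector: which samples of a profile fall inside a mask
## (nearest-pixel lookup).
profileInMask <- function(profile, mask) {
    xy <- profileXY(profile)
    r <- round(xy$y) + 1; c <- round(xy$x) + 1
    ok <- r >= 1 & r <= nrow(mask) & c >= 1 & c <= ncol(mask)
    out <- logical(length(r)); out[ok] <- mask[cbind(r[ok], c[ok])]
    out
}

## ---------------------------------------------------------------------------
## membrane detection
## ---------------------------------------------------------------------------

#' Detect membrane crossings on a line profile
#'
#' Locates the entry and exit membrane peaks as the highest local maxima
#' within the outer 25\% of each end of the cell-crossing span, and defines
#' each membrane segment as the contiguous run of samples around its peak
#' with intensity at least \code{baseline + 0.5 * (peak - baseline)}, where
#' the baseline is the median of the central 50\% of the span. On a flat
#' profile (peak not above baseline) the segment degenerates to the single
#' boundary sample and the peak height is set to the baseline, so that the
#' RME evaluates to 0.
#'
#' @param profile A \linkS4class{LineProfile}.
#' @param cellSpan Integer length-2: first and last sample index inside the
#'   cell.
#' @return A list of class \code{"MembraneSegments"}: \code{entry} and
#'   \code{exit} index intervals, \code{peaks} (indices), \code{peakHeights}
#'   (intensities), \code{baseline}, \code{flat} (logical per side) and
#'   \code{span}.
#' @export
detectMembrane <- function(profile, cellSpan) {
    v <- profile@intensities
    i0 <- cellSpan[1]; i1 <- cellSpan[2]
    len <- i1 - i0 + 1L
    if (len < MIN_SPAN_SAMPLES)
        stop("cell span shorter than ", MIN_SPAN_SAMPLES, " samples")
    nw <- max(2L, as.integer(ceiling(0.25 * len)))
    entryW <- i0:(i0 + nw - 1L)
    exitW <- (i1 - nw + 1L):i1
    qs <- i0 + as.integer(floor(0.25 * len))
    qe <- i0 + as.integer(ceiling(0.75 * len)) - 1L
    baseline <- stats::median(v[qs:qe])

    pickPeak <- function(window, fromEnd) {
        isMax <- vapply(window, function(k) {
            lo <- if (k > 1L) v[k - 1L] else -Inf
            hi <- if (k < length(v)) v[k + 1L] else -Inf
            v[k] >= lo && v[k] >= hi
        }, logical(1))
        cand <- window[isMax]
        if (length(cand) == 0L) cand <- window
        best <- cand[v[cand] == max(v[cand])]
        if (fromEnd) best[length(best)] else best[1L]
    }
    segAround <- function(peak) {
        th <- baseline + 0.5 * (v[peak] - baseline)
        s <- peak
        while (s > i0 && v[s - 1L] >= th) s <- s - 1L
        e <- peak
        while (e < i1 && v[e + 1L] >= th) e <- e + 1L
        c(s, e)
    }

    pe <- pickPeak(entryW, FALSE)
    px <- pickPeak(exitW, TRUE)
    flat <- c(v[pe] - baseline <= 0, v[px] - baseline <= 0)
    entry <- if (flat[1]) c(i0, i0) else segAround(pe)
    exit <- if (flat[2]) c(i1, i1) else segAround(px)
    ## if the two half-height runs meet, split at the minimum between peaks
    if (entry[2] >= exit[1]) {
        mid <- pe + which.min(v[pe:px]) - 1L
        entry[2] <- min(entry[2], mid - 1L)
        exit[1] <- max(exit[1], mid)
        if (entry[2] < entry[1]) entry <- c(entry[1], entry[1])
        if (exit[2] < exit[1]) exit <- c(exit[2], exit[2])
    }
    structure(list(entry = entry, exit = exit, peaks = c(pe, px),
                   peakHeights = ifelse(flat, baseline, v[c(pe, px)]),
                   baseline = baseline, flat = flat, span = c(i0, i1)),
              class = "MembraneSegments")
}

## ---------------------------------------------------------------------------
## RME
## ---------------------------------------------------------------------------

#' Compute the RME of one line profile
#'
#' Evaluates \code{RME = 100 * (M - C) / Imax} after subtracting the image
#' background from all intensities. By default M is the mean of the two
#' membrane crossing peak heights (see the package vignette for why this, and
#' not the mean over the half-height segments, reproduces the definitional
#' anchors 0 and 100); \code{mMethod = "segment"} averages over the
#' half-height segments instead. C averages the cell-span samples excluding
#' the membrane segments, a membrane-adjacent buffer at each end of the span,
#' nucleus samples and (when supplied) ER-colocalized samples. Imax is the
#' maximum intensity within the span. RME is not clamped; negative values
#' (intracellular brighter than membrane) are reported as-is.
#'
#' @param profile A \linkS4class{LineProfile}.
#' @param segments Output of \code{\link{detectMembrane}}.
#' @param background Scalar background level (image mode outside all cells).
#' @param nucleusIn,erIn Optional logical vectors (one per sample): sample
#'   lies in the (dilated) nucleus / ER mask.
#' @param membraneBuffer Width (micrometres) of the membrane-adjacent zone at
#'   each end of the span excluded from C (default 0.8: ring 0.6 plus one
#'   pixel).
#' @param pixelSize Micrometres per pixel (converts the buffer to samples).
#' @param mMethod \code{"peak"} (default) or \code{"segment"}.
#' @param erAffectsMax Also exclude ER samples from Imax (default FALSE).
#' @param profileId Identifier copied to the output.
#' @return One-row data.frame: \code{profile_id}, \code{cell_id}, \code{M},
#'   \code{C}, \code{Imax}, \code{rme}, \code{negative} (flag).
#' @examples
#' ## M = 80, C = 20, Imax = 100 (background 0) gives RME 60 by the identity
#' @export
computeRme <- function(profile, segments, background = 0,
                       nucleusIn = NULL, erIn = NULL, membraneBuffer = 0.8,
                       pixelSize = 0.2, mMethod = c("peak", "segment"),
                       erAffectsMax = FALSE, profileId = 1L) {
    mMethod <- match.arg(mMethod)
    v <- profile@intensities - background
    i0 <- segments$span[1]; i1 <- segments$span[2]
    span <- i0:i1
    segIdx <- c(seq(segments$entry[1], segments$entry[2]),
                seq(segments$exit[1], segments$exit[2]))

    maxIdx <- span
    if (erAffectsMax && !is.null(erIn)) maxIdx <- setdiff(maxIdx, which(erIn))
    Imax <- max(v[maxIdx])
    if (Imax <= 0) stop("empty cell: Imax <= 0 after background subtraction")

    M <- if (mMethod == "peak") mean(segments$peakHeights - background)
         else mean(v[unique(segIdx)])

    bufSamples <- as.integer(round(membraneBuffer / pixelSize /
                                       PROFILE_STEP_PX))
    buffer <- unique(c(i0:min(i1, i0 + bufSamples),
                       max(i0, i1 - bufSamples):i1))
    cIdx <- setdiff(span, c(segIdx, buffer))
    if (!is.null(nucleusIn)) cIdx <- setdiff(cIdx, which(nucleusIn))
    if (!is.null(erIn)) cIdx <- setdiff(cIdx, which(erIn))
    if (length(cIdx) == 0L)
        stop("no intracellular samples left for C ",
             "(exclusions cover the whole span)")
    C <- mean(v[cIdx])

    rme <- 100 * (M - C) / Imax
    data.frame(profile_id = profileId, cell_id = profile@cellId,
               M = M, C = C, Imax = Imax, rme = rme, negative = rme < 0)
}

#' ER mask from an ER-marker channel
#'
#' Otsu threshold on the ER channel restricted to the cell footprint; samples
#' in the resulting mask are excluded from the intracellular average C
#' (exclusion, rather than literal pixel-value subtraction, is robust to
#' channel gain differences).
#'
#' @param erChannel Numeric matrix.
#' @param cellMask Logical matrix.
#' @return Logical matrix (TRUE = ER-colocalized).
#' @export
erMaskFromChannel <- function(erChannel, cellMask) {
    vals <- erChannel[cellMask]
    if (length(vals) == 0L || diff(range(vals)) == 0)
        return(matrix(FALSE, nrow(erChannel), ncol(erChannel)))
    th <- otsuThreshold(vals)
    erChannel > th & cellMask
}

## ---------------------------------------------------------------------------
## scene-level convenience and aggregation
## ---------------------------------------------------------------------------

#' Per-profile RME for a rendered scene
#'
#' Places \code{nLines} profiles per transfected cell using the scene's truth
#' masks, samples the protein channel, detects the membrane crossings and
#' computes the RME of every profile. Background is the image mode outside
#' all cell footprints. When the scene carries an ER channel and
#' \code{erExclude} is TRUE, ER-colocalized samples are excluded from C.
#'
#' @param scene A \linkS4class{Scene}.
#' @param nLines Profiles per cell.
#' @param erExclude Exclude ER-colocalized samples (default TRUE when an ER
#'   channel is present).
#' @param mMethod,membraneBuffer,erAffectsMax Passed to
#'   \code{\link{computeRme}}.
#' @return data.frame with one row per profile (see \code{\link{computeRme}}).
#' @examples
#' sc <- renderScene(sceneSpec(cellSpec(center = c(64, 64),
#'                                      membraneFraction = 1),
#'                             backgroundLevel = 0))
#' mean(rmeForScene(sc)$rme)  # ~100
#' @export
rmeForScene <- function(scene, nLines = 3L,
                        erExclude = "er_marker" %in% channelNames(scene),
                        mMethod = "peak", membraneBuffer = 0.8,
                        erAffectsMax = FALSE) {
    img <- getChannel(scene, "protein")
    px <- scene@spec@pixelSize
    allCells <- Reduce(`|`, lapply(scene@masks, `[[`, "cell"))
    background <- intensityMode(img[!dilateDisk(allCells, 2L)])
    erM <- NULL
    if (erExclude && "er_marker" %in% channelNames(scene))
        erM <- erMaskFromChannel(getChannel(scene, "er_marker"), allCells)

    out <- list()
    for (ci in seq_along(scene@masks)) {
        mk <- scene@masks[[ci]]
        if (!mk$spec@transfected) next
        nucD <- if (any(mk$nucleus)) dilateDisk(mk$nucleus, 2L) else NULL
        lines <- placeProfiles(mk$cell, mk$nucleus, nLines = nLines,
                               cellId = ci)
        for (li in seq_along(lines)) {
            pr <- sampleProfile(img, lines[[li]]$endpoints, pixelSize = px,
                                cellId = ci)
            inCell <- profileInMask(pr, mk$cell)
            if (!any(inCell)) next
            span <- range(which(inCell))
            seg <- detectMembrane(pr, span)
            nucIn <- if (!is.null(nucD)) profileInMask(pr, nucD) else NULL
            erIn <- if (!is.null(erM)) profileInMask(pr, erM) else NULL
            out[[length(out) + 1L]] <- computeRme(
                pr, seg, background = background, nucleusIn = nucIn,
                erIn = erIn, membraneBuffer = membraneBuffer,
                pixelSize = px, mMethod = mMethod,
                erAffectsMax = erAffectsMax,
                profileId = sprintf("c%d_p%d", ci, li))
        }
    }
    do.call(rbind, out)
}

#' RME / membrane-fraction calibration
#'
#' Under the even-plus-ring intensity model the noise-free RME of a cell is
#' a saturating function of its membrane fraction f:
#' \code{RME = 100 f / (f + (1 - f) rho)}, where
#' \code{rho = A_ring / A_uniform} is the ratio of the membrane-ring area to
#' the effective area carrying the uniform intracellular signal (cell area
#' minus 80\% of the nucleus area, the nucleus being rendered at 20\%
#' intensity). \code{cellRho} computes rho from a cell's geometry;
#' \code{fractionToRme} and \code{rmeToFraction} convert between the two
#' scales, e.g. to choose ground-truth fractions that reproduce published
#' RME levels.
#'
#' @param cs A \linkS4class{CellSpec}.
#' @param f Membrane fraction in [0, 1].
#' @param rme RME value in (approximately) [0, 100).
#' @param rho Area ratio (see above).
#' @return Numeric.
#' @examples
#' rho <- cellRho(cellSpec(center = c(64, 64)))
#' rmeToFraction(67.1, rho)  # fraction rendering an RME of ~67
#' @export
cellRho <- function(cs) {
    aRing <- pi * (cs@radius^2 - (cs@radius - cs@membraneThickness)^2)
    aUnif <- pi * cs@radius^2 - (1 - NUCLEUS_DIM) * pi * cs@nucleusRadius^2
    aRing / aUnif
}

#' @rdname cellRho
#' @export
fractionToRme <- function(f, rho) 100 * f / (f + (1 - f) * rho)

#' @rdname cellRho
#' @export
rmeToFraction <- function(rme, rho) {
    r <- rme / 100
    r * rho / (1 - r + r * rho)
}

#' Hierarchical aggregation of per-profile RME values
#'
#' Averages profiles to cells, cells to experimental repeats and repeats to
#' the condition mean; the SEM is computed across repeats (n = number of
#' repeats), the unit of biological replication in the sampling design
#' (three profiles per cell, at least three cells per image, n = 3 repeats).
#'
#' @param df data.frame with columns \code{rme}, \code{cell_id},
#'   \code{repeat_id} and optionally \code{condition}.
#' @return A list with \code{perCell}, \code{perRepeat} and \code{summary}
#'   data.frames; the summary has columns \code{condition}, \code{mean_rme},
#'   \code{sem}, \code{n} and \code{sem_defined}.
#' @export
aggregateRme <- function(df) {
    stopifnot(all(c("rme", "cell_id", "repeat_id") %in% names(df)))
    if (is.null(df$condition)) df$condition <- "all"
    perCell <- stats::aggregate(rme ~ condition + repeat_id + cell_id,
                                data = df, FUN = mean)
    perRepeat <- stats::aggregate(rme ~ condition + repeat_id,
                                  data = perCell, FUN = mean)
    out <- do.call(rbind, lapply(split(perRepeat, perRepeat$condition),
        function(g) {
            n <- nrow(g)
            data.frame(condition = g$condition[1], mean_rme = mean(g$rme),
                       sem = semOf(g$rme), n = n, sem_defined = n >= 2L)
        }))
    rownames(out) <- NULL
    if (any(!out$sem_defined))
        warning("SEM undefined for conditions with fewer than 2 repeats")
    list(perCell = perCell, perRepeat = perRepeat, summary = out)
}
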