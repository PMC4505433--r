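# Synthetic-scene rendering. Cells are circles rendered with 4x supersampling
# followed by block averaging, so partial-pixel coverage at the ring and cell
# boundary is represented and ring/interior means are stable.

SUPERSAMPLE <- 4L
NUCLEUS_DIM <- 0.2      # nucleus intensity relative to cytoplasm
DYE_RING_LEVEL <- 200   # membrane-dye ring intensity, a.u.
ER_SIGMA_PX <- 2        # ER punctum Gaussian sigma, pixels
## Spot count: enough puncta that the ER signal stays dimmer than the
## membrane ring (the ER is a spread reticular network, not a few bright
## blobs); with few spots a punctum can exceed the ring peak and corrupt the
## per-profile maximum.
ER_N_SPOTS <- 30L

## Supersampled coordinate grids for an image of shape (nr, nc): coordinates
## of supersample centres in base-pixel units (0-based, pixel-centred).
ssCoords <- function(n) {
    ss <- SUPERSAMPLE
    (seq_len(n * ss) - 0.5) / ss - 0.5
}

blockAverage <- function(m) {
    ss <- SUPERSAMPLE
    nr <- nrow(m) / ss; nc <- ncol(m) / ss
    ## average ss x ss blocks
    m <- matrix(colMeans(matrix(m, nrow = ss)), nrow = nr, ncol = nc * ss)
    t(matrix(colMeans(matrix(t(m), nrow = ss)), nrow = nc, ncol = nr))
}

#' Render a synthetic two-channel micrograph with ground truth
#'
#' Renders every cell of a \linkS4class{SceneSpec} into a \code{"protein"}
#' channel (transfected cells only), a \code{"membrane_dye"} channel (ring for
#' every cell, emulating a membrane dye such as FM4-64) and, when any cell has
#' \code{erFraction > 0}, an \code{"er_marker"} channel. Noise (optional
#' Poisson followed by additive Gaussian) is applied last; identical specs
#' (including seed) give identical output.
#'
#' The noise-free protein intensity follows the even-plus-ring model described
#' in \linkS4class{CellSpec}: the integrated background-subtracted signal per
#' transfected cell equals its \code{totalSignal} (to well within 1\%).
#'
#' @param spec A \linkS4class{SceneSpec}.
#' @return A \linkS4class{Scene}.
#' @examples
#' sc <- renderScene(sceneSpec(cellSpec(center = c(64, 64),
#'                                      membraneFraction = 0.5)))
#' range(getChannel(sc, "protein"))
#' @export
renderScene <- function(spec) {
    validObject(spec)
    nr <- spec@imageShape[1]; nc <- spec@imageShape[2]
    px <- spec@pixelSize
    cells <- spec@cells

    ## overlapping footprints are ambiguous ground truth
    if (length(cells) > 1L) {
        for (i in seq_len(length(cells) - 1L)) for (j in (i + 1L):length(cells)) {
            d <- sqrt(sum((cells[[i]]@center - cells[[j]]@center)^2))
            if (d <= (cells[[i]]@radius + cells[[j]]@radius) / px)
                stop("cell footprints ", i, " and ", j, " overlap")
        }
    }

    xs <- ssCoords(nc); ys <- ssCoords(nr)
    ssnr <- nr * SUPERSAMPLE; ssnc <- nc * SUPERSAMPLE
    protein <- matrix(0, ssnr, ssnc)
    dye <- matrix(0, ssnr, ssnc)
    er <- matrix(0, ssnr, ssnc)
    anyEr <- any(vapply(cells, function(cs)
        cs@erFraction > 0 && cs@transfected, logical(1)))
    masks <- vector("list", length(cells))

    withSeed(spec@seed, {
        for (ci in seq_along(cells)) {
            cs <- cells[[ci]]
            R <- cs@radius / px
            w <- cs@membraneThickness / px
            rn <- cs@nucleusRadius / px
            cx <- cs@center[1]; cy <- cs@center[2]

            ## supersampled bounding box
            pad <- ceiling(R) + 2L
            ri <- which(ys >= cy - pad & ys <= cy + pad)
            cj <- which(xs >= cx - pad & xs <= cx + pad)
            d2 <- outer((ys[ri] - cy)^2, (xs[cj] - cx)^2, "+")
            inCell <- d2 <= R^2
            inRing <- inCell & d2 > (R - w)^2
            inNuc <- d2 <= rn^2
            inInterior <- inCell & !inRing

            ## areas in base-pixel units
            aCell <- sum(inCell) / SUPERSAMPLE^2
            aRing <- sum(inRing) / SUPERSAMPLE^2
            aNuc <- sum(inNuc) / SUPERSAMPLE^2

            erTot <- cs@erFraction * (1 - cs@membraneFraction) * cs@totalSignal
            uniTot <- (1 - cs@membraneFraction) * cs@totalSignal - erTot
            ## uniform density over the cell, nucleus dimmed to NUCLEUS_DIM
            dU <- uniTot / (aCell - (1 - NUCLEUS_DIM) * aNuc)
            mE <- if (aRing > 0) cs@membraneFraction * cs@totalSignal / aRing
                  else 0

            cellImg <- matrix(0, length(ri), length(cj))
            cellImg[inCell] <- dU
            cellImg[inNuc] <- NUCLEUS_DIM * dU
            cellImg[inRing] <- cellImg[inRing] + mE

            ## ER puncta: seeded positions in the interior, outside nucleus
            erImg <- NULL
            if (erTot > 0 && cs@transfected) {
                erImg <- matrix(0, length(ri), length(cj))
                nsp <- ER_N_SPOTS
                ang <- stats::runif(nsp, 0, 2 * pi)
                rad <- sqrt(stats::runif(nsp)) * (R - w - ER_SIGMA_PX)
                keep <- rad > rn + ER_SIGMA_PX
                if (!any(keep)) keep[which.max(rad)] <- TRUE
                ang <- ang[keep]; rad <- rad[keep]
                for (k in seq_along(ang)) {
                    sx <- cx + rad[k] * cos(ang[k])
                    sy <- cy + rad[k] * sin(ang[k])
                    g <- outer(exp(-(ys[ri] - sy)^2 / (2 * ER_SIGMA_PX^2)),
                               exp(-(xs[cj] - sx)^2 / (2 * ER_SIGMA_PX^2)))
                    g[!inInterior | inNuc] <- 0
                    erImg <- erImg + g
                }
                erImg <- erImg * (erTot * SUPERSAMPLE^2 / sum(erImg))
            }

            if (cs@transfected) {
                protein[ri, cj] <- protein[ri, cj] + cellImg
                if (!is.null(erImg)) {
                    protein[ri, cj] <- protein[ri, cj] + erImg
                    er[ri, cj] <- er[ri, cj] + erImg
                }
            }
            dyeImg <- matrix(0, length(ri), length(cj))
            dyeImg[inRing] <- DYE_RING_LEVEL
            dye[ri, cj] <- dye[ri, cj] + dyeImg

            ## base-resolution truth masks: pixel in mask if >= 50% covered
            mkMask <- function(ssLogical) {
                full <- matrix(0, ssnr, ssnc)
                full[ri, cj] <- ssLogical
                blockAverage(full) >= 0.5
            }
            erMaskTrue <- if (!is.null(erImg))
                mkMask(erImg > 0.05 * max(erImg))
            else matrix(FALSE, nr, nc)
            masks[[ci]] <- list(cell = mkMask(inCell), ring = mkMask(inRing),
                                interior = mkMask(inInterior),
                                nucleus = mkMask(inNuc), er = erMaskTrue,
                                spec = cs)
        }

        channels <- list(protein = blockAverage(protein) +
                             spec@backgroundLevel,
                         membrane_dye = blockAverage(dye) +
                             spec@backgroundLevel)
        if (anyEr) channels$er_marker <- blockAverage(er) +
                0.5 * spec@backgroundLevel

        ## noise applied last: Poisson on the intensity scale, then Gaussian
        channels <- lapply(channels, function(ch) {
            if (spec@noisePoisson)
                ch <- matrix(stats::rpois(length(ch), lambda = pmax(ch, 0)),
                             nrow(ch), ncol(ch))
            if (spec@noiseGaussianSd > 0)
                ch <- ch + matrix(stats::rnorm(length(ch), 0,
                                               spec@noiseGaussianSd),
                                  nrow(ch), ncol(ch))
            ch
        })
        new("Scene", channels = channels, masks = masks, spec = spec)
    })
}

#' Swollen copy of a scene specification
#'
#' Returns the post-challenge counterpart of \code{spec}: each cell's radius
#' is scaled by \code{sqrt(swellingAreaRatio)} (nucleus and ring thickness
#' unchanged), with total signal conserved.
#'
#' @param spec A \linkS4class{SceneSpec}.
#' @param progress Fraction of the swelling reached, in [0, 1] (1 = fully
#'   swollen); intermediate values interpolate the area ratio.
#' @return A \linkS4class{SceneSpec}.
#' @export
swellScene <- function(spec, progress = 1) {
    cells <- lapply(spec@cells, function(cs) {
        ratio <- 1 + (cs@swellingAreaRatio - 1) * progress
        cs@radius <- cs@radius * sqrt(ratio)
        cs
    })
    spec@cells <- cells
    validObject(spec)
    spec
}

#' Render a translocation time course
#'
#' Renders frames at \code{t_k = k / frameRate} for \code{k = 0, 1, ...} up to
#' \code{duration} (inclusive), with every cell's membrane fraction following
#' first-order kinetics
#' \code{f(t) = fEnd + (fStart - fEnd) * exp(-t / tau)}. When \code{swell} is
#' TRUE the cell radius approaches its swollen value with the same time
#' constant.
#'
#' @param spec A \linkS4class{SceneSpec} (its cells' \code{membraneFraction}
#'   is overridden frame by frame).
#' @param fStart,fEnd Membrane fraction at t = 0 and t = Inf.
#' @param tau Time constant, seconds (> 0).
#' @param frameRate Frames per second (> 0); the paper's stacks use 0.1.
#' @param duration Total duration, seconds (> 0).
#' @param swell Interpolate cell swelling with the same kinetics.
#' @return List of \linkS4class{Scene}, one per frame, with an attribute
#'   \code{times} (seconds).
#' @examples
#' frames <- renderTimecourse(sceneSpec(cellSpec(center = c(64, 64))),
#'                            fStart = 0.05, fEnd = 0.23, tau = 30,
#'                            frameRate = 0.1, duration = 120)
#' length(frames)  # 13
#' @export
renderTimecourse <- function(spec, fStart, fEnd, tau, frameRate = 0.1,
                             duration = 120, swell = FALSE) {
    if (tau <= 0) stop("'tau' must be > 0")
    if (frameRate <= 0) stop("'frameRate' must be > 0")
    if (duration <= 0) stop("'duration' must be > 0")
    stopifnot(fStart >= 0, fStart <= 1, fEnd >= 0, fEnd <= 1)
    times <- seq(0, duration, by = 1 / frameRate)
    frames <- vector("list", length(times))
    for (k in seq_along(times)) {
        t <- times[k]
        f <- fEnd + (fStart - fEnd) * exp(-t / tau)
        fspec <- spec
        fspec@cells <- lapply(spec@cells, function(cs) {
            cs@membraneFraction <- f
            cs
        })
        if (swell)
            fspec <- swellScene(fspec, progress = 1 - exp(-t / tau))
        ## one seed per frame, derived deterministically from the scene seed
        fspec@seed <- deriveSeed(spec@seed, k)
        frames[[k]] <- renderScene(fspec)
    }
    attr(frames, "times") <- times
    frames
}
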