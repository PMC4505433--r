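# Internal utilities: seeded evaluation, interpolation, image-mode estimation,
# and small binary-morphology primitives shared by the rendering and
# segmentation code.

#' Evaluate an expression with a private random seed
#'
#' Runs \code{expr} with the global RNG seeded at \code{seed} and restores the
#' caller's RNG state afterwards, so that seeded operations never leak random
#' state into the session.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return Value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single integer")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Derive a child seed from a parent seed and a stream index without integer
## overflow (result always in [1, 2^31 - 2]).
deriveSeed <- function(seed, k) {
    as.integer((as.numeric(seed) * 99991 + as.numeric(k)) %% 2147483646) + 1L
}

## Bilinear interpolation on a matrix at 0-based, pixel-centred coordinates:
## the centre of pixel img[r, c] is (x, y) = (c - 1, r - 1). Coordinates are
## clamped to the image domain.
bilinearAt <- function(img, x, y) {
    nr <- nrow(img); nc <- ncol(img)
    x <- pmin(pmax(x, 0), nc - 1)
    y <- pmin(pmax(y, 0), nr - 1)
    x0 <- floor(x); y0 <- floor(y)
    x0 <- pmin(x0, nc - 2); y0 <- pmin(y0, nr - 2)
    x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
    fx <- x - x0; fy <- y - y0
    i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
    i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
    (1 - fy) * ((1 - fx) * img[i00] + fx * img[i01]) +
        fy * ((1 - fx) * img[i10] + fx * img[i11])
}

## Mode of an intensity sample. For (near-)discrete data the most frequent
## rounded value; for continuous data this is a robust stand-in for the
## histogram mode at unit binning.
intensityMode <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0L) return(NA_real_)
    tab <- table(round(x))
    as.numeric(names(tab)[which.max(tab)])
}

## ---- binary morphology on logical matrices (4/8-connectivity) -------------

shiftMat <- function(m, dr, dc, fill = FALSE) {
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(fill, nr, nc)
    rs <- seq_len(nr); cs <- seq_len(nc)
    rdst <- rs + dr; cdst <- cs + dc
    ok_r <- rdst >= 1 & rdst <= nr; ok_c <- cdst >= 1 & cdst <= nc
    out[rdst[ok_r], cdst[ok_c]] <- m[rs[ok_r], cs[ok_c]]
    out
}

dilateOnce <- function(m, connectivity = 8L) {
    out <- m
    out <- out | shiftMat(m, 1, 0) | shiftMat(m, -1, 0) |
        shiftMat(m, 0, 1) | shiftMat(m, 0, -1)
    if (connectivity == 8L)
        out <- out | shiftMat(m, 1, 1) | shiftMat(m, 1, -1) |
            shiftMat(m, -1, 1) | shiftMat(m, -1, -1)
    out
}

## Dilate a mask by a disk of the given pixel radius (distance transform via
## repeated unit dilation; radius is small everywhere this is used).
dilateDisk <- function(m, radius) {
    if (radius <= 0 || !any(m)) return(m)
    idx <- which(m, arr.ind = TRUE)
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(FALSE, nr, nc)
    rr <- seq_len(nr)
    for (k in seq_len(nrow(idx))) {
        r0 <- idx[k, 1]; c0 <- idx[k, 2]
        rs <- max(1, r0 - radius):min(nr, r0 + radius)
        cs <- max(1, c0 - radius):min(nc, c0 + radius)
        sub <- outer((rs - r0)^2, (cs - c0)^2, "+") <= radius^2
        out[rs, cs] <- out[rs, cs] | sub
    }
    out
}

## Fill holes: background connected to the image border stays background;
## enclosed background becomes foreground.
fillHoles <- function(mask) {
    bg <- !mask
    reach <- matrix(FALSE, nrow(mask), ncol(mask))
    reach[1, ] <- bg[1, ]; reach[nrow(mask), ] <- bg[nrow(mask), ]
    reach[, 1] <- bg[, 1]; reach[, ncol(mask)] <- bg[, ncol(mask)]
    repeat {
        grown <- dilateOnce(reach, 4L) & bg
        if (identical(grown, reach)) break
        reach <- grown
    }
    mask | (bg & !reach)
}

## Label connected components (8-connectivity by default). Returns an integer
## matrix; labels are assigned in raster order of discovery and then re-sorted
## by centroid (row-major) so labelling is stable across calls.
labelComponents <- function(mask, connectivity = 8L) {
    lab <- matrix(0L, nrow(mask), ncol(mask))
    cur <- 0L
    todo <- mask
    while (any(todo)) {
        seedIdx <- which(todo)[1L]
        comp <- matrix(FALSE, nrow(mask), ncol(mask))
        comp[seedIdx] <- TRUE
        repeat {
            grown <- dilateOnce(comp, connectivity) & mask
            if (identical(grown, comp)) break
            comp <- grown
        }
        cur <- cur + 1L
        lab[comp] <- cur
        todo <- todo & !comp
    }
    if (cur > 1L) {
        cent <- t(vapply(seq_len(cur), function(i) {
            ij <- which(lab == i, arr.ind = TRUE)
            c(mean(ij[, 1]), mean(ij[, 2]))
        }, numeric(2)))
        ord <- order(cent[, 1], cent[, 2])
        relab <- integer(cur); relab[ord] <- seq_len(cur)
        lab[lab > 0L] <- relab[lab[lab > 0L]]
    }
    lab
}

#' Otsu's threshold
#'
#' Global threshold maximizing between-class variance on a 256-bin histogram.
#'
#' @param x Numeric matrix or vector of intensities.
#' @param nbins Number of histogram bins.
#' @return Threshold value; pixels strictly greater are foreground.
#' @export
otsuThreshold <- function(x, nbins = 256L) {
    v <- as.numeric(x)
    v <- v[is.finite(v)]
    rng <- range(v)
    if (diff(rng) == 0) return(rng[1])
    br <- seq(rng[1], rng[2], length.out = nbins + 1L)
    h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
    p <- h / sum(h)
    mids <- (br[-1] + br[-length(br)]) / 2
    w0 <- cumsum(p)
    mu <- cumsum(p * mids)
    muT <- mu[nbins]
    sb <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
    sb[!is.finite(sb)] <- 0
    mids[which.max(sb)]
}

## SEM of a vector across its elements (NA if fewer than 2).
semOf <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2L) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
}

## Run-length encode a logical matrix (column-major), for JSON sidecars.
rleMask <- function(mask) {
    r <- rle(as.logical(mask))
    list(dim = dim(mask), lengths = r$lengths, values = r$values)
}

unrleMask <- function(enc) {
    d <- as.integer(unlist(enc$dim))
    matrix(inverse.rle(list(lengths = as.integer(unlist(enc$lengths)),
                            values = as.logical(unlist(enc$values)))),
           nrow = d[1], ncol = d[2])
}
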