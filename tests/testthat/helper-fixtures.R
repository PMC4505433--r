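# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; no stored data.

## internal morphology helper, reachable when testing the installed package
dil <- function(m, r) rmequant:::dilateDisk(m, r)

## One centred cell, optionally noisy.
oneCellScene <- function(f = 0, noise = 0, background = 10, seed = 1L,
                         er = 0, nucleus = 3, signal = 2e5) {
    renderScene(sceneSpec(
        cellSpec(center = c(64, 64), membraneFraction = f,
                 erFraction = er, nucleusRadius = nucleus,
                 totalSignal = signal),
        backgroundLevel = background, noiseGaussianSd = noise, seed = seed))
}

## A wide scene with one transfected and one non-transfected cell, for the
## swelling pipeline (transfected swells by swT, non-transfected by swN).
swellPairSpec <- function(swT = 1.45, swN = 1.05, f = 0.059, seed = 1L,
                          noise = 2) {
    cells <- list(
        cellSpec(center = c(52, 64), membraneFraction = f,
                 swellingAreaRatio = swT),
        cellSpec(center = c(156, 64), membraneFraction = 0, totalSignal = 0,
                 transfected = FALSE, swellingAreaRatio = swN))
    sceneSpec(cells, imageShape = c(128L, 220L), noiseGaussianSd = noise,
              seed = seed)
}

## ---- independent oracles ---------------------------------------------------

## Brute-force membrane segmentation: same half-height criterion as
## detectMembrane but implemented by exhaustive scanning (no run-growing):
## for each side, scan every index of the window for the highest local
## maximum, then collect ALL indices in the span meeting the threshold and
## take the contiguous block containing the peak.
bruteForceSegments <- function(v, i0, i1) {
    len <- i1 - i0 + 1L
    nw <- max(2L, as.integer(ceiling(0.25 * len)))
    qs <- i0 + as.integer(floor(0.25 * len))
    qe <- i0 + as.integer(ceiling(0.75 * len)) - 1L
    baseline <- median(v[qs:qe])
    localMax <- function(k) {
        lo <- if (k > 1L) v[k - 1L] else -Inf
        hi <- if (k < length(v)) v[k + 1L] else -Inf
        v[k] >= lo && v[k] >= hi
    }
    pick <- function(window, fromEnd) {
        cand <- Filter(localMax, window)
        if (!length(cand)) cand <- window
        best <- cand[vapply(cand, function(k) v[k], 0) == max(v[cand])]
        if (fromEnd) best[length(best)] else best[1L]
    }
    seg <- function(peak) {
        th <- baseline + 0.5 * (v[peak] - baseline)
        ok <- which(v >= th)
        ok <- ok[ok >= i0 & ok <= i1]
        ## contiguous block containing the peak
        blocks <- split(ok, cumsum(c(1, diff(ok) != 1)))
        blk <- blocks[[which(vapply(blocks, function(b) peak %in% b, TRUE))]]
        range(blk)
    }
    pe <- pick(i0:(i0 + nw - 1L), FALSE)
    px <- pick((i1 - nw + 1L):i1, TRUE)
    flat <- c(v[pe] - baseline <= 0, v[px] - baseline <= 0)
    entry <- if (flat[1]) c(i0, i0) else seg(pe)
    exit <- if (flat[2]) c(i1, i1) else seg(px)
    list(entry = entry, exit = exit, peaks = c(pe, px), baseline = baseline,
         flat = flat)
}

## Nested (hierarchical) mean oracle: explicit loops, no aggregate().
nestedMeanOracle <- function(df) {
    repMeans <- c()
    for (r in unique(df$repeat_id)) {
        cellMeans <- c()
        dfr <- df[df$repeat_id == r, ]
        for (cl in unique(dfr$cell_id))
            cellMeans <- c(cellMeans, mean(dfr$rme[dfr$cell_id == cl]))
        repMeans <- c(repMeans, mean(cellMeans))
    }
    list(mean = mean(repMeans),
         sem = sd(repMeans) / sqrt(length(repMeans)))
}

## Hand paired-t oracle (textbook formula).
pairedTOracle <- function(before, after) {
    d <- after - before
    n <- length(d)
    t <- mean(d) / (sd(d) / sqrt(n))
    p <- 2 * pt(-abs(t), df = n - 1)
    list(t = t, p = p)
}

## Hand Welch-t oracle.
welchTOracle <- function(a, b) {
    va <- var(a) / length(a); vb <- var(b) / length(b)
    t <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    p <- 2 * pt(-abs(t), df = df)
    list(t = t, p = p)
}

## Hand one-way repeated-measures ANOVA oracle (balanced).
rmAnovaOracle <- function(groups) {
    k <- length(groups); n <- length(groups[[1]])
    y <- matrix(unlist(groups), nrow = n)      # rows = subjects
    gm <- mean(y)
    ssTreat <- n * sum((colMeans(y) - gm)^2)
    ssSubj <- k * sum((rowMeans(y) - gm)^2)
    ssErr <- sum((y - gm)^2) - ssTreat - ssSubj
    Fv <- (ssTreat / (k - 1)) / (ssErr / ((k - 1) * (n - 1)))
    p <- pf(Fv, k - 1, (k - 1) * (n - 1), lower.tail = FALSE)
    list(F = Fv, p = p)
}
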