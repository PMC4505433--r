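# Line profiles, membrane detection and the RME statistic.

test_that("bilinear sampling reproduces hand-computed values", {
    img <- matrix(7, 20, 20)
    pr <- sampleProfile(img, c(2, 3, 15, 11))
    expect_true(all(pr@intensities == 7))
    ## axis-aligned line hits pixel values at integer steps
    img2 <- matrix(seq_len(400), 20, 20)   # column-major fill
    pr2 <- sampleProfile(img2, c(0, 5, 10, 5))   # along row y = 5
    atInt <- pr2@intensities[seq(1, length(pr2@intensities), by = 2)]
    expect_equal(atInt, img2[6, 1:11])
    ## diagonal across a 2x2 checkerboard: the interpolant at the centre
    ## equals the mean of the 4 pixels (hand bilinear formula)
    cb <- matrix(c(1, 0, 0, 1), 2, 2)
    expect_equal(rmequant:::bilinearAt(cb, 0.5, 0.5), 0.5)
    prd <- sampleProfile(cb, c(0, 0, 1, 1))
    expect_equal(prd@intensities[1], 1)
    expect_error(sampleProfile(img, c(3, 3, 3, 3)), "identical")
    ## positions are in micrometres
    expect_equal(diff(pr@positions)[1], 0.5 * 0.2)
})

test_that("profile placement avoids the dilated nucleus and sweeps angles", {
    sc <- oneCellScene(f = 0.3)
    mk <- sceneMasks(sc)[[1]]
    ## no nucleus: three diameters at 0, 60, 120 degrees
    lines0 <- placeProfiles(mk$cell, nucleusMask = NULL, nLines = 3L)
    expect_equal(vapply(lines0, `[[`, 0, "angle"), c(0, 60, 120))
    ## central nucleus: all returned lines must miss the dilated nucleus,
    ## verified against a brute-force point-in-mask sweep
    nucD <- dil(mk$nucleus, 2L)
    lines <- placeProfiles(mk$cell, mk$nucleus, nLines = 3L)
    expect_length(lines, 3L)
    for (ln in lines) {
        pr <- sampleProfile(getChannel(sc, "protein"), ln$endpoints)
        expect_false(any(rmequant:::profileInMask(pr, nucD)))
        ## crosses the cell fully: both endpoints outside
        inC <- rmequant:::profileInMask(pr, mk$cell)
        expect_false(inC[1])
        expect_false(inC[length(inC)])
        expect_gte(sum(inC), 20L)
    }
    expect_equal(anyDuplicated(vapply(lines, `[[`, 0, "angle")), 0L)
    ## nucleus covering the whole cell body is infeasible and names the cell
    big <- dil(mk$cell, 2L)
    expect_error(placeProfiles(mk$cell, big, cellId = 7L), "cell 7")
})

test_that("membrane detection matches the half-height rule and truth masks", {
    ## synthetic membrane-only cell: segments sit on the true ring crossings
    sc <- renderScene(sceneSpec(cellSpec(center = c(64, 64),
                                         membraneFraction = 1),
                                backgroundLevel = 0))
    mk <- sceneMasks(sc)[[1]]
    ln <- placeProfiles(mk$cell, mk$nucleus)[[1]]
    pr <- sampleProfile(getChannel(sc, "protein"), ln$endpoints)
    span <- range(which(rmequant:::profileInMask(pr, mk$cell)))
    seg <- detectMembrane(pr, span)
    ringIdx <- which(rmequant:::profileInMask(pr, mk$ring))
    entryRing <- ringIdx[ringIdx < mean(span)]
    exitRing <- ringIdx[ringIdx > mean(span)]
    expect_lte(abs(seg$entry[1] - min(entryRing)), 1L)
    expect_lte(abs(seg$exit[2] - max(exitRing)), 1L)
    ## uniform disk triggers the flat rule: M collapses to the baseline
    scF <- oneCellScene(f = 0, nucleus = 0)
    mkF <- sceneMasks(scF)[[1]]
    lnF <- placeProfiles(mkF$cell, NULL)[[1]]
    prF <- sampleProfile(getChannel(scF, "protein"), lnF$endpoints)
    spanF <- range(which(rmequant:::profileInMask(prF, mkF$cell)))
    segF <- detectMembrane(prF, spanF)
    expect_true(all(segF$flat))
    expect_equal(segF$peakHeights, rep(segF$baseline, 2))
    ## constructed profile, peaks 100 over baseline 20: half-height threshold
    ## is 60, so each segment is the contiguous run of samples >= 60
    v <- c(0, 0, 20, 100, 60, rep(20, 12), 60, 100, 20, 0)
    prC <- new("LineProfile", endpoints = c(0, 0, (length(v) - 1) / 2, 0),
               positions = seq(0, by = 0.1, length.out = length(v)),
               intensities = v, cellId = 1L)
    segC <- detectMembrane(prC, c(3L, 20L))
    expect_equal(segC$baseline, 20)
    expect_equal(segC$entry, c(4L, 5L))
    expect_equal(segC$exit, c(18L, 19L))
    expect_equal(segC$peakHeights, c(100, 100))
    expect_error(detectMembrane(prC, c(3L, 8L)), "8 samples")
})

test_that("compute_rme applies the definitional identity and exclusions", {
    ## direct formula: M = 80, C = 20, Imax = 100 -> RME 60
    v <- c(0, 20, 80, 20, 20, 20, 20, 20, 20, 80, 20, 0)
    pr <- new("LineProfile", endpoints = c(0, 0, 5.5, 0),
              positions = seq(0, by = 0.1, length.out = 12),
              intensities = v, cellId = 1L)
    seg <- detectMembrane(pr, c(2L, 11L))
    ## force Imax to 100 via a brighter interior sample
    v2 <- v; v2[6] <- 100
    pr2 <- new("LineProfile", endpoints = c(0, 0, 5.5, 0),
               positions = seq(0, by = 0.1, length.out = 12),
               intensities = v2, cellId = 1L)
    seg2 <- detectMembrane(pr2, c(2L, 11L))
    r <- computeRme(pr2, seg2, background = 0, membraneBuffer = 0)
    expect_equal(r$M, 80)
    expect_equal(r$Imax, 100)
    expect_equal(r$rme, 100 * (80 - r$C) / 100)
    ## background subtraction: empty cell errors
    prB <- new("LineProfile", endpoints = c(0, 0, 5.5, 0),
               positions = seq(0, by = 0.1, length.out = 12),
               intensities = rep(5, 12), cellId = 1L)
    segB <- detectMembrane(prB, c(2L, 11L))
    expect_error(computeRme(prB, segB, background = 5), "empty cell")
})

test_that("RME anchors: 0 for even distribution, ~100 for membrane-only", {
    df0 <- rmeForScene(oneCellScene(f = 0))
    expect_equal(mean(df0$rme), 0, tolerance = 1e-8)
    sc1 <- renderScene(sceneSpec(cellSpec(center = c(64, 64),
                                          membraneFraction = 1),
                                 backgroundLevel = 0))
    r1 <- mean(rmeForScene(sc1)$rme)
    expect_gte(r1, 98)
    expect_lte(r1, 100)
})

test_that("RME is strictly monotone in the membrane fraction", {
    rmes <- vapply(c(0, 0.2, 0.4, 0.6, 0.8, 1), function(f)
        mean(rmeForScene(oneCellScene(f = f))$rme), numeric(1))
    expect_true(all(diff(rmes) > 0))
})

test_that("RME is invariant to rotation and intensity scaling", {
    sc <- oneCellScene(f = 0.3)
    base <- mean(rmeForScene(sc)$rme)
    ## 90-degree rotation of channels, masks and cell geometry
    rot <- function(m) t(m)[, nrow(m):1, drop = FALSE]
    scR <- sc
    scR@channels <- lapply(sc@channels, rot)
    scR@masks <- lapply(sc@masks, function(mk) {
        out <- lapply(mk[c("cell", "ring", "interior", "nucleus", "er")], rot)
        out$spec <- mk$spec
        out
    })
    expect_equal(mean(rmeForScene(scR)$rme), base, tolerance = 1)
    ## scale invariance: multiply all intensities by c
    scS <- sc
    scS@channels <- lapply(sc@channels, function(m) m * 37)
    expect_equal(mean(rmeForScene(scS)$rme), base, tolerance = 1e-6)
})

test_that("detect+compute agree with the brute-force segmentation oracle", {
    set.seed(5)
    for (k in 1:50) {
        n <- sample(20:50, 1)
        i0 <- sample(1:3, 1); i1 <- n - sample(1:3, 1)
        base <- runif(1, 10, 50)
        v <- base + rnorm(n, 0, runif(1, 0, 8))
        ## add membrane-like bumps near the ends of the span
        v[i0 + sample(0:2, 1)] <- base + runif(1, 20, 80)
        v[i1 - sample(0:2, 1)] <- base + runif(1, 20, 80)
        pr <- new("LineProfile", endpoints = c(0, 0, (n - 1) / 2, 0),
                  positions = seq(0, by = 0.1, length.out = n),
                  intensities = v, cellId = 1L)
        seg <- detectMembrane(pr, c(i0, i1))
        ora <- bruteForceSegments(v, i0, i1)
        if (ora$entry[2] < ora$exit[1]) {   # oracle valid (non-overlapping)
            expect_equal(seg$entry, as.integer(ora$entry))
            expect_equal(seg$exit, as.integer(ora$exit))
            expect_equal(seg$baseline, ora$baseline)
        }
    }
})

test_that("ER exclusion is an identity at er = 0 and bounded at er = 0.3", {
    scNoEr <- oneCellScene(f = 0.3, er = 0, seed = 3L)
    base <- mean(rmeForScene(scNoEr)$rme)
    ## er = 0 scene has no ER channel; exclusion is the identity
    expect_equal(mean(rmeForScene(scNoEr, erExclude = TRUE)$rme), base)
    ## er = 0.3: averaged over cells/seeds, (a) the ER exclusion changes the
    ## calculated RME by < 10% relative, and (b) the corrected RME recovers
    ## the ER-free scene's RME within 10% relative
    devCorr <- devRecover <- numeric(6)
    for (s in 1:6) {
        ref <- mean(rmeForScene(oneCellScene(f = 0.3, er = 0, seed = s))$rme)
        scEr <- oneCellScene(f = 0.3, er = 0.3, seed = s)
        un <- mean(rmeForScene(scEr, erExclude = FALSE)$rme)
        co <- mean(rmeForScene(scEr, erExclude = TRUE)$rme)
        devCorr[s] <- abs(co - un) / un
        devRecover[s] <- abs(co - ref) / ref
    }
    expect_lt(mean(devCorr), 0.10)
    expect_lt(mean(devRecover), 0.10)
    ## degenerate exclusion: ER mask covering the whole interior
    mk <- sceneMasks(scEr)[[1]]
    ln <- placeProfiles(mk$cell, mk$nucleus)[[1]]
    pr <- sampleProfile(getChannel(scEr, "protein"), ln$endpoints)
    span <- range(which(rmequant:::profileInMask(pr, mk$cell)))
    seg <- detectMembrane(pr, span)
    allEr <- rep(TRUE, length(pr@intensities))
    expect_error(computeRme(pr, seg, background = 10, erIn = allEr),
                 "no intracellular samples")
})

test_that("aggregation is hierarchical, not pooled", {
    ## repeats with cell-means {20, 30, 40}: mean 30, SEM 5.774
    df <- data.frame(rme = c(20, 20, 30, 30, 40, 40),
                     cell_id = c(1, 1, 1, 1, 1, 1),
                     repeat_id = c(1, 1, 2, 2, 3, 3))
    agg <- aggregateRme(df)
    expect_equal(agg$summary$mean_rme, 30)
    expect_equal(agg$summary$sem, 10 / sqrt(3), tolerance = 1e-4)
    expect_equal(round(agg$summary$sem, 3), 5.774)
    ## constant input: SEM 0
    dfc <- data.frame(rme = rep(12, 6), cell_id = rep(1:2, 3),
                      repeat_id = rep(1:3, each = 2))
    expect_equal(aggregateRme(dfc)$summary$sem, 0)
    ## unbalanced cells per repeat: equals the nested-mean oracle
    set.seed(11)
    dfu <- data.frame(rme = runif(13, 0, 100),
                      cell_id = c(1, 1, 1, 2, 2, 1, 1, 2, 3, 3, 3, 1, 2),
                      repeat_id = c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 2, 3, 3))
    agg <- aggregateRme(dfu)
    ora <- nestedMeanOracle(dfu)
    expect_equal(agg$summary$mean_rme, ora$mean)
    expect_equal(agg$summary$sem, ora$sem)
    expect_false(isTRUE(all.equal(agg$summary$mean_rme, mean(dfu$rme))))
    ## fewer than 2 repeats: flagged
    expect_warning(aggregateRme(df[df$repeat_id == 1, ]), "fewer than 2")
})

test_that("RME/fraction calibration inverts the rendered curve", {
    cs <- cellSpec(center = c(64, 64))
    rho <- cellRho(cs)
    for (f in c(0.1, 0.3)) {
        sc <- oneCellScene(f = f)
        measured <- mean(rmeForScene(sc)$rme)
        expect_equal(measured, fractionToRme(f, rho), tolerance = 2)
        expect_equal(rmeToFraction(fractionToRme(f, rho), rho), f,
                     tolerance = 1e-10)
    }
})
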