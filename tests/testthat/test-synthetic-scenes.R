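# Renderer and plate simulator: analytic anchors, conservation, determinism.

test_that("even distribution (f = 0) renders ring and interior at one level", {
    sc <- oneCellScene(f = 0)
    p <- getChannel(sc, "protein")
    mk <- sceneMasks(sc)[[1]]
    ## interior away from nucleus and ring is constant
    core <- mk$interior & !dil(mk$nucleus, 2L)
    ringVals <- p[mk$ring & !dil(!mk$cell, 1L)]  # fully interior ring px
    expect_lt(diff(range(p[core])), 1e-6)
    expect_equal(mean(ringVals), mean(p[core]), tolerance = 1e-3)
})

test_that("membrane-only cell (f = 1) confines protein to the ring", {
    sc <- renderScene(sceneSpec(cellSpec(center = c(64, 64),
                                         membraneFraction = 1),
                                backgroundLevel = 5))
    p <- getChannel(sc, "protein")
    mk <- sceneMasks(sc)[[1]]
    inner <- mk$interior & !dil(mk$ring, 2L)
    expect_true(all(abs(p[inner] - 5) < 1e-9))
    expect_gt(mean(p[mk$ring]), 100)
})

test_that("integrated noise-free signal equals totalSignal within 1%", {
    for (f in c(0, 0.3, 1)) {
        sc <- oneCellScene(f = f, background = 10)
        tot <- sum(getChannel(sc, "protein") - 10)
        expect_equal(tot, 2e5, tolerance = 0.01)
    }
    ## with ER puncta the budget still balances
    sc <- oneCellScene(f = 0.3, er = 0.3)
    expect_equal(sum(getChannel(sc, "protein") - 10), 2e5, tolerance = 0.01)
    ## and over multiple transfected cells
    spec <- swellPairSpec(noise = 0)
    tot <- sum(getChannel(renderScene(spec), "protein") -
                   spec@backgroundLevel)
    expect_equal(tot, 2e5, tolerance = 0.01)
})

test_that("identical specs (including seed) render bit-identical scenes", {
    a <- oneCellScene(f = 0.4, noise = 3, seed = 42L)
    b <- oneCellScene(f = 0.4, noise = 3, seed = 42L)
    expect_identical(a@channels, b@channels)
    c <- oneCellScene(f = 0.4, noise = 3, seed = 43L)
    expect_false(identical(a@channels, c@channels))
    ## plates too
    tr <- elisaTruth(c("a", "b"), c(1, 2), cv = 0.2, seed = 9L)
    expect_identical(plateWells(simulateElisaPlate(tr)),
                     plateWells(simulateElisaPlate(tr)))
})

test_that("ring/interior intensity ratio increases strictly with f", {
    ratios <- vapply(c(0, 0.2, 0.4, 0.6, 0.8, 1), function(f) {
        sc <- oneCellScene(f = f)
        p <- getChannel(sc, "protein") - 10
        mk <- sceneMasks(sc)[[1]]
        core <- mk$interior & !dil(mk$nucleus, 2L) &
            !dil(mk$ring, 2L)
        mean(p[mk$ring]) / max(mean(p[core]), 1e-12)
    }, numeric(1))
    expect_true(all(diff(ratios) > 0))
})

test_that("renderer rejects ambiguous or impossible geometry", {
    expect_error(renderScene(sceneSpec(list(
        cellSpec(center = c(60, 64)), cellSpec(center = c(80, 64))))),
        "overlap")
    expect_error(cellSpec(center = c(64, 64), nucleusRadius = 9),
                 "nucleusRadius")
    expect_error(sceneSpec(cellSpec(center = c(5, 5))), "outside")
})

test_that("timecourse sampling follows t_k = k / frameRate inclusive", {
    spec <- sceneSpec(cellSpec(center = c(64, 64)))
    frames <- renderTimecourse(spec, fStart = 0.1, fEnd = 0.1, tau = 30,
                               frameRate = 0.1, duration = 120)
    expect_length(frames, 13L)
    expect_equal(attr(frames, "times"), seq(0, 120, by = 10))
    ## f_start = f_end: frames identical apart from noise (noise off here)
    p1 <- getChannel(frames[[1]], "protein")
    p7 <- getChannel(frames[[7]], "protein")
    expect_equal(p1, p7, tolerance = 1e-12)
    expect_error(renderTimecourse(spec, 0.1, 0.5, tau = 30, duration = 0),
                 "duration")
    expect_error(renderTimecourse(spec, 0.1, 0.5, tau = -1), "tau")
})

test_that("timecourse membrane fraction decays exponentially", {
    spec <- sceneSpec(cellSpec(center = c(64, 64)))
    frames <- renderTimecourse(spec, fStart = 0.8, fEnd = 0.2, tau = 30,
                               frameRate = 0.1, duration = 120)
    fOf <- function(fr) sceneMasks(fr)[[1]]$spec@membraneFraction
    ## at t = tau, f - fEnd = (fStart - fEnd)/e
    fTau <- 0.2 + 0.6 * exp(-1)
    fs <- vapply(frames, fOf, numeric(1))
    expect_equal(approx(attr(frames, "times"), fs, xout = 30)$y, fTau,
                 tolerance = 0.01)
    expect_equal(fs[1], 0.8)
})

test_that("plate simulator honours layout and exact noise-free levels", {
    tr <- elisaTruth(c("ctl", "treat"), c(0.3, 0.6), cv = 0,
                     blankLevel = 0, nRepeats = 2L)
    w <- plateWells(simulateElisaPlate(tr))
    expect_true(all(w$absorbance[w$condition == "ctl"] == 0.3))
    expect_true(all(w$absorbance[w$condition == "treat"] == 0.6))
    expect_equal(sum(w$condition == "ctl"), 6L)      # 2 repeats x 3 wells
    expect_false(anyDuplicated(w$well) > 0)
    ## estimated fold is exact at cv = 0
    q <- quantifyPlate(simulateElisaPlate(tr))
    fc <- foldChange(q, "ctl")
    expect_equal(fc$fold[fc$condition == "treat"], 2.0)
})

test_that("mean estimated fold is within 5% of truth at cv = 0.1 (MC)", {
    folds <- vapply(1:60, function(s) {
        tr <- elisaTruth(c("ctl", "treat"), c(1, 2), cv = 0.1, seed = s)
        q <- quantifyPlate(simulateElisaPlate(tr))
        fc <- foldChange(q, "ctl")
        fc$fold[fc$condition == "treat"]
    }, numeric(1))
    expect_equal(mean(folds), 2, tolerance = 0.05)
})
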