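# Segmentation, matching, transfection classification and area change.

test_that("segmentation recovers disk areas and filters specks", {
    ## noise-free disk of radius r px: one component, area within 2% of pi r^2
    img <- matrix(0, 100, 100)
    d2 <- outer((1:100 - 50)^2, (1:100 - 50)^2, "+")
    img[d2 <= 30^2] <- 100
    seg <- segmentCells(img)
    expect_equal(nrow(seg$table), 1L)
    expect_equal(seg$table$area_px, pi * 30^2, tolerance = 0.02)
    ## two disjoint disks: two labels with independent areas
    img2 <- matrix(0, 100, 200)
    img2[outer((1:100 - 50)^2, (1:200 - 50)^2, "+") <= 20^2] <- 100
    img2[outer((1:100 - 50)^2, (1:200 - 150)^2, "+") <= 30^2] <- 100
    seg2 <- segmentCells(img2)
    expect_equal(nrow(seg2$table), 2L)
    expect_equal(sort(seg2$table$area_px),
                 sort(c(sum(outer((1:100 - 50)^2, (1:200 - 50)^2, "+")
                            <= 20^2),
                        sum(outer((1:100 - 50)^2, (1:200 - 150)^2, "+")
                            <= 30^2))))
    ## a 10-px speck is removed by the min-size filter
    img3 <- img
    img3[5:6, 5:9] <- 100
    seg3 <- segmentCells(img3)
    expect_equal(nrow(seg3$table), 1L)
    ## blank image: empty result, not an error
    expect_equal(nrow(segmentCells(matrix(0, 50, 50))$table), 0L)
})

test_that("dye-channel segmentation fills the ring to the full footprint", {
    sc <- oneCellScene(f = 0.5)
    seg <- segmentCells(getChannel(sc, "membrane_dye"))
    truth <- sum(sceneMasks(sc)[[1]]$cell)
    expect_equal(nrow(seg$table), 1L)
    expect_equal(seg$table$area_px, truth, tolerance = 0.03)
})

test_that("area estimator is close to unbiased over noisy disks", {
    areas <- vapply(1:40, function(s) {
        sc <- renderScene(sceneSpec(cellSpec(center = c(64, 64)),
                                    noiseGaussianSd = 2, seed = s))
        segmentCells(getChannel(sc, "membrane_dye"))$table$area_px[1]
    }, numeric(1))
    expect_equal(mean(areas), pi * 40^2, tolerance = 0.03)
})

test_that("matching pairs cells by centroid and drops lost cells", {
    img <- matrix(0, 100, 200)
    img[outer((1:100 - 50)^2, (1:200 - 50)^2, "+") <= 20^2] <- 100
    img[outer((1:100 - 50)^2, (1:200 - 150)^2, "+") <= 20^2] <- 100
    seg <- segmentCells(img)
    ## identical frames: identity matching
    m <- matchCells(seg, seg)
    expect_equal(m$cell_id, m$cell_id_post)
    expect_equal(nrow(m), 2L)
    ## one cell shifted 2 px: still matched
    img2 <- matrix(0, 100, 200)
    img2[outer((1:100 - 50)^2, (1:200 - 52)^2, "+") <= 20^2] <- 100
    img2[outer((1:100 - 50)^2, (1:200 - 150)^2, "+") <= 20^2] <- 100
    m2 <- matchCells(seg, segmentCells(img2))
    expect_equal(nrow(m2), 2L)
    ## matching is symmetric for small displacements
    m2r <- suppressWarnings(matchCells(segmentCells(img2), seg))
    expect_equal(m2$displacement_px, m2r$displacement_px)
    ## cell disappearing post: dropped with a warning
    img3 <- matrix(0, 100, 200)
    img3[outer((1:100 - 50)^2, (1:200 - 50)^2, "+") <= 20^2] <- 100
    expect_warning(m3 <- matchCells(seg, segmentCells(img3)), "unmatched")
    expect_equal(nrow(m3), 1L)
})

test_that("transfection classification separates signal from none", {
    spec <- swellPairSpec(noise = 2, seed = 4L)
    sc <- renderScene(spec)
    seg <- segmentCells(getChannel(sc, "membrane_dye"))
    protein <- getChannel(sc, "protein")
    bg <- !dil(seg$labels > 0L, 2L)
    flags <- vapply(seg$table$cell_id, function(id)
        classifyTransfected(seg$labels == id, protein, bg), logical(1))
    ## cell 1 (left) carries signal; cell 2 does not
    expect_equal(sort(seg$table$centroid_x[flags]), 52, tolerance = 1)
    expect_equal(sum(flags), 1L)
    ## strict inequality: a borderline cell at exactly the threshold is
    ## non-transfected
    flat <- matrix(10, 60, 60)
    mask <- matrix(FALSE, 60, 60); mask[20:40, 20:40] <- TRUE
    expect_false(classifyTransfected(mask, flat, !mask))
})

test_that("area change follows the post-as-percent-of-pre convention", {
    ## identical pre/post: change 100%, increase 0%
    pairs <- data.frame(area_px_pre = c(100, 200), area_px_post = c(100, 200),
                        transfected = c(TRUE, FALSE))
    g <- areaChange(pairs)
    expect_equal(g$mean_pct, c(100, 100))
    expect_equal(g$increase, c(0, 0))
    ## generator ground truth: swelling 1.45 -> increase ~45%
    spec <- swellPairSpec(swT = 1.45, swN = 1.05, seed = 2L)
    sw <- measureSwelling(renderScene(spec), renderScene(swellScene(spec)))
    g2 <- sw$groups
    expect_equal(g2$increase[g2$transfected], 45, tolerance = 2)
    expect_equal(g2$increase[!g2$transfected], 5, tolerance = 2)
})

test_that("group means recover 45% and 5% swelling over seeds", {
    inc <- t(vapply(1:8, function(s) {
        spec <- swellPairSpec(seed = s)
        sw <- measureSwelling(renderScene(spec),
                              renderScene(swellScene(spec)))
        g <- sw$groups
        c(g$increase[g$transfected], g$increase[!g$transfected])
    }, numeric(2)))
    expect_equal(mean(inc[, 1]), 45, tolerance = 2)
    expect_equal(mean(inc[, 2]), 5, tolerance = 2)
})
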