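# ELISA quantification: blank handling, folds, percent-of-reference.

test_that("plate quantification follows triplicate-minus-blank arithmetic", {
    ## triplicates {0.30, 0.32, 0.34} with blank 0.02 -> level 0.30
    wells <- data.frame(
        well = c("A1", "A2", "A3", "A4"),
        row = 1L, col = 1:4,
        condition = c(rep("x", 3), "blank"),
        repeat_id = c(1L, 1L, 1L, 1L),
        replicate = c(1L, 2L, 3L, 1L),
        absorbance = c(0.30, 0.32, 0.34, 0.02))
    plate <- new("ElisaPlate", wells = wells, truth = NULL)
    q <- quantifyPlate(plate)
    expect_equal(q$summary$level, 0.30)
    ## all wells equal to the blank -> level 0
    wells2 <- wells; wells2$absorbance <- 0.1
    expect_equal(quantifyPlate(new("ElisaPlate", wells = wells2,
                                   truth = NULL))$summary$level, 0)
    ## negative blank-subtracted values floor at 0 with a warning
    wells3 <- wells; wells3$absorbance <- c(0.01, 0.01, 0.01, 0.05)
    expect_warning(q3 <- quantifyPlate(new("ElisaPlate", wells = wells3,
                                           truth = NULL)), "floored")
    expect_equal(q3$summary$level, 0)
    ## no blanks and no configured level is an error
    wells4 <- wells[wells$condition != "blank", ]
    expect_error(quantifyPlate(new("ElisaPlate", wells = wells4,
                                   truth = NULL)), "blank")
    expect_equal(quantifyPlate(new("ElisaPlate", wells = wells4,
                                   truth = NULL),
                               blank = 0.02)$summary$level, 0.30)
})

test_that("fold change and percent-of-reference identities hold", {
    tr <- elisaTruth(c("ctl", "same", "up"), c(0.2, 0.2, 0.54), cv = 0,
                     blankLevel = 0)
    q <- quantifyPlate(simulateElisaPlate(tr))
    fc <- foldChange(q, "ctl")
    expect_equal(fc$fold[fc$condition == "ctl"], 1)
    expect_equal(fc$fold[fc$condition == "same"], 1)
    ## levels {0.2, 0.54} -> fold 2.7
    expect_equal(fc$fold[fc$condition == "up"], 2.7)
    pct <- pctOfReference(q, "ctl")
    expect_equal(pct$pct_of_reference[pct$condition == "ctl"], 100)
    expect_equal(pct$pct_of_reference[pct$condition == "up"], 270)
    expect_error(foldChange(q, "nope"), "not present")
    ## emulated low-expression mutant: level 0.17 vs reference 1.0 -> 17%
    tr2 <- elisaTruth(c("wt", "mut"), c(1.0, 0.17), cv = 0, blankLevel = 0)
    q2 <- quantifyPlate(simulateElisaPlate(tr2))
    p2 <- pctOfReference(q2, "wt")
    expect_equal(p2$pct_of_reference[p2$condition == "mut"], 17.0)
    expect_false(p2$low_expression[p2$condition == "mut"])
})

test_that("fold estimator bias shrinks as cv decreases", {
    bias <- vapply(c(0.2, 0.1, 0.05), function(cv) {
        folds <- vapply(1:60, function(s) {
            tr <- elisaTruth(c("a", "b"), c(1, 2), cv = cv,
                             seed = 1000L + s)
            fc <- foldChange(quantifyPlate(simulateElisaPlate(tr)), "a")
            fc$fold[fc$condition == "b"]
        }, numeric(1))
        abs(mean(folds) - 2) / 2
    }, numeric(1))
    expect_true(all(diff(bias) < 0))    # monotone improvement
    expect_lt(bias[3], 0.01)
})

test_that("a no-change analyte is not called: CI covers fold 1", {
    ## negative-control emulation (a transporter that does not respond):
    ## true fold 1.0, cv 0.1; the per-repeat fold CI covers 1 in >= 90% of
    ## seeds
    cover <- vapply(1:100, function(s) {
        tr <- elisaTruth(c("iso", "hypo"), c(1, 1), cv = 0.1, seed = s)
        fc <- foldChange(quantifyPlate(simulateElisaPlate(tr)), "iso")
        f <- fc[fc$condition == "hypo", ]
        ci <- f$fold + c(-1, 1) * stats::qt(0.975, f$n - 1) * f$fold_sem
        ci[1] <= 1 && 1 <= ci[2]
    }, logical(1))
    expect_gte(mean(cover), 0.90)
})

test_that("outputs are invariant to well-row permutation", {
    tr <- elisaTruth(c("a", "b"), c(1, 2.7), cv = 0.1, seed = 5L)
    plate <- simulateElisaPlate(tr)
    q1 <- quantifyPlate(plate)
    perm <- plate
    set.seed(1)
    perm@wells <- perm@wells[sample(nrow(perm@wells)), ]
    q2 <- quantifyPlate(perm)
    expect_equal(q1$summary, q2$summary)
    expect_equal(foldChange(q1, "a"), foldChange(q2, "a"))
})
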