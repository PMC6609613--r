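test_that("ICC estimates match the explicit ANOVA oracle to 1e-10", {
    set.seed(77)
    for (case in 1:25) {
        x <- matrix(rnorm(8 * 6, mean = 10), 8, 6)
        expect_equal(iccEstimate(x, "ICC(2,1)")$estimate,
                     oracle_icc(x, "ICC(2,1)"), tolerance = 1e-10)
        expect_equal(iccEstimate(x, "ICC(3,1)")$estimate,
                     oracle_icc(x, "ICC(3,1)"), tolerance = 1e-10)
    }
})

test_that("identical raters give perfect absolute agreement", {
    x <- matrix(rep(c(1, 3, 7, 2, 9), 4), ncol = 4)
    r <- iccEstimate(x, "ICC(2,1)")
    expect_equal(r$estimate, 1)
    expect_true(r$lower <= 1 && r$upper >= 1 - 1e-12)
})

test_that("additive rater offsets: consistency 1, agreement below 1", {
    s <- c(4, 8, 15, 16, 23, 42)
    offs <- c(0, 2, 5, 9)
    x <- outer(s, rep(1, 4)) + outer(rep(1, 6), offs)
    i31 <- iccEstimate(x, "ICC(3,1)")
    i21 <- iccEstimate(x, "ICC(2,1)")
    expect_equal(i31$estimate, 1)
    expect_lt(i21$estimate, 1)
    # agreement decreases as the offsets grow
    x2 <- outer(s, rep(1, 4)) + outer(rep(1, 6), offs * 3)
    expect_lt(iccEstimate(x2, "ICC(2,1)")$estimate, i21$estimate)
})

test_that("ICC is invariant to adding a common constant", {
    set.seed(8)
    x <- matrix(rnorm(30), 6, 5)
    for (m in c("ICC(2,1)", "ICC(3,1)"))
        expect_equal(iccEstimate(x + 100, m)$estimate,
                     iccEstimate(x, m)$estimate, tolerance = 1e-9)
})

test_that("a perfectly constant matrix is perfectly stable", {
    r <- iccEstimate(matrix(5, 4, 3))
    expect_equal(r$estimate, 1)
    expect_equal(c(r$lower, r$upper), c(1, 1))
    expect_error(iccEstimate(matrix(1, 1, 3)), "at least 2")
})

test_that("confidence intervals bracket the estimate", {
    set.seed(12)
    for (case in 1:10) {
        x <- matrix(rnorm(40, 5), 10, 4) + outer(rnorm(10, 0, 3), rep(1, 4))
        for (m in c("ICC(2,1)", "ICC(3,1)")) {
            r <- iccEstimate(x, m)
            expect_lte(r$lower, r$estimate)
            expect_gte(r$upper, r$estimate)
        }
    }
})

test_that("patient ranking is ascending with fractional ties", {
    expect_equal(rankPatients(c(0.2, 0.5, 0.9)), c(1, 2, 3))
    expect_equal(rankPatients(c(0.2, 0.5, 0.5, 0.9)), c(1, 2.5, 2.5, 4))
    expect_equal(rankPatients(c(0.9, 0.5, 0.2)), c(3, 2, 1))
    expect_error(rankPatients(c(NA_real_, NA_real_)), "missing")
})

test_that("Spearman rho against the reference matches the base oracle", {
    set.seed(40)
    ladder <- c(1.5, 1.8, 2.0, 2.2, 2.5, 2.7)
    tab <- do.call(rbind, lapply(ladder, function(v)
        data.frame(patient = sprintf("P%02d", 1:10), voxel_size_mm = v,
                   interpolator = "trilinear", feature = "f",
                   value = rnorm(10), stringsAsFactors = FALSE)))
    sp <- spearmanVsReference(tab, "f")
    ref <- tab$value[tab$voxel_size_mm == 2.7]
    for (v in setdiff(ladder, 2.7)) {
        x <- tab$value[tab$voxel_size_mm == v]
        expect_equal(unname(sp$rho[as.character(v)]),
                     cor(x, ref, method = "spearman"), tolerance = 1e-12)
    }
    expect_equal(sp$rhoMean, mean(sp$rho))
})

test_that("order-preserving and order-reversing sizes give rho 1 and -1", {
    base <- c(5, 1, 3, 2, 4)
    tab <- rbind(
        data.frame(patient = sprintf("P%d", 1:5), voxel_size_mm = 2.7,
                   interpolator = "trilinear", feature = "f", value = base),
        data.frame(patient = sprintf("P%d", 1:5), voxel_size_mm = 2.0,
                   interpolator = "trilinear", feature = "f",
                   value = base * 10),
        data.frame(patient = sprintf("P%d", 1:5), voxel_size_mm = 1.5,
                   interpolator = "trilinear", feature = "f", value = -base))
    sp <- spearmanVsReference(tab, "f")
    expect_equal(unname(sp$rho[as.character(2.0)]), 1)
    expect_equal(unname(sp$rho[as.character(1.5)]), -1)
})

test_that("categorisation reproduces the four-quadrant flow chart", {
    expect_equal(categoriseRobustness(0.95, 0.97), "R")
    expect_equal(categoriseRobustness(0.95, 0.90), "LR")
    expect_equal(categoriseRobustness(0.70, 0.97), "C")
    expect_equal(categoriseRobustness(0.70, 0.90), "NR")
    # strict boundaries: exactly at threshold fails
    expect_equal(categoriseRobustness(0.90, 0.97), "C")
    expect_equal(categoriseRobustness(0.95, 0.95), "LR")
    expect_equal(categoriseRobustness(0.90, 0.95), "NR")
    # truth-table sweep against an independent quadrant oracle
    for (icc in c(0.5, 0.89, 0.9, 0.91, 0.99))
        for (rho in c(0.5, 0.94, 0.95, 0.96, 0.99)) {
            truth <- if (icc > 0.9 && rho > 0.95) "R"
                     else if (icc > 0.9) "LR"
                     else if (rho > 0.95) "C" else "NR"
            expect_equal(categoriseRobustness(icc, rho), truth)
        }
    # validation mode collapses C into NR
    expect_equal(categoriseRobustness(0.7, 0.97, allowCorrectable = FALSE),
                 "NR")
})

test_that("Bland-Altman percentage differences follow the formula", {
    ba0 <- blandAltmanPct(c(1, 2, 3), c(1, 2, 3))
    expect_equal(ba0$differences, c(0, 0, 0))
    expect_equal(ba0$loa, c(0, 0))
    ba <- blandAltmanPct(2, 1)
    expect_equal(ba$differences, 100 * 1 / 1.5)
    a <- c(3, 5, 8, 2)
    b <- c(2.5, 5.5, 7, 2.2)
    expect_equal(blandAltmanPct(a, b)$differences,
                 -blandAltmanPct(b, a)$differences)
    expect_warning(bz <- blandAltmanPct(c(1, 1), c(-1, 2)), "zero average")
    expect_equal(length(bz$differences), 1L)
})

test_that("features are ordered by descending IQR with alphabetical ties", {
    ba <- list(f1 = list(iqr = 10), f2 = list(iqr = 40), f3 = list(iqr = 10))
    expect_equal(iqrOrder(ba), c("f2", "f1", "f3"))
    allz <- list(b = list(iqr = 0), a = list(iqr = 0))
    expect_equal(iqrOrder(allz), c("a", "b"))
    set.seed(6)
    rnd <- setNames(lapply(1:8, function(i) list(iqr = runif(1))),
                    paste0("f", 1:8))
    expect_equal(iqrOrder(rnd),
                 names(rnd)[order(-vapply(rnd, `[[`, 1, "iqr"),
                                  names(rnd))])
})

test_that("the robustness report is recomputable from its stored values", {
    dt <- generateDriftedFeatureTable(30, driftSpec(), seed = 17)
    rep <- robustnessReport(dt$table)
    expect_equal(rep$category,
                 mapply(categoriseRobustness, rep$icc21, rep$rho_mean))
    expect_true(all(rep$icc21_lo <= rep$icc21 & rep$icc21 <= rep$icc21_hi))
})
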