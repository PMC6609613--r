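test_that("cohort splitting honours the fraction, determinism and disjointness", {
    ids <- sprintf("P%03d", 1:441)
    s <- splitCohort(ids, 0.8, seed = 5)
    expect_length(s$testing, 353L)
    expect_length(s$validation, 88L)
    expect_length(intersect(s$testing, s$validation), 0L)
    expect_setequal(c(s$testing, s$validation), ids)
    expect_identical(splitCohort(ids, 0.8, seed = 5), s)
    expect_false(identical(splitCohort(ids, 0.8, seed = 6)$testing,
                           s$testing))
    s10 <- splitCohort(sprintf("P%d", 1:10), 0.8, seed = 1)
    expect_length(s10$testing, 8L)
    expect_length(s10$validation, 2L)
    expect_error(splitCohort(c("a", "b"), 0.01, seed = 1), "empty")
})

test_that("percentage change uses the exact-inversion orientation", {
    dt <- generateDriftedFeatureTable(20, driftSpec(coef = 0.3, sigma = 0),
                                      seed = 2)
    sc <- pctChangeTable(dt$table, "synthetic-drifted")
    # f(p, 1.5) = 1.36 f(p, 2.7) so d = (1.36 - 1)/1.36
    expect_equal(unique(round(sc$change[sc$voxel_size_mm == 1.5], 10)),
                 round(0.36 / 1.36, 10))
    expect_true(all(sc$change[sc$voxel_size_mm == 2.7] == 0))
    # literal orientation divides by the reference value instead
    scr <- pctChangeTable(dt$table, "synthetic-drifted",
                          orientation = "reference")
    expect_equal(unique(round(scr$change[scr$voxel_size_mm == 1.5], 10)), 0.36)

    const <- generateDriftedFeatureTable(15, driftSpec(coef = 0, sigma = 0),
                                         seed = 3)
    expect_true(all(pctChangeTable(const$table, "synthetic-drifted")$change == 0))
})

test_that("a null scatter fits the zero surface", {
    dt <- generateDriftedFeatureTable(30, driftSpec(coef = 0, sigma = 0),
                                      seed = 4)
    m <- fitSurface(pctChangeTable(dt$table, "synthetic-drifted"),
                    "synthetic-drifted")
    expect_lt(m@residualRMS, 1e-9)
    grid <- expand.grid(f = seq(min(m@valueRange), max(m@valueRange),
                                length.out = 7),
                        v = c(1.5, 2.0, 2.7))
    expect_lt(max(abs(evaluateSurface(m, grid$f, grid$v))), 1e-9)
})

test_that("a value-independent rational drift is recovered within 1e-3", {
    dt <- generateDriftedFeatureTable(60, driftSpec(coef = 0.3, sigma = 0),
                                      seed = 6)
    m <- fitSurface(pctChangeTable(dt$table, "synthetic-drifted"),
                    "synthetic-drifted")
    ladder <- c(1.5, 1.8, 2.0, 2.2, 2.5, 2.7)
    # closed form: in the exact-inversion orientation,
    # d(v) = alpha u / (1 + alpha u), u = 2.7 - v, alpha = 0.3
    u <- 2.7 - ladder
    target <- 0.3 * u / (1 + 0.3 * u)
    f <- median(dt$table$value)
    expect_lt(max(abs(evaluateSurface(m, rep(f, 6), ladder) - target)), 1e-3)
    # surface is monotone in voxel size where the injected drift is
    vv <- seq(1.5, 2.7, by = 0.05)
    sm <- evaluateSurface(m, rep(f, length(vv)), vv)
    expect_true(all(diff(sm) < 1e-6))
})

test_that("noisy fits keep the residual near the injected noise level", {
    dt <- generateDriftedFeatureTable(200, driftSpec(coef = 0.3, sigma = 0.01),
                                      seed = 8)
    m <- fitSurface(pctChangeTable(dt$table, "synthetic-drifted"),
                    "synthetic-drifted")
    # d carries noise from both the current and the reference value,
    # so its RMS stays below twice the injected 1% level
    expect_lt(m@residualRMS, 0.02)
})

test_that("Eq.-style correction inverts a noiseless drift exactly", {
    dt <- generateDriftedFeatureTable(60, driftSpec(coef = 1 / 3, sigma = 0),
                                      seed = 9)
    m <- fitSurface(pctChangeTable(dt$table, "synthetic-drifted"),
                    "synthetic-drifted")
    corr <- applyCorrection(m, dt$table)
    expect_equal(unique(corr$feature), "synthetic-drifted-Surface-norm")
    rel <- abs(corr$value - dt$baselines[corr$patient]) /
        dt$baselines[corr$patient]
    expect_lt(max(rel), 1e-3)
})

test_that("the identity surface leaves values unchanged and zeros stay zero", {
    dt <- generateDriftedFeatureTable(30, driftSpec(coef = 0, sigma = 0),
                                      seed = 10)
    m <- fitSurface(pctChangeTable(dt$table, "synthetic-drifted"),
                    "synthetic-drifted")
    tab <- dt$table
    tab$value[1] <- 0
    corr <- applyCorrection(m, tab)
    expect_equal(corr$value[-1], tab$value[-1], tolerance = 1e-9)
    expect_equal(corr$value[1], 0)
})

test_that("fitted surfaces are a pure function of the testing split", {
    dt <- generateDriftedFeatureTable(100, driftSpec(sigma = 0.01), seed = 12)
    split <- splitCohort(unique(dt$table$patient), 0.8, seed = 12)
    testTab <- dt$table[dt$table$patient %in% split$testing, ]
    valTab <- dt$table[dt$table$patient %in% split$validation, ]
    m1 <- fitSurface(pctChangeTable(testTab, "synthetic-drifted"),
                     "synthetic-drifted")
    # permute validation patients; the fit must not change
    valPerm <- valTab
    valPerm$value <- valTab$value[sample(nrow(valTab))]
    m2 <- fitSurface(pctChangeTable(testTab, "synthetic-drifted"),
                     "synthetic-drifted")
    expect_identical(m1@coefficients, m2@coefficients)
})

test_that("surface models survive a JSON round-trip", {
    dt <- generateDriftedFeatureTable(40, driftSpec(sigma = 0.01), seed = 13)
    m <- fitSurface(pctChangeTable(dt$table, "synthetic-drifted"),
                    "synthetic-drifted")
    f <- withr::local_tempfile(fileext = ".json")
    writeSurfaceModels(list(m), f)
    back <- readSurfaceModels(f)[[1]]
    expect_equal(back@coefficients, m@coefficients)
    expect_equal(back@valueRange, m@valueRange)
    grid <- expand.grid(f = exp(seq(log(50), log(200), length.out = 5)),
                        v = c(1.5, 2.2, 2.7))
    expect_equal(evaluateSurface(back, grid$f, grid$v),
                 evaluateSurface(m, grid$f, grid$v), tolerance = 1e-12)
})

test_that("recoverable drift goes C -> R; patient-specific drift ends NR", {
    dt <- generateDriftedFeatureTable(200, driftSpec(sigma = 0.02), seed = 14)
    split <- splitCohort(unique(dt$table$patient), 0.8, seed = 14)
    testTab <- dt$table[dt$table$patient %in% split$testing, ]
    valTab <- dt$table[dt$table$patient %in% split$validation, ]
    repT <- robustnessReport(testTab)
    expect_equal(repT$category, "C")
    m <- fitSurface(pctChangeTable(testTab, "synthetic-drifted"),
                    "synthetic-drifted")
    vc <- validateCorrection(list(m), valTab)
    expect_equal(vc$category_after, "R")
    expect_gt(vc$icc21_after, 0.9)

    # hidden per-patient drift factor: no (value, voxel size) surface can
    # generalise, the corrected feature stays below the ICC threshold
    dtn <- generateDriftedFeatureTable(200,
                                       driftSpec(sigma = 0.02,
                                                 patientSpread = 1.2),
                                       seed = 15)
    tstn <- dtn$table[dtn$table$patient %in% split$testing, ]
    valn <- dtn$table[dtn$table$patient %in% split$validation, ]
    mn <- fitSurface(pctChangeTable(tstn, "synthetic-drifted"),
                     "synthetic-drifted")
    vcn <- validateCorrection(list(mn), valn)
    expect_equal(vcn$category_after, "NR")
    expect_lt(vcn$icc21_after, 0.9)

    # drift-free feature: R before and after
    dt0 <- generateDriftedFeatureTable(200, driftSpec(coef = 0, sigma = 0.01),
                                       seed = 16)
    tst0 <- dt0$table[dt0$table$patient %in% split$testing, ]
    val0 <- dt0$table[dt0$table$patient %in% split$validation, ]
    m0 <- fitSurface(pctChangeTable(tst0, "synthetic-drifted"),
                     "synthetic-drifted")
    vc0 <- validateCorrection(list(m0), val0)
    expect_equal(vc0$category_before, "R")
    expect_equal(vc0$category_after, "R")
})
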