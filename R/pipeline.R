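#' Study configuration
#'
#' Collects every tunable of the full pipeline run.  All randomness flows
#' from \code{seed}: the cohort split uses it directly.
#'
#' @param ladder isotropic voxel sizes (mm); must contain \code{reference}.
#' @param reference reference ("ground truth") voxel size in mm.
#' @param interpolators scan interpolators to run (masks always use
#'   trilinear).
#' @param binWidth fixed bin width (SUV) for discretisation.
#' @param lowerBound discretisation lower bound (SUV).
#' @param thresholds numeric(2): ICC(2,1) and rho_mean categorisation
#'   thresholds.
#' @param splitFraction testing-split fraction.
#' @param seed master integer seed.
#' @param outDir optional output directory for CSV/JSON artefacts.
#' @return list of class "StudyConfig".
#' @export
studyConfig <- function(ladder = voxelLadder(),
                        reference = referenceVoxelSize(),
                        interpolators = c("trilinear", "spline"),
                        binWidth = 0.5, lowerBound = 0,
                        thresholds = c(0.9, 0.95),
                        splitFraction = 0.8, seed = 1L,
                        outDir = NULL) {
    if (!any(abs(ladder - reference) < 1e-9))
        stop("voxel ladder must contain the reference size")
    if (any(thresholds <= 0) || any(thresholds >= 1))
        stop("thresholds must lie in (0, 1)")
    stopifnot(all(interpolators %in% c("trilinear", "spline")),
              binWidth > 0)
    out <- list(ladder = sort(ladder), reference = reference,
                interpolators = interpolators, binWidth = binWidth,
                lowerBound = lowerBound, thresholds = thresholds,
                splitFraction = splitFraction, seed = as.integer(seed),
                outDir = outDir)
    class(out) <- "StudyConfig"
    out
}

#' Read a study configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the \code{\link{studyConfig}}
#'   arguments.
#' @return a "StudyConfig".
#' @export
readStudyConfig <- function(path) {
    y <- yaml::read_yaml(path)
    args <- y[intersect(names(y), names(formals(studyConfig)))]
    do.call(studyConfig, args)
}

#' Extract the feature table of a cohort over the voxel ladder
#'
#' One feature vector per (patient, voxel size, interpolator).  Per-VOI
#' failures (e.g. a mask that empties under resampling) degrade to missing
#' values with a message rather than aborting the run.
#'
#' @param cohort list of per-patient lists with elements id, volume, mask
#'   (as returned by \code{\link{generateCohort}}).
#' @param config a \code{\link{studyConfig}}.
#' @return a feature table data.frame.
#' @export
extractCohortTable <- function(cohort, config = studyConfig()) {
    stopifnot(length(cohort) >= 1)
    roster <- featureRoster()
    rows <- vector("list", length(cohort) * length(config$ladder) *
                       length(config$interpolators))
    idx <- 0L
    for (pat in cohort) {
        for (s in config$ladder) {
            grid <- targetGrid(pat$volume, s)
            rmask <- suppressWarnings(resampleMask(pat$mask, grid))
            for (interp in config$interpolators) {
                fv <- tryCatch({
                    rimg <- resampleImage(pat$volume, grid, interp)
                    suppressWarnings(
                        extractFeatures(rimg, rmask,
                                        binWidth = config$binWidth,
                                        lowerBound = config$lowerBound,
                                        roster = roster))
                }, error = function(e) {
                    message("VOI failed (", pat$id, ", ", s, " mm, ", interp,
                            "): ", conditionMessage(e))
                    setNames(rep(NA_real_, length(roster)), roster)
                })
                idx <- idx + 1L
                rows[[idx]] <- data.frame(patient = pat$id,
                                          voxel_size_mm = s,
                                          interpolator = interp,
                                          feature = names(fv),
                                          value = unname(fv),
                                          stringsAsFactors = FALSE)
            }
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    validateFeatureTable(out)
    out
}

#' Bland-Altman comparison of the two scan interpolators
#'
#' Per-feature percentage differences between the two interpolator arms at
#' the reference voxel size, ordered by descending interquartile range.
#' Morphology features depend only on the (always trilinearly resampled)
#' mask, so their difference is exactly zero by construction.
#'
#' @param table feature table holding both interpolator arms.
#' @param reference reference voxel size (mm).
#' @param interpolators character(2): method A and method B.
#' @return data.frame (one row per feature, descending IQR): meanDiff,
#'   loa_lo, loa_hi, shapiroW, shapiroP, iqr, n.
#' @export
compareInterpolators <- function(table, reference = referenceVoxelSize(),
                                 interpolators = c("trilinear", "spline")) {
    validateFeatureTable(table)
    df <- table[abs(table$voxel_size_mm - reference) < 1e-9, , drop = FALSE]
    a <- df[df$interpolator == interpolators[1], , drop = FALSE]
    b <- df[df$interpolator == interpolators[2], , drop = FALSE]
    if (!nrow(a) || !nrow(b))
        stop("both interpolator arms are required at the reference size")
    feats <- sort(intersect(unique(a$feature), unique(b$feature)))
    baList <- lapply(feats, function(f) {
        av <- a[a$feature == f, ]
        bv <- b[b$feature == f, ]
        pats <- intersect(av$patient, bv$patient)
        suppressWarnings(
            blandAltmanPct(av$value[match(pats, av$patient)],
                           bv$value[match(pats, bv$patient)]))
    })
    names(baList) <- feats
    ord <- iqrOrder(baList)
    out <- do.call(rbind, lapply(ord, function(f) {
        ba <- baList[[f]]
        data.frame(feature = f, meanDiff = ba$meanDiff,
                   loa_lo = ba$loa[1], loa_hi = ba$loa[2],
                   shapiroW = ba$shapiroW, shapiroP = ba$shapiroP,
                   iqr = ba$iqr, n = length(ba$differences),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

.categoryCounts <- function(report) {
    report$group <- featureGroup(report$feature)
    tab <- table(factor(report$group, c("group1", "group2")),
                 factor(report$category, c("R", "LR", "C", "NR")))
    df <- as.data.frame.matrix(tab)
    df <- cbind(group = rownames(df), df, total = rowSums(df))
    rownames(df) <- NULL
    df
}

#' Run the full interpolation-robustness study
#'
#' Cohort to feature table (all ladder sizes, both interpolators), testing
#' split categorisation, surface fits for the Potentially Correctable
#' features, before/after validation on the held-out split, and the
#' linear-vs-spline Bland-Altman comparison at the reference size.  When
#' \code{config$outDir} is set, every artefact is written there as CSV /
#' JSON together with the configuration.
#'
#' @param cohort list of per-patient lists (id, volume, mask), or an
#'   already-extracted feature table data.frame.
#' @param config a \code{\link{studyConfig}}.
#' @param fitAll fit surfaces for all features instead of only the
#'   C-category ones (research override).
#' @return list: featureTable, split, testingReport, categoryCounts,
#'   models, validation, baReport.
#' @export
runStudy <- function(cohort, config = studyConfig(), fitAll = FALSE) {
    tab <- if (is.data.frame(cohort)) {
        validateFeatureTable(cohort)
        cohort
    } else extractCohortTable(cohort, config)
    mainInterp <- config$interpolators[1]
    main <- tab[tab$interpolator == mainInterp, , drop = FALSE]
    ids <- sort(unique(main$patient))
    split <- splitCohort(ids, config$splitFraction, config$seed)
    testTab <- main[main$patient %in% split$testing, , drop = FALSE]
    valTab <- main[main$patient %in% split$validation, , drop = FALSE]
    testingReport <- robustnessReport(testTab, reference = config$reference,
                                      thresholds = config$thresholds)
    fitFeats <- if (fitAll) testingReport$feature else
        testingReport$feature[testingReport$category == "C"]
    models <- list()
    for (f in fitFeats) {
        m <- tryCatch({
            sc <- suppressWarnings(
                pctChangeTable(testTab, f, reference = config$reference))
            fitSurface(sc, feature = f, reference = config$reference)
        }, error = function(e) {
            message("surface fit failed for ", f, ": ", conditionMessage(e))
            NULL
        })
        if (!is.null(m)) models[[f]] <- m
    }
    validation <- if (length(models) && length(split$validation) >= 2)
        validateCorrection(models, valTab, reference = config$reference,
                           thresholds = config$thresholds) else NULL
    baReport <- if (length(config$interpolators) >= 2)
        compareInterpolators(tab, reference = config$reference,
                             interpolators = config$interpolators[1:2]) else
        NULL
    res <- list(featureTable = tab, split = split,
                testingReport = testingReport,
                categoryCounts = .categoryCounts(testingReport),
                models = models, validation = validation,
                baReport = baReport)
    if (!is.null(config$outDir)) .writeStudyArtefacts(res, config)
    res
}

.writeStudyArtefacts <- function(res, config) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$outDir, f)
    writeFeatureTable(res$featureTable, p("features.csv"))
    write.csv(res$testingReport, p("robustness_testing.csv"),
              row.names = FALSE)
    write.csv(res$categoryCounts, p("category_counts.csv"),
              row.names = FALSE)
    if (!is.null(res$validation))
        write.csv(res$validation, p("validation_before_after.csv"),
                  row.names = FALSE)
    if (!is.null(res$baReport))
        write.csv(res$baReport, p("ba_interpolators.csv"), row.names = FALSE)
    if (length(res$models))
        writeSurfaceModels(res$models, p("models.json"))
    cfg <- config
    cfg$outDir <- NULL
    yaml::write_yaml(c(unclass(cfg),
                       list(testing = res$split$testing,
                            validation = res$split$validation)),
                     p("run_config.yaml"))
    invisible(NULL)
}
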