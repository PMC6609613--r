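#' Randomly split a cohort into testing and validation sets
#'
#' @param ids character vector of patient ids.
#' @param fraction fraction assigned to the testing split (default 0.8).
#' @param seed integer seed; the split is reproducible.
#' @return list of class "CohortSplit" with \code{testing},
#'   \code{validation}, \code{fraction} and \code{seed}.
#' @examples
#' s <- splitCohort(sprintf("P%03d", 1:441), 0.8, seed = 7)
#' lengths(s[c("testing", "validation")])  # 353 and 88
#' @export
splitCohort <- function(ids, fraction = 0.8, seed = 1L) {
    n <- length(ids)
    stopifnot(n >= 2, fraction > 0, fraction < 1)
    nTest <- round(fraction * n)
    if (nTest == 0 || nTest == n)
        stop("fraction leaves an empty split for n = ", n)
    test <- .withSeed(seed, sort(sample(ids, nTest)))
    out <- list(testing = test, validation = sort(setdiff(ids, test)),
                fraction = fraction, seed = as.integer(seed))
    class(out) <- "CohortSplit"
    out
}

#' Relative-change scatter of a feature against the reference voxel size
#'
#' For every patient and voxel size, the fractional change of the feature
#' value relative to its reference-size value.  By default the change is
#' expressed relative to the current value, d = (f - f_ref) / f, the
#' orientation under which the surface correction
#' f_sn = f - SM(f, V_s) * f inverts a fitted drift exactly;
#' \code{orientation = "reference"} gives the literal
#' (f - f_ref) / f_ref.  Patients with a zero denominator are excluded
#' with a warning.
#'
#' @param table a feature table.
#' @param feature feature name.
#' @param reference reference voxel size (mm).
#' @param orientation "current" (default) or "reference".
#' @param interpolator optional interpolator filter.
#' @return data.frame with columns patient, voxel_size_mm, value (current
#'   feature value f) and change (d).
#' @export
pctChangeTable <- function(table, feature,
                           reference = referenceVoxelSize(),
                           orientation = c("current", "reference"),
                           interpolator = NULL) {
    orientation <- match.arg(orientation)
    df <- table[table$feature == feature, , drop = FALSE]
    if (!is.null(interpolator))
        df <- df[df$interpolator == interpolator, , drop = FALSE]
    if (length(unique(df$interpolator)) > 1)
        stop("several interpolators present; pass `interpolator`")
    refRows <- df[abs(df$voxel_size_mm - reference) < 1e-9, , drop = FALSE]
    if (!nrow(refRows)) stop("no reference-size values for ", feature)
    fref <- setNames(refRows$value, refRows$patient)
    f <- df$value
    fr <- fref[df$patient]
    den <- if (orientation == "current") f else fr
    bad <- !is.finite(f) | !is.finite(fr) | den == 0
    if (any(bad))
        warning(sum(bad), " point(s) dropped (missing value or zero ",
                "denominator) for ", feature)
    data.frame(patient = df$patient[!bad],
               voxel_size_mm = df$voxel_size_mm[!bad],
               value = f[!bad],
               change = (f[!bad] - fr[!bad]) / den[!bad],
               stringsAsFactors = FALSE)
}

.surfaceDesign <- function(u, v, degU, degV) {
    cols <- list(rep(1, length(u)))
    nm <- "1"
    for (a in 0:degU) for (b in 0:degV) {
        if (a == 0 && b == 0) next
        cols <- c(cols, list(u^a * v^b))
        nm <- c(nm, paste0("u", a, "v", b))
    }
    m <- do.call(cbind, cols)
    colnames(m) <- nm
    m
}

#' Fit a drift surface for one feature
#'
#' Least-squares fit of the fractional change d as a bivariate polynomial
#' in (standardised feature value, voxel size) over a
#' \code{\link{pctChangeTable}} scatter.  The reference-size points
#' (d = 0) are part of the scatter, anchoring the surface near 0 at the
#' reference.  When all training values are positive and span more than a
#' decade, the value axis is log-transformed before standardisation.
#'
#' @param scatter a \code{\link{pctChangeTable}} result.
#' @param feature feature name stored in the model.
#' @param degreeValue polynomial degree in the value axis.
#' @param degreeVoxel polynomial degree in the voxel-size axis.
#' @param logValue TRUE / FALSE / "auto".
#' @param reference reference voxel size (mm).
#' @return A \linkS4class{SurfaceModel}.
#' @export
fitSurface <- function(scatter, feature = "feature",
                       degreeValue = 2L, degreeVoxel = 3L,
                       logValue = "auto",
                       reference = referenceVoxelSize()) {
    stopifnot(nrow(scatter) >= 10,
              length(unique(scatter$voxel_size_mm)) >= 2)
    f <- scatter$value
    v <- scatter$voxel_size_mm
    d <- scatter$change
    if (identical(logValue, "auto"))
        logValue <- all(f > 0) && max(f) / max(min(f), .Machine$double.xmin) > 10
    logValue <- isTRUE(logValue)
    t <- if (logValue) log(f) else f
    ctr <- mean(t)
    scl <- sd(t)
    if (!is.finite(scl) || scl == 0) scl <- 1
    u <- (t - ctr) / scl
    X <- .surfaceDesign(u, v, degreeValue, degreeVoxel)
    fit <- lm.fit(X, d)
    if (any(is.na(fit$coefficients)))
        stop("rank-deficient surface design; lower degreeValue/degreeVoxel")
    new("SurfaceModel", feature = feature,
        coefficients = setNames(fit$coefficients, colnames(X)),
        degreeValue = as.integer(degreeValue),
        degreeVoxel = as.integer(degreeVoxel),
        logValue = logValue, valueCenter = ctr, valueScale = scl,
        valueRange = range(f), voxelRange = range(v),
        reference = reference, nTrain = nrow(scatter),
        residualRMS = sqrt(mean(fit$residuals^2)))
}

#' Evaluate a fitted drift surface
#'
#' Inputs outside the stored training domain are clamped to the domain
#' boundary.
#'
#' @param model a \linkS4class{SurfaceModel}.
#' @param f numeric feature values.
#' @param v numeric voxel sizes (mm).
#' @return fitted fractional change SM(f, v).
#' @export
evaluateSurface <- function(model, f, v) {
    f <- pmin(pmax(f, model@valueRange[1]), model@valueRange[2])
    v <- pmin(pmax(v, model@voxelRange[1]), model@voxelRange[2])
    t <- if (model@logValue) log(f) else f
    u <- (t - model@valueCenter) / model@valueScale
    X <- .surfaceDesign(u, v, model@degreeValue, model@degreeVoxel)
    as.numeric(X %*% model@coefficients)
}

#' Apply surface correction to a feature table
#'
#' Rescales each value with f_sn = f - SM(f, V_s) * f and emits the
#' corrected feature under the original name plus the suffix
#' \code{-Surface-norm}.  Values of exactly 0 stay 0; out-of-domain inputs
#' are clamped by \code{\link{evaluateSurface}}.
#'
#' @param models a \linkS4class{SurfaceModel} or list of them.
#' @param table a feature table containing the model features.
#' @return feature table of the corrected rows only.
#' @export
applyCorrection <- function(models, table) {
    if (is(models, "SurfaceModel")) models <- list(models)
    validateFeatureTable(table)
    out <- lapply(models, function(m) {
        df <- table[table$feature == m@feature, , drop = FALSE]
        if (!nrow(df)) stop("feature absent from table: ", m@feature)
        sm <- evaluateSurface(m, df$value, df$voxel_size_mm)
        df$value <- df$value - sm * df$value
        df$feature <- paste0(m@feature, "-Surface-norm")
        df
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Validate surface corrections on a held-out cohort
#'
#' Categorises each model's feature on the validation table before and
#' after correction.  Corrected features can no longer be Potentially
#' Correctable: below the ICC threshold they are Not Robust.
#'
#' @param models list of \linkS4class{SurfaceModel}s (trained on the
#'   testing split only).
#' @param table validation-split feature table.
#' @param reference reference voxel size (mm).
#' @param thresholds ICC and rho categorisation thresholds.
#' @return data.frame with one row per feature: ICC(2,1), rho_mean and
#'   category before and after correction.
#' @export
validateCorrection <- function(models, table,
                               reference = referenceVoxelSize(),
                               thresholds = c(0.9, 0.95)) {
    if (is(models, "SurfaceModel")) models <- list(models)
    stopifnot(length(models) >= 1)
    feats <- vapply(models, function(m) m@feature, character(1))
    base <- table[table$feature %in% feats, , drop = FALSE]
    if (!nrow(base)) stop("validation table holds none of the model features")
    before <- robustnessReport(base, reference = reference,
                               thresholds = thresholds,
                               allowCorrectable = TRUE)
    corrected <- applyCorrection(models, base)
    after <- robustnessReport(corrected, reference = reference,
                              thresholds = thresholds,
                              allowCorrectable = FALSE)
    after$feature <- sub("-Surface-norm$", "", after$feature)
    merged <- merge(before[, c("feature", "icc21", "rho_mean", "category")],
                    after[, c("feature", "icc21", "rho_mean", "category")],
                    by = "feature", suffixes = c("_before", "_after"))
    merged[order(merged$feature), ]
}

#' Read / write surface models as JSON
#'
#' Serialises the full model state (family, degrees, coefficients, value
#' transform, domain, reference) so corrections are reproducible from the
#' file alone.
#'
#' @param models list of \linkS4class{SurfaceModel}s.
#' @param path JSON file path.
#' @return \code{readSurfaceModels} returns a list of models;
#'   \code{writeSurfaceModels} returns \code{path} invisibly.
#' @export
writeSurfaceModels <- function(models, path) {
    if (is(models, "SurfaceModel")) models <- list(models)
    enc <- lapply(models, function(m) list(
        feature = m@feature, family = "polynomial",
        degreeValue = m@degreeValue, degreeVoxel = m@degreeVoxel,
        logValue = m@logValue,
        coefficients = as.list(m@coefficients),
        valueCenter = m@valueCenter, valueScale = m@valueScale,
        valueRange = m@valueRange, voxelRange = m@voxelRange,
        reference = m@reference, nTrain = m@nTrain,
        residualRMS = m@residualRMS))
    jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeSurfaceModels
#' @export
readSurfaceModels <- function(path) {
    enc <- jsonlite::read_json(path, simplifyVector = FALSE)
    lapply(enc, function(e) new("SurfaceModel",
        feature = e$feature,
        coefficients = unlist(e$coefficients),
        degreeValue = as.integer(e$degreeValue),
        degreeVoxel = as.integer(e$degreeVoxel),
        logValue = as.logical(e$logValue),
        valueCenter = as.numeric(e$valueCenter),
        valueScale = as.numeric(e$valueScale),
        valueRange = as.numeric(unlist(e$valueRange)),
        voxelRange = as.numeric(unlist(e$voxelRange)),
        reference = as.numeric(e$reference),
        nTrain = as.integer(e$nTrain),
        residualRMS = as.numeric(e$residualRMS)))
}
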