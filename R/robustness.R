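#' Intraclass correlation for feature stability across voxel sizes
#'
#' Treats each voxel size as a rater and each patient as a subject and
#' computes single-rater two-way ICCs from the two-way ANOVA mean squares:
#' absolute agreement ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE +
#' k/n (MSC - MSE)) and consistency ICC(3,1) = (MSR - MSE) /
#' (MSR + (k-1) MSE), with 95\% confidence intervals from the F-based
#' formulas of McGraw & Wong (1996).  Rows containing missing values are
#' dropped.  A matrix with zero total variance (a perfectly constant
#' feature) is perfectly stable by definition: estimate 1 with degenerate
#' CI [1, 1].
#'
#' @param x numeric matrix, subjects (patients) x raters (voxel sizes).
#' @param model "ICC(2,1)" (absolute agreement, default) or "ICC(3,1)"
#'   (consistency).
#' @param conf confidence level for the interval.
#' @return list with estimate, lower, upper, model, and the mean squares
#'   (MSR, MSC, MSE) with n and k.
#' @export
iccEstimate <- function(x, model = c("ICC(2,1)", "ICC(3,1)"), conf = 0.95) {
    model <- match.arg(model)
    x <- as.matrix(x)
    x <- x[complete.cases(x), , drop = FALSE]
    n <- nrow(x)
    k <- ncol(x)
    if (n < 2 || k < 2)
        stop("need at least 2 subjects and 2 raters after dropping ",
             "incomplete rows")
    gm <- mean(x)
    if (all(abs(x - gm) < 1e-12 * max(1, abs(gm))))
        return(list(estimate = 1, lower = 1, upper = 1, model = model,
                    MSR = 0, MSC = 0, MSE = 0, n = n, k = k))
    ri <- rowMeans(x)
    cj <- colMeans(x)
    SSR <- k * sum((ri - gm)^2)
    SSC <- n * sum((cj - gm)^2)
    SST <- sum((x - gm)^2)
    SSE <- max(0, SST - SSR - SSC)
    MSR <- SSR / (n - 1)
    MSC <- SSC / (k - 1)
    MSE <- SSE / ((n - 1) * (k - 1))
    alpha <- 1 - conf
    if (model == "ICC(3,1)") {
        den <- MSR + (k - 1) * MSE
        est <- if (den > 0) (MSR - MSE) / den else 1
        if (MSE <= 0) {
            lo <- up <- 1
        } else {
            Fo <- MSR / MSE
            FL <- Fo / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
            FU <- Fo * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
            lo <- (FL - 1) / (FL + k - 1)
            up <- (FU - 1) / (FU + k - 1)
        }
    } else {
        den <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
        est <- if (den > 0) (MSR - MSE) / den else 1
        a <- (k * est) / (n * (1 - est))
        b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
        if (!is.finite(a) || !is.finite(b) || (a * MSC + b * MSE) <= 0) {
            lo <- up <- est
        } else {
            v <- (a * MSC + b * MSE)^2 /
                ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
            FL <- qf(1 - alpha / 2, n - 1, v)
            FU <- qf(1 - alpha / 2, v, n - 1)
            lo <- n * (MSR - FL * MSE) /
                (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
            up <- n * (FU * MSR - MSE) /
                (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
        }
    }
    list(estimate = est, lower = min(lo, est), upper = max(up, est),
         model = model, MSR = MSR, MSC = MSC, MSE = MSE, n = n, k = k)
}

#' Rank patients by feature value
#'
#' The patient with the lowest value gets rank 1, the second lowest rank 2,
#' and so on; equal values share the same (fractional / mid) rank, the
#' standard tie treatment for Spearman correlation.
#'
#' @param values numeric vector of per-patient feature values.
#' @return numeric vector of ranks (NA where the value is missing).
#' @export
rankPatients <- function(values) {
    if (all(is.na(values))) stop("all values missing: cannot rank")
    rank(values, ties.method = "average", na.last = "keep")
}

#' Spearman rank correlation against the reference voxel size
#'
#' For each non-reference voxel size, correlates the patient ranking with
#' the ranking at the reference size (Pearson correlation of tie-adjusted
#' ranks).  Patients missing either value are dropped pairwise.  A constant
#' vector makes the pair's correlation undefined; it is excluded from the
#' mean with a warning.
#'
#' @param table a feature table (see \code{\link{featureTable}}).
#' @param feature feature name to analyse.
#' @param reference reference voxel size in mm.
#' @param interpolator optional interpolator tag to filter on; required when
#'   the table holds several.
#' @return list with \code{rho} (named by voxel size) and \code{rhoMean}.
#' @export
spearmanVsReference <- function(table, feature,
                                reference = referenceVoxelSize(),
                                interpolator = NULL) {
    df <- table[table$feature == feature, , drop = FALSE]
    if (!is.null(interpolator))
        df <- df[df$interpolator == interpolator, , drop = FALSE]
    if (length(unique(df$interpolator)) > 1)
        stop("several interpolators present; pass `interpolator`")
    sizes <- sort(unique(df$voxel_size_mm))
    if (!any(abs(sizes - reference) < 1e-9))
        stop("reference voxel size absent for feature ", feature)
    others <- sizes[abs(sizes - reference) >= 1e-9]
    if (!length(others)) stop("need at least one non-reference voxel size")
    wide <- .wideValues(df, sizes)
    ref <- wide[, which(abs(sizes - reference) < 1e-9)]
    rho <- vapply(others, function(s) {
        v <- wide[, which(abs(sizes - s) < 1e-9)]
        ok <- !is.na(v) & !is.na(ref)
        if (sum(ok) < 3) return(NA_real_)
        rv <- rankPatients(v[ok])
        rr <- rankPatients(ref[ok])
        if (sd(rv) == 0 || sd(rr) == 0) return(NA_real_)
        cor(rv, rr)
    }, numeric(1))
    names(rho) <- as.character(others)
    if (anyNA(rho))
        warning("rank correlation undefined (constant or short vector) for ",
                sum(is.na(rho)), " voxel size(s); excluded from the mean")
    list(rho = rho, rhoMean = mean(rho, na.rm = TRUE))
}

# patients x voxel-sizes value matrix for one feature
.wideValues <- function(df, sizes) {
    pats <- sort(unique(df$patient))
    wide <- matrix(NA_real_, length(pats), length(sizes),
                   dimnames = list(pats, as.character(sizes)))
    pi <- match(df$patient, pats)
    si <- vapply(df$voxel_size_mm,
                 function(v) which(abs(sizes - v) < 1e-9)[1], integer(1))
    wide[cbind(pi, si)] <- df$value
    wide
}

#' Categorise a feature's interpolation response
#'
#' Combines the two stability tests with strict thresholds: ICC(2,1) > 0.9
#' and rho_mean > 0.95 gives Robust (R); ICC only, Limited Robustness (LR);
#' rho only, Potentially Correctable (C); neither, Not Robust (NR).  For
#' validation of corrected features C is not an allowed outcome and falls
#' through to NR.
#'
#' @param icc21 ICC(2,1) estimate.
#' @param rhoMean mean pairwise Spearman rho against the reference size.
#' @param thresholds numeric(2): the ICC and rho thresholds.
#' @param allowCorrectable logical; FALSE restricts the outcome to
#'   \{R, LR, NR\}.
#' @return one of "R", "LR", "C", "NR".
#' @export
categoriseRobustness <- function(icc21, rhoMean, thresholds = c(0.9, 0.95),
                                 allowCorrectable = TRUE) {
    stopifnot(is.finite(icc21))
    iccPass <- icc21 > thresholds[1]
    # an undefined rho_mean (all pairs degenerate) cannot demonstrate
    # ranking consistency, so the rho test fails
    rhoPass <- is.finite(rhoMean) && rhoMean > thresholds[2]
    if (iccPass && rhoPass) return("R")
    if (iccPass) return("LR")
    if (rhoPass && allowCorrectable) return("C")
    "NR"
}

#' Bland-Altman percentage comparison of two methods
#'
#' Per-patient percentage difference d = 100 (a - b) / ((a + b) / 2), with
#' mean difference, 1.96 SD limits of agreement, a Shapiro-Wilk normality
#' test and the interquartile range of the differences.  Pairs whose
#' average is 0 are excluded with a warning.
#'
#' @param a,b paired per-patient values for methods A and B.
#' @return list with differences, meanDiff, sdDiff, loa (length 2),
#'   shapiroW, shapiroP, iqr and nExcluded.
#' @export
blandAltmanPct <- function(a, b) {
    stopifnot(length(a) == length(b))
    ok <- is.finite(a) & is.finite(b)
    a <- a[ok]; b <- b[ok]
    avg <- (a + b) / 2
    zero <- avg == 0
    if (any(zero))
        warning(sum(zero), " pair(s) with zero average excluded")
    d <- 100 * (a[!zero] - b[!zero]) / avg[!zero]
    m <- mean(d)
    s <- if (length(d) > 1) sd(d) else 0
    sw <- if (length(d) >= 3 && length(d) <= 5000 && sd(d) > 0)
        shapiro.test(d) else NULL
    list(differences = d,
         meanDiff = m,
         sdDiff = s,
         loa = c(m - 1.96 * s, m + 1.96 * s),
         shapiroW = if (is.null(sw)) NA_real_ else unname(sw$statistic),
         shapiroP = if (is.null(sw)) NA_real_ else sw$p.value,
         iqr = if (length(d)) unname(diff(quantile(d, c(0.25, 0.75)))) else
             NA_real_,
         nExcluded = sum(zero))
}

#' Order features by Bland-Altman interquartile range
#'
#' @param baList named list of \code{\link{blandAltmanPct}} results (names
#'   are feature names).
#' @return character vector of feature names in descending IQR order, ties
#'   broken alphabetically.
#' @export
iqrOrder <- function(baList) {
    stopifnot(length(baList) >= 1)
    iqrs <- vapply(baList, function(x) x$iqr, numeric(1))
    nm <- names(baList)
    nm[order(-iqrs, nm)]
}

#' Per-feature robustness report
#'
#' For every feature in the table: ICC(2,1) and ICC(3,1) with 95\% CIs over
#' the patients x voxel-sizes matrix, pairwise Spearman rho against the
#' reference size, rho_mean, and the resulting category.
#'
#' @param table a feature table restricted to one interpolator (or pass
#'   \code{interpolator}).
#' @param reference reference voxel size in mm.
#' @param interpolator optional interpolator tag filter.
#' @param thresholds ICC and rho thresholds for categorisation.
#' @param allowCorrectable FALSE restricts categories to \{R, LR, NR\}
#'   (validation of corrected features).
#' @return data.frame with one row per feature: icc21 (+ CI), icc31 (+ CI),
#'   one rho column per non-reference size, rho_mean and category.
#' @export
robustnessReport <- function(table, reference = referenceVoxelSize(),
                             interpolator = NULL, thresholds = c(0.9, 0.95),
                             allowCorrectable = TRUE) {
    validateFeatureTable(table)
    if (!is.null(interpolator))
        table <- table[table$interpolator == interpolator, , drop = FALSE]
    if (length(unique(table$interpolator)) > 1)
        stop("several interpolators present; pass `interpolator`")
    feats <- sort(unique(table$feature))
    sizes <- sort(unique(table$voxel_size_mm))
    others <- sizes[abs(sizes - reference) >= 1e-9]
    rows <- lapply(feats, function(f) {
        df <- table[table$feature == f, , drop = FALSE]
        wide <- .wideValues(df, sizes)
        if (sum(complete.cases(wide)) < 2 || anyNA(colMeans(wide, na.rm = TRUE)))
            return(NULL)
        i21 <- iccEstimate(wide, "ICC(2,1)")
        i31 <- iccEstimate(wide, "ICC(3,1)")
        sp <- spearmanVsReference(df, f, reference = reference)
        out <- data.frame(feature = f,
                          icc21 = i21$estimate, icc21_lo = i21$lower,
                          icc21_hi = i21$upper,
                          icc31 = i31$estimate, icc31_lo = i31$lower,
                          icc31_hi = i31$upper,
                          stringsAsFactors = FALSE)
        for (s in others)
            out[[paste0("rho_", s)]] <- unname(sp$rho[as.character(s)])
        out$rho_mean <- sp$rhoMean
        out$category <- categoriseRobustness(i21$estimate, sp$rhoMean,
                                             thresholds, allowCorrectable)
        out
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) stop("no feature had enough complete data to report")
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
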