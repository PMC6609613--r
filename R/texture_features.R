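.xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

#' Texture features per family
#'
#' Compute the standardised feature set of a texture-matrix family:
#' 25 GLCM, 16 GLRLM, 16 GLSZM, 16 GLDZM and 5 NGTDM features (78 in
#' total).  Degenerate cases never yield infinities: GLCM correlation and
#' information correlation on a single-level VOI are 0, NGTDM coarseness
#' with a zero denominator is 1e6, and zero-variance moments are 0.
#'
#' @param m a \code{\link{buildGLCM}}-style "TextureMatrix".
#' @return named numeric vector of features for the family.
#' @name texture-features
NULL

#' @rdname texture-features
#' @export
glcmFeatures <- function(m) {
    stopifnot(m$family == "GLCM")
    p <- m$counts / sum(m$counts)
    ng <- nrow(p)
    i <- matrix(seq_len(ng), ng, ng)
    j <- t(i)
    pi_ <- rowSums(p)          # symmetric: row and column marginals agree
    mu <- sum(i * p)
    sig2 <- sum((i - mu)^2 * p)
    dif <- abs(i - j)
    pd <- tapply(p, dif, sum)                      # indexed 0..ng-1
    kd <- as.numeric(names(pd))
    ps <- tapply(p, i + j, sum)                    # indexed 2..2ng
    ks <- as.numeric(names(ps))
    da <- sum(kd * pd)
    sa <- sum(ks * ps)
    hxy <- -sum(.xlog2(p))
    pipj <- pi_[i] * pi_[j]
    hxy1 <- -sum(ifelse(pipj > 0, p * log2(pipj), 0))
    hxy2 <- -sum(.xlog2(pipj))
    hx <- -sum(.xlog2(pi_))
    corr <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 0
    ic1 <- if (hx > 0) (hxy - hxy1) / hx else 0
    ic2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
    offd <- dif > 0
    c("glcm3d-jointMaximum" = max(p),
      "glcm3d-jointAverage" = mu,
      "glcm3d-jointVariance" = sig2,
      "glcm3d-jointEntropy" = hxy,
      "glcm3d-differenceAverage" = da,
      "glcm3d-differenceVariance" = sum((kd - da)^2 * pd),
      "glcm3d-differenceEntropy" = -sum(.xlog2(pd)),
      "glcm3d-sumAverage" = sa,
      "glcm3d-sumVariance" = sum((ks - sa)^2 * ps),
      "glcm3d-sumEntropy" = -sum(.xlog2(ps)),
      "glcm3d-angularSecondMoment" = sum(p^2),
      "glcm3d-contrast" = sum((i - j)^2 * p),
      "glcm3d-dissimilarity" = sum(dif * p),
      "glcm3d-inverseDifference" = sum(p / (1 + dif)),
      "glcm3d-normalisedInverseDifference" = sum(p / (1 + dif / ng)),
      "glcm3d-inverseDifferenceMoment" = sum(p / (1 + dif^2)),
      "glcm3d-normalisedInverseDifferenceMoment" = sum(p / (1 + dif^2 / ng^2)),
      "glcm3d-inverseVariance" = sum(p[offd] / dif[offd]^2),
      "glcm3d-correlation" = corr,
      "glcm3d-autocorrelation" = sum(i * j * p),
      "glcm3d-clusterTendency" = sum((i + j - 2 * mu)^2 * p),
      "glcm3d-clusterShade" = sum((i + j - 2 * mu)^3 * p),
      "glcm3d-clusterProminence" = sum((i + j - 2 * mu)^4 * p),
      "glcm3d-informationCorrelation1" = ic1,
      "glcm3d-informationCorrelation2" = ic2)
}

# shared structure of the run-length-style families: counts indexed by
# (grey level i, attribute j), j weighting by run length / zone size /
# zone distance
.rlmFeatures <- function(counts, nVoxels, nTotalRef, prefix, jNames) {
    ns <- sum(counts)
    ng <- nrow(counts)
    nj <- ncol(counts)
    i <- matrix(seq_len(ng), ng, nj)
    j <- t(matrix(seq_len(nj), nj, ng))
    ri <- rowSums(counts)
    rj <- colSums(counts)
    p <- counts / ns
    mui <- sum(i * p)
    muj <- sum(j * p)
    f <- c(sum(counts / j^2) / ns,
           sum(counts * j^2) / ns,
           sum(counts / i^2) / ns,
           sum(counts * i^2) / ns,
           sum(counts / (i^2 * j^2)) / ns,
           sum(counts * i^2 / j^2) / ns,
           sum(counts * j^2 / i^2) / ns,
           sum(counts * i^2 * j^2) / ns,
           sum(ri^2) / ns,
           sum(ri^2) / ns^2,
           sum(rj^2) / ns,
           sum(rj^2) / ns^2,
           ns / nTotalRef,
           sum((i - mui)^2 * p),
           sum((j - muj)^2 * p),
           -sum(.xlog2(p)))
    names(f) <- paste0(prefix, jNames)
    f
}

#' @rdname texture-features
#' @export
glrlmFeatures <- function(m) {
    stopifnot(m$family == "GLRLM")
    .rlmFeatures(m$counts, m$nVoxels, m$nVoxels * m$nDirections, "glrl3d-",
                 c("shortRunEmphasis", "longRunEmphasis",
                   "lowGreyLevelRunEmphasis", "highGreyLevelRunEmphasis",
                   "shortRunLowGreyLevelEmphasis",
                   "shortRunHighGreyLevelEmphasis",
                   "longRunLowGreyLevelEmphasis",
                   "longRunHighGreyLevelEmphasis",
                   "gl_NonUniformity", "gl_NonUniformityNormalised",
                   "rl_NonUniformity", "rl_NonUniformityNormalised",
                   "runPercentage", "greyLevelVariance",
                   "runLengthVariance", "runEntropy"))
}

#' @rdname texture-features
#' @export
glszmFeatures <- function(m) {
    stopifnot(m$family == "GLSZM")
    .rlmFeatures(m$counts, m$nVoxels, m$nVoxels, "glszm3d-",
                 c("smallZoneEmphasis", "largeZoneEmphasis",
                   "lowGreyLevelZoneEmphasis", "highGreyLevelZoneEmphasis",
                   "smallZoneLowGreyLevelEmphasis",
                   "smallZoneHighGreyLevelEmphasis",
                   "largeZoneLowGreyLevelEmphasis",
                   "largeZoneHighGreyLevelEmphasis",
                   "gl_NonUniformity", "gl_NonUniformityNormalised",
                   "zoneSize_NonUniformity", "zoneSize_NonUniformityNormalised",
                   "zonePercentage", "greyLevelVariance",
                   "zoneSizeVariance", "zoneSizeEntropy"))
}

#' @rdname texture-features
#' @export
gldzmFeatures <- function(m) {
    stopifnot(m$family == "GLDZM")
    .rlmFeatures(m$counts, m$nVoxels, m$nVoxels, "gldzm3d-",
                 c("smallDistanceEmphasis", "largeDistanceEmphasis",
                   "lowGreyLevelZoneEmphasis", "highGreyLevelZoneEmphasis",
                   "smallDistanceLowGreyLevelEmphasis",
                   "smallDistanceHighGreyLevelEmphasis",
                   "largeDistanceLowGreyLevelEmphasis",
                   "largeDistanceHighGreyLevelEmphasis",
                   "gl_NonUniformity", "gl_NonUniformityNormalised",
                   "zoneDistance_NonUniformity",
                   "zoneDistance_NonUniformityNormalised",
                   "zonePercentage", "greyLevelVariance",
                   "zoneDistanceVariance", "zoneDistanceEntropy"))
}

#' @rdname texture-features
#' @export
ngtdmFeatures <- function(m) {
    stopifnot(m$family == "NGTDM")
    n_i <- m$counts[, "n"]
    s_i <- m$counts[, "s"]
    nvc <- sum(n_i)
    p_i <- n_i / nvc
    ng <- length(n_i)
    act <- which(p_i > 0)
    ngp <- length(act)
    i <- seq_len(ng)
    coarse_den <- sum(p_i * s_i)
    coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
    contrast <- if (ngp > 1) {
        (sum(outer(p_i[act], p_i[act]) * outer(i[act], i[act], "-")^2) /
            (ngp * (ngp - 1))) * (sum(s_i) / nvc)
    } else 0
    # double sums below run over ordered pairs of occupied levels, as the
    # standardised definitions do
    busy_den <- sum(abs(outer(i[act] * p_i[act], i[act] * p_i[act], "-")))
    busyness <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0
    cplx <- 0
    strength_num <- 0
    for (a in act) for (b in act) {
        if (a == b) next
        cplx <- cplx + abs(a - b) *
            (p_i[a] * s_i[a] + p_i[b] * s_i[b]) / (p_i[a] + p_i[b])
        strength_num <- strength_num + (p_i[a] + p_i[b]) * (a - b)^2
    }
    cplx <- cplx / nvc
    strength <- if (sum(s_i) > 0) strength_num / sum(s_i) else 0
    c("ngtdm3d-coarseness" = coarseness,
      "ngtdm3d-contrast" = contrast,
      "ngtdm3d-busyness" = busyness,
      "ngtdm3d-complexity" = cplx,
      "ngtdm3d-strength" = strength)
}
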