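.popVar <- function(x) mean((x - mean(x))^2)

.skewKurt <- function(x) {
    m2 <- .popVar(x)
    if (m2 <= 0) return(c(skew = 0, kurt = 0))
    m3 <- mean((x - mean(x))^3)
    m4 <- mean((x - mean(x))^4)
    c(skew = m3 / m2^1.5, kurt = m4 / m2^2 - 3)
}

# the common dispersion/location block shared by the intensity-statistics
# and intensity-histogram families
.distStats <- function(x) {
    q <- quantile(x, c(0.1, 0.25, 0.75, 0.9), names = FALSE, type = 7)
    sk <- .skewKurt(x)
    inner <- x[x >= q[1] & x <= q[4]]
    mu <- mean(x)
    c(mean = mu,
      variance = .popVar(x),
      skewness = sk[["skew"]],
      kurtosis = sk[["kurt"]],
      median = median(x),
      minimum = min(x),
      percentile10 = q[1],
      percentile90 = q[4],
      maximum = max(x),
      interquartileRange = q[3] - q[2],
      range = max(x) - min(x),
      meanAbsoluteDeviation = mean(abs(x - mu)),
      robustMeanAbsoluteDeviation = mean(abs(inner - mean(inner))),
      medianAbsoluteDeviation = mean(abs(x - median(x))),
      coefficientOfVariation = if (mu != 0) sqrt(.popVar(x)) / mu else 0,
      quartileCoefficientOfDispersion =
          if (q[3] + q[2] != 0) (q[3] - q[2]) / (q[3] + q[2]) else 0)
}

#' First-order intensity features
#'
#' Intensity-based statistics are computed on the raw SUV values within the
#' VOI (18 features, prefix \code{stat-}); intensity-histogram features are
#' computed on the discretised grey levels (23 features, prefix \code{ih-}).
#' Skewness and kurtosis (excess) of a constant VOI are 0, as is the
#' coefficient of variation when the mean is 0.
#'
#' @param vol an \linkS4class{ImageVolume}.
#' @param mask the paired \linkS4class{BinaryMask}.
#' @param d the \code{\link{discretiseFBS}} result for the same VOI.
#' @return named numeric vector of 41 features.
#' @export
intensityFeatures <- function(vol, mask, d) {
    inVoi <- mask@voxels == 1
    if (!any(inVoi)) stop("empty mask")
    x <- vol@voxels[inVoi]
    g <- d$levels[d$levels > 0]
    st <- .distStats(x)
    names(st) <- paste0("stat-", names(st))
    st <- c(st, "stat-energy" = sum(x^2),
            "stat-rootMeanSquare" = sqrt(mean(x^2)))
    hs <- .distStats(g)
    names(hs) <- paste0("ih-", names(hs))
    ng <- d$ng
    cnt <- tabulate(g, nbins = ng)
    p <- cnt / sum(cnt)
    mode_g <- which.max(cnt)   # lowest level on ties
    if (ng == 1L) {
        grad <- 0
        mx <- mn <- 1L
        gmax <- gmin <- 0
    } else {
        grad <- numeric(ng)
        grad[1] <- cnt[2] - cnt[1]
        grad[ng] <- cnt[ng] - cnt[ng - 1]
        if (ng > 2) grad[2:(ng - 1)] <- (cnt[3:ng] - cnt[1:(ng - 2)]) / 2
        mx <- which.max(grad)
        mn <- which.min(grad)
        gmax <- grad[mx]
        gmin <- grad[mn]
    }
    c(st, hs,
      "ih-mode" = as.numeric(mode_g),
      "ih-entropy" = -sum(.xlog2(p)),
      "ih-uniformity" = sum(p^2),
      "ih-maxHistogramGradient" = gmax,
      "ih-maxHistogramGradientLevel" = as.numeric(mx),
      "ih-minHistogramGradient" = gmin,
      "ih-minHistogramGradientLevel" = as.numeric(mn))
}
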