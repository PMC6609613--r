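.rosterGroup1 <- function() {
    c(paste0("morph-", c("volume", "approxVolume", "surfaceArea",
                         "surfaceToVolumeRatio", "compactness1",
                         "compactness2", "sphericalDisproportion",
                         "sphericity", "asphericity", "centreOfMassShift",
                         "max3dDiameter", "majorAxisLength", "minorAxisLength",
                         "leastAxisLength", "elongation", "flatness",
                         "volumeDensityAABB", "areaDensityAABB",
                         "volumeDensityAEE", "areaDensityAEE",
                         "integratedIntensity", "moranI")),
      paste0("stat-", c("mean", "variance", "skewness", "kurtosis", "median",
                        "minimum", "percentile10", "percentile90", "maximum",
                        "interquartileRange", "range", "meanAbsoluteDeviation",
                        "robustMeanAbsoluteDeviation",
                        "medianAbsoluteDeviation", "coefficientOfVariation",
                        "quartileCoefficientOfDispersion", "energy",
                        "rootMeanSquare")),
      paste0("ih-", c("mean", "variance", "skewness", "kurtosis", "median",
                      "minimum", "percentile10", "percentile90", "maximum",
                      "mode", "interquartileRange", "range",
                      "meanAbsoluteDeviation", "robustMeanAbsoluteDeviation",
                      "medianAbsoluteDeviation", "coefficientOfVariation",
                      "quartileCoefficientOfDispersion", "entropy",
                      "uniformity", "maxHistogramGradient",
                      "maxHistogramGradientLevel", "minHistogramGradient",
                      "minHistogramGradientLevel")))
}

.rosterGroup2 <- function() {
    c(paste0("glcm3d-", c("jointMaximum", "jointAverage", "jointVariance",
                          "jointEntropy", "differenceAverage",
                          "differenceVariance", "differenceEntropy",
                          "sumAverage", "sumVariance", "sumEntropy",
                          "angularSecondMoment", "contrast", "dissimilarity",
                          "inverseDifference", "normalisedInverseDifference",
                          "inverseDifferenceMoment",
                          "normalisedInverseDifferenceMoment",
                          "inverseVariance", "correlation", "autocorrelation",
                          "clusterTendency", "clusterShade",
                          "clusterProminence", "informationCorrelation1",
                          "informationCorrelation2")),
      paste0("glrl3d-", c("shortRunEmphasis", "longRunEmphasis",
                          "lowGreyLevelRunEmphasis", "highGreyLevelRunEmphasis",
                          "shortRunLowGreyLevelEmphasis",
                          "shortRunHighGreyLevelEmphasis",
                          "longRunLowGreyLevelEmphasis",
                          "longRunHighGreyLevelEmphasis",
                          "gl_NonUniformity", "gl_NonUniformityNormalised",
                          "rl_NonUniformity", "rl_NonUniformityNormalised",
                          "runPercentage", "greyLevelVariance",
                          "runLengthVariance", "runEntropy")),
      paste0("glszm3d-", c("smallZoneEmphasis", "largeZoneEmphasis",
                           "lowGreyLevelZoneEmphasis",
                           "highGreyLevelZoneEmphasis",
                           "smallZoneLowGreyLevelEmphasis",
                           "smallZoneHighGreyLevelEmphasis",
                           "largeZoneLowGreyLevelEmphasis",
                           "largeZoneHighGreyLevelEmphasis",
                           "gl_NonUniformity", "gl_NonUniformityNormalised",
                           "zoneSize_NonUniformity",
                           "zoneSize_NonUniformityNormalised",
                           "zonePercentage", "greyLevelVariance",
                           "zoneSizeVariance", "zoneSizeEntropy")),
      paste0("gldzm3d-", c("smallDistanceEmphasis", "largeDistanceEmphasis",
                           "lowGreyLevelZoneEmphasis",
                           "highGreyLevelZoneEmphasis",
                           "smallDistanceLowGreyLevelEmphasis",
                           "smallDistanceHighGreyLevelEmphasis",
                           "largeDistanceLowGreyLevelEmphasis",
                           "largeDistanceHighGreyLevelEmphasis",
                           "gl_NonUniformity", "gl_NonUniformityNormalised",
                           "zoneDistance_NonUniformity",
                           "zoneDistance_NonUniformityNormalised",
                           "zonePercentage", "greyLevelVariance",
                           "zoneDistanceVariance", "zoneDistanceEntropy")),
      paste0("ngtdm3d-", c("coarseness", "contrast", "busyness", "complexity",
                           "strength")))
}

#' The default 141-feature roster
#'
#' Group 1 holds 63 morphology / intensity-statistics / intensity-histogram
#' features; group 2 holds the 78 texture features (25 GLCM + 16 GLRLM +
#' 16 GLSZM + 16 GLDZM + 5 NGTDM).
#'
#' @param group "all" (141 names), "group1" (63) or "group2" (78).
#' @return character vector of feature names.
#' @export
featureRoster <- function(group = c("all", "group1", "group2")) {
    group <- match.arg(group)
    switch(group,
           all = c(.rosterGroup1(), .rosterGroup2()),
           group1 = .rosterGroup1(),
           group2 = .rosterGroup2())
}

#' Which roster group a feature belongs to
#'
#' @param feature character vector of feature names (the corrected-feature
#'   suffix "-Surface-norm" and "-Voxel-Norm" are stripped before lookup).
#' @return character vector: "group1", "group2" or NA.
#' @export
featureGroup <- function(feature) {
    base <- sub("(-Surface-norm|-Voxel-Norm)$", "", feature)
    ifelse(base %in% .rosterGroup1(), "group1",
           ifelse(base %in% .rosterGroup2(), "group2", NA_character_))
}

#' Voxel-number normalisation of a feature value
#'
#' Divides a feature value by the VOI voxel count, emitting the result
#' under the original name plus the suffix \code{-Voxel-Norm}.  Intended
#' for features whose magnitude scales with voxel number by construction
#' (default set: run-length non-uniformity).
#'
#' @param name feature name.
#' @param value scalar feature value.
#' @param n VOI voxel count (>= 1).
#' @return named scalar: value / n under \code{<name>-Voxel-Norm}.
#' @export
voxelNumberNormalise <- function(name, value, n) {
    if (n < 1) stop("voxel count must be >= 1")
    setNames(value / n, paste0(name, "-Voxel-Norm"))
}

#' Extract the full feature vector from one VOI
#'
#' Runs fixed-bin-size discretisation, all five texture-matrix builders and
#' the morphology/intensity feature sets, returning the configured roster
#' (141 features by default).  A degenerate VOI (empty mask) yields an
#' all-NA vector rather than an error so cohort runs are not aborted.
#'
#' @param vol an \linkS4class{ImageVolume}.
#' @param mask the paired \linkS4class{BinaryMask}.
#' @param binWidth fixed bin width in SUV.
#' @param lowerBound discretisation lower bound in SUV.
#' @param roster character vector of feature names to return (default the
#'   full 141-name roster).
#' @return named numeric vector over \code{roster}.
#' @export
extractFeatures <- function(vol, mask, binWidth = 0.5, lowerBound = 0,
                            roster = featureRoster()) {
    if (isEmptyMask(mask)) {
        warning("empty mask: returning missing feature values")
        return(setNames(rep(NA_real_, length(roster)), roster))
    }
    d <- discretiseFBS(vol, mask, binWidth = binWidth,
                       lowerBound = lowerBound)
    vals <- c(morphologyFeatures(mask, vol),
              intensityFeatures(vol, mask, d),
              glcmFeatures(buildGLCM(d)),
              glrlmFeatures(buildGLRLM(d)),
              glszmFeatures(buildGLSZM(d)),
              gldzmFeatures(buildGLDZM(d)),
              ngtdmFeatures(buildNGTDM(d)))
    missing <- setdiff(roster, names(vals))
    if (length(missing))
        stop("roster names not produced by extraction: ",
             paste(head(missing, 5), collapse = ", "))
    vals[roster]
}
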