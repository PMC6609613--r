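.ellipsoidArea <- function(a, b, c) {
    # Thomsen's approximation (p ~ 1.6075), accurate to ~1%
    p <- 1.6075
    4 * pi * ((a^p * b^p + a^p * c^p + b^p * c^p) / 3)^(1 / p)
}

# Gaussian-smooth a zero-padded copy of the occupancy grid.  Meshing the
# smoothed field's 0.5 level set instead of the raw binary steps removes the
# staircase bias in surface area (the level set of a smoothed half-space is
# unbiased; only curvature-scale errors of order sigma^2/R remain).  sigma
# is fixed in mm (of the order of a clinical PET point-spread sigma) so the
# meshed boundary is the same physical surface at every voxel size of the
# ladder, with a floor of 0.8 voxel below which the staircase would
# reappear.
.smoothOccupancy <- function(arr, spacing, sigmaMM = 1.5) {
    sigma <- pmax(0.8, sigmaMM / spacing)
    pad <- as.integer(ceiling(4 * max(sigma)) + 1L)
    d <- dim(arr)
    padded <- array(0, d + 2L * pad)
    padded[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- arr
    .gaussSmoothFFT(padded, sigma)
}

#' Morphological (shape) features of a VOI mask
#'
#' The mask is meshed at iso-level 0.5 with a marching-tetrahedra algorithm
#' (a marching-cubes variant on a 6-tetrahedron cell decomposition), giving
#' mesh volume and surface area; derived descriptors follow the
#' standardised definitions.  The occupancy grid is lightly Gaussian-smoothed
#' (sigma = 1 voxel) before meshing so the triangulation tracks the smooth
#' lesion boundary rather than the binary staircase; if smoothing erases the
#' iso-surface entirely (very small masks) the raw binary grid is meshed
#' instead.  Morphology uses the mask geometry only (plus
#' raw intensities for the centre-of-mass shift, integrated intensity and
#' Moran's I), so its values are identical whichever scan interpolator
#' produced the accompanying image.
#'
#' Moran's I uses inverse-Euclidean-distance weights over voxel pairs; for
#' VOIs above 2000 voxels a deterministic evenly-strided subsample of 2000
#' voxels is used.
#'
#' @param mask a non-empty \linkS4class{BinaryMask}.
#' @param vol the paired \linkS4class{ImageVolume} (intensities).
#' @return named numeric vector of 22 features (prefix \code{morph-}).
#' @export
morphologyFeatures <- function(mask, vol) {
    inVoi <- mask@voxels == 1
    n <- sum(inVoi)
    if (n < 1) stop("mask too small to mesh")
    sp <- mask@spacing
    sm <- .smoothOccupancy(mask@voxels, sp)
    if (max(sm) < 0.5) sm <- mask@voxels
    mesh <- cpp_mesh_field(as.numeric(sm), as.integer(dim(sm)), sp, 0.5)
    vu <- unique(round(mesh$vertices, 6))
    if (nrow(vu) > 10000) {
        # snap to a half-voxel grid before the O(n^2) diameter search;
        # displaces the extremes by well under a voxel
        h <- min(sp) / 2
        vu <- unique(round(vu / h)) * h
    }
    V <- mesh$volume
    A <- mesh$area
    vox <- which(inVoi, arr.ind = TRUE)
    coords <- voxelToWorld(mask, vox)
    x <- vol@voxels[inVoi]
    # population covariance of voxel centres
    cc <- sweep(coords, 2, colMeans(coords))
    lam <- sort(eigen(crossprod(cc) / n, symmetric = TRUE,
                      only.values = TRUE)$values, decreasing = TRUE)
    lam <- pmax(lam, 0)
    ext <- apply(vu, 2, function(v) diff(range(v)))
    aabbV <- prod(ext)
    aabbA <- 2 * (ext[1] * ext[2] + ext[1] * ext[3] + ext[2] * ext[3])
    ax <- 2 * sqrt(lam)        # AEE semi-axes
    aeeV <- 4 * pi * prod(ax) / 3
    aeeA <- if (all(ax > 0)) .ellipsoidArea(ax[1], ax[2], ax[3]) else 0
    comGeom <- colMeans(coords)
    comInt <- colSums(coords * x) / sum(x)
    if (n > 2000) {
        keep <- unique(round(seq(1, n, length.out = 2000)))
    } else keep <- seq_len(n)
    mi <- cpp_moran_geary(coords[keep, , drop = FALSE], x[keep])[1]
    c("morph-volume" = V,
      "morph-approxVolume" = n * prod(sp),
      "morph-surfaceArea" = A,
      "morph-surfaceToVolumeRatio" = A / V,
      "morph-compactness1" = V / (sqrt(pi) * A^1.5),
      "morph-compactness2" = 36 * pi * V^2 / A^3,
      "morph-sphericalDisproportion" = A / (36 * pi * V^2)^(1 / 3),
      "morph-sphericity" = (36 * pi * V^2)^(1 / 3) / A,
      "morph-asphericity" = (A^3 / (36 * pi * V^2))^(1 / 3) - 1,
      "morph-centreOfMassShift" = sqrt(sum((comGeom - comInt)^2)),
      "morph-max3dDiameter" = cpp_max_pairwise_distance(vu),
      "morph-majorAxisLength" = 4 * sqrt(lam[1]),
      "morph-minorAxisLength" = 4 * sqrt(lam[2]),
      "morph-leastAxisLength" = 4 * sqrt(lam[3]),
      "morph-elongation" = if (lam[1] > 0) sqrt(lam[2] / lam[1]) else 1,
      "morph-flatness" = if (lam[1] > 0) sqrt(lam[3] / lam[1]) else 1,
      "morph-volumeDensityAABB" = if (aabbV > 0) V / aabbV else NA_real_,
      "morph-areaDensityAABB" = if (aabbA > 0) A / aabbA else NA_real_,
      "morph-volumeDensityAEE" = if (aeeV > 0) V / aeeV else NA_real_,
      "morph-areaDensityAEE" = if (aeeA > 0) A / aeeA else NA_real_,
      "morph-integratedIntensity" = mean(x) * V,
      "morph-moranI" = mi)
}
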