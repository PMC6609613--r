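#' ImageVolume: a 3D scalar SUV grid with physical geometry
#'
#' Axis-aligned 3D scalar field (typically SUV-valued) together with the
#' voxel spacing in mm per axis and the world coordinate (mm) of the centre
#' of voxel (1,1,1).  Voxel index (i,j,k) (1-based in R) maps to world
#' coordinate \code{origin + (i-1, j-1, k-1) * spacing}.
#'
#' @slot voxels 3D numeric array of voxel values.
#' @slot spacing numeric(3), voxel edge lengths in mm (all > 0).
#' @slot origin numeric(3), world position (mm) of the first voxel centre.
#' @export
setClass("ImageVolume",
    representation(voxels = "array", spacing = "numeric", origin = "numeric"),
    prototype(voxels = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
              origin = c(0, 0, 0)))

setValidity("ImageVolume", function(object) {
    msg <- character()
    if (length(dim(object@voxels)) != 3L)
        msg <- c(msg, "voxels must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 3 positive finite numbers (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        msg <- c(msg, "origin must be 3 finite numbers (mm)")
    if (any(!is.finite(object@voxels)))
        msg <- c(msg, "voxel values must all be finite")
    if (length(msg)) msg else TRUE
})

#' BinaryMask: a volume-of-interest occupancy grid
#'
#' An \linkS4class{ImageVolume} whose voxel values are restricted to
#' \{0, 1\}.  Shares the geometry conventions of its paired image volume.
#'
#' @export
setClass("BinaryMask", contains = "ImageVolume")

setValidity("BinaryMask", function(object) {
    if (!all(object@voxels %in% c(0, 1)))
        return("mask values must be exactly 0 or 1")
    TRUE
})

#' ResampleGrid: a target geometry for isotropic resampling
#'
#' Describes the isotropic grid a source volume is interpolated onto.  The
#' world-space centre of the target grid coincides with the centre of the
#' source grid (grid-centre alignment).
#'
#' @slot spacing numeric(3), target voxel size (isotropic) in mm.
#' @slot dims integer(3), target grid dimensions.
#' @slot origin numeric(3), world position (mm) of the first target voxel
#'   centre.
#' @slot sourceDims integer(3), dimensions of the source grid the target was
#'   derived from (used to check provenance).
#' @slot sourceSpacing numeric(3), spacing of the source grid.
#' @slot sourceOrigin numeric(3), origin of the source grid.
#' @export
setClass("ResampleGrid",
    representation(spacing = "numeric", dims = "integer", origin = "numeric",
                   sourceDims = "integer", sourceSpacing = "numeric",
                   sourceOrigin = "numeric"))

setValidity("ResampleGrid", function(object) {
    msg <- character()
    if (any(object@dims < 1L)) msg <- c(msg, "target dims must all be >= 1")
    if (any(object@spacing <= 0)) msg <- c(msg, "target spacing must be > 0")
    # grid-centre alignment invariant
    cs <- object@sourceOrigin + (object@sourceDims - 1) * object@sourceSpacing / 2
    ct <- object@origin + (object@dims - 1) * object@spacing / 2
    if (any(abs(cs - ct) > 1e-9))
        msg <- c(msg, "target grid centre must coincide with source grid centre")
    if (length(msg)) msg else TRUE
})

#' SurfaceModel: fitted voxel-size drift surface for one feature
#'
#' Least-squares surface mapping (feature value, voxel size) to the fitted
#' fractional change relative to the reference voxel size, used to rescale
#' drifted feature values back to the reference scale.
#'
#' @slot feature character, feature name the surface corrects.
#' @slot coefficients numeric, coefficients of the bivariate polynomial
#'   basis.
#' @slot degreeValue integer, polynomial degree in the (standardised)
#'   feature-value axis.
#' @slot degreeVoxel integer, polynomial degree in the voxel-size axis.
#' @slot logValue logical, whether the feature-value axis was log-transformed
#'   before standardisation.
#' @slot valueCenter,valueScale numeric, standardisation of the value axis.
#' @slot valueRange numeric(2), training range of the (raw) feature value;
#'   evaluation outside is clamped.
#' @slot voxelRange numeric(2), training range of voxel size (mm).
#' @slot reference numeric, reference voxel size (mm).
#' @slot nTrain integer, number of training points.
#' @slot residualRMS numeric, root-mean-square residual of the fit.
#' @export
setClass("SurfaceModel",
    representation(feature = "character", coefficients = "numeric",
                   degreeValue = "integer", degreeVoxel = "integer",
                   logValue = "logical", valueCenter = "numeric",
                   valueScale = "numeric", valueRange = "numeric",
                   voxelRange = "numeric", reference = "numeric",
                   nTrain = "integer", residualRMS = "numeric"))

setMethod("show", "ImageVolume", function(object) {
    d <- dim(object@voxels)
    cat(sprintf("%s: %d x %d x %d voxels, spacing (%.4g, %.4g, %.4g) mm\n",
                class(object), d[1], d[2], d[3],
                object@spacing[1], object@spacing[2], object@spacing[3]))
    cat(sprintf("  origin (%.4g, %.4g, %.4g) mm, value range [%.4g, %.4g]\n",
                object@origin[1], object@origin[2], object@origin[3],
                min(object@voxels), max(object@voxels)))
})

setMethod("show", "ResampleGrid", function(object) {
    cat(sprintf("ResampleGrid: %d x %d x %d @ %.4g mm (from %d x %d x %d)\n",
                object@dims[1], object@dims[2], object@dims[3],
                object@spacing[1], object@sourceDims[1], object@sourceDims[2],
                object@sourceDims[3]))
})

setMethod("show", "SurfaceModel", function(object) {
    cat(sprintf("SurfaceModel for '%s': degree (%d, %d), %d points, RMS %.4g\n",
                object@feature, object@degreeValue, object@degreeVoxel,
                object@nTrain, object@residualRMS))
    cat(sprintf("  reference %.2f mm, voxel range [%.2f, %.2f] mm, log-value: %s\n",
                object@reference, object@voxelRange[1], object@voxelRange[2],
                object@logValue))
})
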