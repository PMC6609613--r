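#' Accessors for image geometry
#'
#' @param x an \linkS4class{ImageVolume} (or subclass) or
#'   \linkS4class{ResampleGrid}.
#' @return \code{voxelSpacing} and \code{worldOrigin} return numeric(3) in
#'   mm; \code{voxelData} returns the 3D array; \code{gridDims} returns the
#'   integer dimensions.
#' @name geometry-accessors
NULL

#' @rdname geometry-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname geometry-accessors
#' @export
setGeneric("worldOrigin", function(x) standardGeneric("worldOrigin"))

#' @rdname geometry-accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname geometry-accessors
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' @rdname geometry-accessors
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)

#' @rdname geometry-accessors
setMethod("voxelSpacing", "ResampleGrid", function(x) x@spacing)

#' @rdname geometry-accessors
setMethod("worldOrigin", "ImageVolume", function(x) x@origin)

#' @rdname geometry-accessors
setMethod("worldOrigin", "ResampleGrid", function(x) x@origin)

#' @rdname geometry-accessors
setMethod("voxelData", "ImageVolume", function(x) x@voxels)

#' @rdname geometry-accessors
setMethod("gridDims", "ImageVolume", function(x) dim(x@voxels))

#' @rdname geometry-accessors
setMethod("gridDims", "ResampleGrid", function(x) x@dims)
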