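#' Derive the isotropic target grid for a source volume
#'
#' Target dimensions are \code{ceiling(dims * spacing / s)} per axis so the
#' source field of view is always covered, and the target origin is chosen
#' so the world-space centres of the two grids coincide (grid-centre
#' alignment).
#'
#' @param source an \linkS4class{ImageVolume} (or \linkS4class{BinaryMask}).
#' @param s target isotropic voxel size in mm (> 0).
#' @return A \linkS4class{ResampleGrid}.
#' @examples
#' vol <- imageVolume(array(0, c(64, 64, 32)), spacing = c(2.73, 2.73, 3.27))
#' gridDims(targetGrid(vol, 2.7))   # 65 65 39
#' @export
targetGrid <- function(source, s) {
    stopifnot(s > 0)
    d <- dim(source@voxels)
    sp <- source@spacing
    # tolerate floating-point representation of an exact integer ratio
    nd <- as.integer(ceiling(d * sp / s - 1e-9))
    centre <- source@origin + (d - 1) * sp / 2
    org <- centre - (nd - 1) * s / 2
    new("ResampleGrid", spacing = rep(s, 3), dims = nd, origin = org,
        sourceDims = as.integer(d), sourceSpacing = sp,
        sourceOrigin = source@origin)
}

.checkProvenance <- function(vol, grid) {
    if (!isTRUE(all.equal(as.integer(dim(vol@voxels)), grid@sourceDims)) ||
        max(abs(vol@spacing - grid@sourceSpacing)) > 1e-9 ||
        max(abs(vol@origin - grid@sourceOrigin)) > 1e-9)
        stop("grid was not derived from this volume's geometry")
}

# continuous 0-based source indices of the target voxel centres, per axis
.sourceCoords <- function(grid) {
    lapply(1:3, function(a) {
        w <- grid@origin[a] + (seq_len(grid@dims[a]) - 1) * grid@spacing[a]
        (w - grid@sourceOrigin[a]) / grid@sourceSpacing[a]
    })
}

#' Resample an image volume onto a target grid
#'
#' Each target voxel centre is mapped to continuous source coordinates and
#' the value interpolated with the chosen method.  Target centres falling
#' outside the source grid take the nearest source-edge value (clamped
#' coordinates).
#'
#' @param vol source \linkS4class{ImageVolume}.
#' @param grid a \linkS4class{ResampleGrid} produced by
#'   \code{\link{targetGrid}} from \code{vol}'s geometry.
#' @param method "trilinear" (8-neighbour linear) or "spline" (cubic
#'   B-spline with prefiltering, mirror boundary).
#' @return the resampled \linkS4class{ImageVolume}.
#' @export
resampleImage <- function(vol, grid, method = c("trilinear", "spline")) {
    method <- match.arg(method)
    .checkProvenance(vol, grid)
    cc <- .sourceCoords(grid)
    sdim <- as.integer(dim(vol@voxels))
    src <- as.numeric(vol@voxels)
    out <- if (method == "trilinear") {
        cpp_trilinear(src, sdim, cc[[1]], cc[[2]], cc[[3]])
    } else {
        coefs <- cpp_bspline_prefilter(src, sdim)
        cpp_bspline_eval(coefs, sdim, cc[[1]], cc[[2]], cc[[3]])
    }
    dim(out) <- grid@dims
    imageVolume(out, spacing = grid@spacing, origin = grid@origin)
}

#' Resample a binary mask onto a target grid
#'
#' The occupancy field is interpolated trilinearly (always, regardless of
#' the scan interpolator) and re-binarised at 0.5: interpolated values
#' >= 0.5 become 1, the rest 0.  An empty result is flagged with a warning,
#' not an error.
#'
#' @param mask source \linkS4class{BinaryMask}.
#' @param grid a \linkS4class{ResampleGrid} from the same source geometry.
#' @return the resampled \linkS4class{BinaryMask}.
#' @export
resampleMask <- function(mask, grid) {
    .checkProvenance(mask, grid)
    cc <- .sourceCoords(grid)
    sdim <- as.integer(dim(mask@voxels))
    out <- cpp_trilinear(as.numeric(mask@voxels), sdim,
                         cc[[1]], cc[[2]], cc[[3]])
    out <- (out >= 0.5) * 1
    dim(out) <- grid@dims
    res <- binaryMask(out, spacing = grid@spacing, origin = grid@origin)
    if (isEmptyMask(res))
        warning("resampled mask is empty at spacing ", grid@spacing[1], " mm")
    res
}

#' The default isotropic voxel-size ladder (mm)
#'
#' Six isotropic voxel sizes spanning the original axial resolution down to
#' 1.5 mm; 2.7 mm is the reference ("ground truth") size, closest to the
#' axial plane resolution of the source grid.
#'
#' @return numeric vector of voxel sizes in mm.
#' @export
voxelLadder <- function() c(1.5, 1.8, 2.0, 2.2, 2.5, 2.7)

#' Reference voxel size (mm)
#' @return 2.7
#' @export
referenceVoxelSize <- function() 2.7
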