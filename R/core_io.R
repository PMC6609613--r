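#' Construct an ImageVolume
#'
#' @param voxels 3D numeric array of voxel values (SUV).
#' @param spacing numeric(3), voxel size in mm per axis.
#' @param origin numeric(3), world coordinate (mm) of the centre of the
#'   first voxel. Defaults to (0,0,0).
#' @return An \linkS4class{ImageVolume}.
#' @examples
#' vol <- imageVolume(array(1, c(4, 4, 4)), spacing = c(2.73, 2.73, 3.27))
#' voxelSpacing(vol)
#' @export
imageVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    if (is.null(dim(voxels))) dim(voxels) <- c(length(voxels), 1L, 1L)
    new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' Construct a BinaryMask
#'
#' @param voxels 3D array with values in \{0, 1\} (logical arrays are
#'   coerced).
#' @inheritParams imageVolume
#' @return A \linkS4class{BinaryMask}.
#' @export
binaryMask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    storage.mode(voxels) <- "double"
    if (is.null(dim(voxels))) dim(voxels) <- c(length(voxels), 1L, 1L)
    new("BinaryMask", voxels = voxels, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' Is a mask empty?
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @return TRUE when no voxel is set.
#' @export
isEmptyMask <- function(mask) sum(mask@voxels) == 0

#' Map voxel indices to world coordinates
#'
#' Voxel (i, j, k) (1-based) has its centre at
#' \code{origin + (i-1, j-1, k-1) * spacing}.
#'
#' @param x an \linkS4class{ImageVolume} or \linkS4class{ResampleGrid}.
#' @param ijk integer matrix (n x 3) or vector of length 3 of 1-based voxel
#'   indices.
#' @return numeric matrix (n x 3) of world coordinates in mm.
#' @export
voxelToWorld <- function(x, ijk) {
    if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1)
    sweep(sweep(ijk - 1, 2, voxelSpacing(x), "*"), 2, worldOrigin(x), "+")
}

.geometryFromNifti <- function(img) {
    m <- RNifti::xform(img)
    rot <- m[1:3, 1:3]
    spacing <- sqrt(colSums(rot^2))
    if (any(spacing <= 0))
        stop("non-positive voxel spacing in NIfTI geometry")
    offdiag <- rot
    diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-4 * max(spacing)))
        stop("oblique (non axis-aligned) NIfTI orientations are not supported")
    list(spacing = as.numeric(spacing), origin = as.numeric(m[1:3, 4]))
}

#' Read a 3D SUV volume from a NIfTI-1 file
#'
#' Spacing and origin are recovered from the file's transform; only
#' axis-aligned volumes are supported.
#'
#' @param path path to a NIfTI-1 file (.nii or .nii.gz) holding a 3D scalar
#'   image.
#' @return An \linkS4class{ImageVolume}.
#' @export
readVolume <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
    if (length(d) != 3L)
        stop("expected a 3D image, got ", length(d), " dimensions: ", path)
    a <- array(as.numeric(img), d)
    g <- .geometryFromNifti(img)
    imageVolume(a, spacing = g$spacing, origin = g$origin)
}

#' Write an ImageVolume to a NIfTI-1 file
#'
#' @param vol an \linkS4class{ImageVolume}.
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
    img <- RNifti::asNifti(vol@voxels)
    RNifti::pixdim(img) <- vol@spacing
    m <- diag(c(vol@spacing, 1))
    m[1:3, 4] <- vol@origin
    img <- RNifti::`sform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Read a binary VOI mask from a NIfTI-1 file
#'
#' Values must round to 0 or 1 within tolerance 1e-6; anything else is a
#' format error.  An all-zero mask is valid but flagged with a warning.
#'
#' @param path path to a NIfTI-1 mask file.
#' @return A \linkS4class{BinaryMask}.
#' @export
readMask <- function(path) {
    vol <- readVolume(path)
    v <- vol@voxels
    r <- round(v)
    if (any(abs(v - r) > 1e-6) || any(!r %in% c(0, 1)))
        stop("mask file contains values other than 0/1: ", path)
    m <- binaryMask(r, spacing = vol@spacing, origin = vol@origin)
    if (isEmptyMask(m)) warning("mask is empty: ", path)
    m
}

#' @rdname writeVolume
#' @export
writeMask <- function(vol, path) writeVolume(vol, path)

# ---------------------------------------------------------------------------
# Feature tables
# ---------------------------------------------------------------------------

#' Construct a long-format feature table
#'
#' The central value store of the pipeline: one row per
#' (patient, voxel size, interpolator, feature) with at most one value per
#' key.  Missing values (degenerate VOIs) are stored as NA and excluded
#' pairwise downstream.
#'
#' @param patient character or integer patient ids.
#' @param voxel_size_mm numeric isotropic voxel size in mm.
#' @param interpolator character interpolator tag ("trilinear" or "spline").
#' @param feature character feature names.
#' @param value numeric feature values (NA allowed).
#' @return A data.frame with columns patient, voxel_size_mm, interpolator,
#'   feature, value.
#' @export
featureTable <- function(patient, voxel_size_mm, interpolator, feature, value) {
    df <- data.frame(patient = as.character(patient),
                     voxel_size_mm = as.numeric(voxel_size_mm),
                     interpolator = as.character(interpolator),
                     feature = as.character(feature),
                     value = as.numeric(value),
                     stringsAsFactors = FALSE)
    validateFeatureTable(df)
    df
}

#' Validate a feature table
#'
#' @param df a data.frame in feature-table layout.
#' @return \code{df}, invisibly; errors on malformed input.
#' @export
validateFeatureTable <- function(df) {
    need <- c("patient", "voxel_size_mm", "interpolator", "feature", "value")
    if (!all(need %in% names(df)))
        stop("feature table must have columns: ", paste(need, collapse = ", "))
    key <- paste(df$patient, df$voxel_size_mm, df$interpolator, df$feature,
                 sep = "\r")
    if (anyDuplicated(key))
        stop("duplicate (patient, voxel size, interpolator, feature) keys")
    invisible(df)
}

#' Read / write feature tables as CSV
#'
#' Long-format RFC-4180 CSV with header
#' \code{patient,voxel_size_mm,interpolator,feature,value}; NA values are
#' serialised as empty fields and restored as missing.
#'
#' @param table a feature table data.frame.
#' @param path CSV file path.
#' @return \code{readFeatureTable} returns the table;
#'   \code{writeFeatureTable} returns \code{path} invisibly.
#' @export
writeFeatureTable <- function(table, path) {
    validateFeatureTable(table)
    if (nrow(table) == 0L) stop("refusing to write an empty feature table")
    write.csv(table, path, row.names = FALSE, na = "")
    invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = c(patient = "character"))
    validateFeatureTable(df)
    df
}
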