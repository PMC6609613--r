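#' Fixed-bin-size discretisation of a VOI
#'
#' Quantises the SUV values inside the mask into integer grey levels with a
#' fixed bin width: \code{level = floor((SUV - b0) / w) + 1}.  A fixed bin
#' width (rather than a fixed bin number) keeps the SUV meaning of each
#' level identical across voxel sizes, which cross-voxel-size comparisons
#' require.
#'
#' @param vol an \linkS4class{ImageVolume}.
#' @param mask a \linkS4class{BinaryMask} with identical geometry.
#' @param binWidth bin width w in SUV (default 0.5).
#' @param lowerBound lower bound b0 in SUV (default 0; bins [0, 0.5),
#'   [0.5, 1.0), ...).
#' @return A list of class "DiscretisedVOI" with elements \code{levels}
#'   (3D integer array, 0 outside the VOI), \code{ng} (max observed level),
#'   \code{nVoxels}, \code{binWidth}, \code{lowerBound}, \code{spacing} and
#'   \code{mask} (the 0/1 occupancy array).
#' @export
discretiseFBS <- function(vol, mask, binWidth = 0.5, lowerBound = 0) {
    stopifnot(binWidth > 0)
    if (!isTRUE(all.equal(dim(vol@voxels), dim(mask@voxels))) ||
        max(abs(vol@spacing - mask@spacing)) > 1e-9)
        stop("volume and mask geometry differ")
    inVoi <- mask@voxels == 1
    if (!any(inVoi)) stop("empty mask: nothing to discretise")
    suv <- vol@voxels[inVoi]
    if (any(suv < lowerBound))
        stop("VOI contains values below the discretisation lower bound")
    lev <- array(0L, dim(vol@voxels))
    lev[inVoi] <- as.integer(floor((suv - lowerBound) / binWidth)) + 1L
    out <- list(levels = lev, ng = max(lev), nVoxels = sum(inVoi),
                binWidth = binWidth, lowerBound = lowerBound,
                spacing = vol@spacing, mask = (mask@voxels == 1) * 1L)
    class(out) <- "DiscretisedVOI"
    out
}

.checkDvoi <- function(d) {
    if (!inherits(d, "DiscretisedVOI")) stop("expected a DiscretisedVOI")
    if (d$nVoxels < 1L) stop("empty DiscretisedVOI")
    invisible(d)
}

.textureMatrix <- function(family, counts, extra = list()) {
    out <- c(list(family = family, counts = counts), extra)
    class(out) <- "TextureMatrix"
    out
}

#' Texture-matrix builders
#'
#' Build the five 3D texture matrices from a discretised VOI.  GLCM and
#' GLRLM are generated for each of the 13 unique directions at Chebyshev
#' distance 1 and merged (summed) before normalisation; GLSZM/GLDZM zones
#' are 26-connected components of equal grey level; GLDZM zone distance is
#' the minimum city-block distance of any zone voxel to the first voxel
#' outside the morphological mask (border voxels have distance 1); NGTDM
#' accumulates, per grey level, the absolute difference to the mean level of
#' the 26-neighbourhood restricted to VOI members.
#'
#' @param d a \code{\link{discretiseFBS}} result.
#' @return A list of class "TextureMatrix" whose \code{counts} element holds
#'   the merged count matrix: GLCM ng x ng (symmetric), GLRLM ng x max run
#'   length, GLSZM ng x max zone size, GLDZM ng x max zone distance, NGTDM
#'   ng x 2 (columns n_i, s_i).
#' @name texture-matrices
NULL

#' @rdname texture-matrices
#' @export
buildGLCM <- function(d) {
    .checkDvoi(d)
    m <- cpp_glcm_merged(as.integer(d$levels), as.integer(dim(d$levels)), d$ng)
    .textureMatrix("GLCM", m, list(nVoxels = d$nVoxels))
}

#' @rdname texture-matrices
#' @export
buildGLRLM <- function(d) {
    .checkDvoi(d)
    m <- cpp_glrlm_merged(as.integer(d$levels), as.integer(dim(d$levels)), d$ng)
    m <- m[, seq_len(max(which(colSums(m) > 0))), drop = FALSE]
    .textureMatrix("GLRLM", m, list(nVoxels = d$nVoxels, nDirections = 13L))
}

.zoneTable <- function(d) {
    lab <- cpp_label_zones(as.integer(d$levels), as.integer(dim(d$levels)))
    keep <- lab > 0L
    zlev <- tapply(d$levels[keep], lab[keep], function(x) x[1])
    zsize <- tabulate(lab[keep])
    list(label = as.integer(names(zlev)), level = as.integer(zlev),
         size = zsize[as.integer(names(zlev))], labels = lab)
}

#' @rdname texture-matrices
#' @export
buildGLSZM <- function(d) {
    .checkDvoi(d)
    z <- .zoneTable(d)
    m <- matrix(0, d$ng, max(z$size))
    for (i in seq_along(z$level))
        m[z$level[i], z$size[i]] <- m[z$level[i], z$size[i]] + 1
    .textureMatrix("GLSZM", m, list(nVoxels = d$nVoxels))
}

#' @rdname texture-matrices
#' @export
buildGLDZM <- function(d) {
    .checkDvoi(d)
    z <- .zoneTable(d)
    dist <- cpp_cityblock_border_distance(as.integer(d$mask),
                                          as.integer(dim(d$levels)))
    keep <- z$labels > 0L
    zdist <- tapply(dist[keep], z$labels[keep], min)
    zdist <- as.integer(zdist[as.character(z$label)])
    m <- matrix(0, d$ng, max(zdist))
    for (i in seq_along(z$level))
        m[z$level[i], zdist[i]] <- m[z$level[i], zdist[i]] + 1
    .textureMatrix("GLDZM", m, list(nVoxels = d$nVoxels))
}

#' @rdname texture-matrices
#' @export
buildNGTDM <- function(d) {
    .checkDvoi(d)
    m <- cpp_ngtdm(as.integer(d$levels), as.integer(dim(d$levels)), d$ng)
    colnames(m) <- c("n", "s")
    .textureMatrix("NGTDM", m, list(nVoxels = d$nVoxels))
}
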