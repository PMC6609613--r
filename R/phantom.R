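#' @noRd
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

#' Specification for a synthetic PET lesion phantom
#'
#' Describes an FDG-avid ellipsoidal lesion with controllable intra-lesion
#' heterogeneity on an anisotropic PET grid.  The continuous activity field
#' is a Gaussian random field (white noise convolved with an isotropic
#' Gaussian of the stated correlation length) supported on the ellipsoid,
#' evaluated on a supersampled grid and block-averaged to the acquisition
#' grid to emulate partial-volume averaging.
#'
#' @param dims integer(3) acquisition grid dimensions.
#' @param spacing numeric(3) acquisition voxel size in mm; the default is a
#'   typical clinical PET reconstruction grid.
#' @param halfAxes numeric(3) lesion ellipsoid half-axes in mm.
#' @param background background SUV outside the lesion.
#' @param lesionMean mean lesion SUV; with the default heterogeneity this
#'   keeps SUVmax well above the FDG-avidity floor of 3.
#' @param amplitude heterogeneity amplitude: the standard deviation (SUV) of
#'   the Gaussian random field added inside the lesion.
#' @param corrLength correlation length (mm) of the heterogeneity texture.
#' @param supersample integer supersampling factor per axis (block-averaged
#'   back to the acquisition grid).
#' @param seed integer seed; phantoms are bit-reproducible given the seed.
#' @return A list of class "PhantomSpec".
#' @export
phantomSpec <- function(dims = c(40L, 40L, 30L),
                        spacing = c(2.73, 2.73, 3.27),
                        halfAxes = c(16, 13, 11),
                        background = 0.5,
                        lesionMean = 5,
                        amplitude = 1,
                        corrLength = 6,
                        supersample = 4L,
                        seed = 1L) {
    spec <- list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 halfAxes = as.numeric(halfAxes), background = background,
                 lesionMean = lesionMean, amplitude = amplitude,
                 corrLength = corrLength, supersample = as.integer(supersample),
                 seed = as.integer(seed))
    class(spec) <- "PhantomSpec"
    extent <- spec$dims * spec$spacing
    if (any(2 * spec$halfAxes > extent - 2 * spec$spacing))
        stop("lesion does not fit inside the grid with a one-voxel margin")
    if (spec$background < 0 || spec$lesionMean < 0 || spec$amplitude < 0)
        stop("SUV parameters must be non-negative")
    if (spec$supersample < 1L) stop("supersample must be >= 1")
    spec
}

# periodic Gaussian smoothing via FFT; sigma in voxel units per axis
.gaussSmoothFFT <- function(arr, sigma) {
    d <- dim(arr)
    kern1 <- function(n, s) {
        if (s <= 0) return(c(1, rep(0, n - 1)))
        x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
        k <- exp(-x^2 / (2 * s^2))
        k / sum(k)
    }
    K <- outer(outer(kern1(d[1], sigma[1]), kern1(d[2], sigma[2])),
               kern1(d[3], sigma[3]))
    dim(K) <- d
    Re(fft(fft(arr) * fft(K), inverse = TRUE)) / prod(d)
}

.blockMean <- function(arr, f) {
    if (f == 1L) return(arr)
    d <- dim(arr) / f
    dim(arr) <- c(f, d[1], f, d[2], f, d[3])
    out <- apply(arr, c(2, 4, 6), mean)
    dim(out) <- d
    out
}

#' Generate a synthetic PET lesion phantom
#'
#' Evaluates the continuous SUV field of a \code{\link{phantomSpec}} on a
#' supersampled grid, block-averages it to the acquisition grid, and derives
#' the VOI mask as ellipsoid occupancy >= 0.5.  Deterministic given the
#' spec's seed.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list with elements \code{volume} (\linkS4class{ImageVolume}) and
#'   \code{mask} (\linkS4class{BinaryMask}).
#' @export
generatePhantom <- function(spec) {
    stopifnot(inherits(spec, "PhantomSpec"))
    f <- spec$supersample
    sd3 <- spec$dims * f
    ssp <- spec$spacing / f
    centre <- (spec$dims * spec$spacing) / 2
    # supersampled voxel-centre coordinates (origin at first coarse voxel centre)
    ax <- (seq_len(sd3[1]) - 0.5) * ssp[1]
    ay <- (seq_len(sd3[2]) - 0.5) * ssp[2]
    az <- (seq_len(sd3[3]) - 0.5) * ssp[3]
    ex <- (ax - centre[1]) / spec$halfAxes[1]
    ey <- (ay - centre[2]) / spec$halfAxes[2]
    ez <- (az - centre[3]) / spec$halfAxes[3]
    inside <- outer(outer(ex^2, ey^2, "+"), ez^2, "+") < 1
    dim(inside) <- sd3
    field <- .withSeed(spec$seed, {
        if (spec$amplitude > 0) {
            noise <- array(rnorm(prod(sd3)), sd3)
            sm <- .gaussSmoothFFT(noise, spec$corrLength / ssp)
            sm <- sm / sd(sm)
        } else {
            sm <- array(0, sd3)
        }
        v <- array(spec$background, sd3)
        v[inside] <- spec$lesionMean + spec$amplitude * sm[inside]
        pmax(v, 0)
    })
    suv <- .blockMean(field, f)
    occ <- .blockMean(array(as.numeric(inside), sd3), f)
    maskArr <- (occ >= 0.5) * 1
    vol <- imageVolume(suv, spacing = spec$spacing, origin = c(0, 0, 0))
    msk <- binaryMask(maskArr, spacing = spec$spacing, origin = c(0, 0, 0))
    if (isEmptyMask(msk))
        stop("generated mask is empty; lesion half-axes too small for the grid")
    suvmax <- max(voxelData(vol)[maskArr == 1])
    if (suvmax < 3)
        stop(sprintf(paste0("phantom SUVmax = %.2f < 3 (non-FDG-avid); raise ",
                            "lesionMean or lower amplitude"), suvmax))
    list(volume = vol, mask = msk)
}

#' Generate a reproducible cohort of phantoms
#'
#' Per-patient phantom parameters are drawn uniformly from the stated ranges
#' with seeds derived deterministically from the master seed, so reruns are
#' identical and ids stable.
#'
#' @param n number of patients (>= 1).
#' @param ranges list of two-element \code{c(lo, hi)} ranges for
#'   \code{halfAxisA} (largest half-axis, mm), \code{lesionMean},
#'   \code{amplitude} and \code{corrLength}; the remaining two half-axes are
#'   drawn as fractions 0.7-1 of the first.
#' @param seed master integer seed.
#' @param dims,spacing,supersample forwarded to \code{\link{phantomSpec}}.
#' @return list of per-patient lists (id, volume, mask, spec).
#' @export
generateCohort <- function(n, ranges = list(halfAxisA = c(10, 18),
                                            lesionMean = c(4, 9),
                                            amplitude = c(0.5, 1.5),
                                            corrLength = c(4, 9)),
                           seed = 1L,
                           dims = c(40L, 40L, 30L),
                           spacing = c(2.73, 2.73, 3.27),
                           supersample = 4L) {
    stopifnot(n >= 1)
    draws <- .withSeed(seed, {
        lapply(seq_len(n), function(i) {
            a <- runif(1, ranges$halfAxisA[1], ranges$halfAxisA[2])
            list(halfAxes = c(a, a * runif(1, 0.7, 1), a * runif(1, 0.7, 1)),
                 lesionMean = runif(1, ranges$lesionMean[1], ranges$lesionMean[2]),
                 amplitude = runif(1, ranges$amplitude[1], ranges$amplitude[2]),
                 corrLength = runif(1, ranges$corrLength[1], ranges$corrLength[2]),
                 seed = (as.integer(seed) + 7919L * i) %% 2147483647L)
        })
    })
    lapply(seq_len(n), function(i) {
        d <- draws[[i]]
        spec <- phantomSpec(dims = dims, spacing = spacing,
                            halfAxes = d$halfAxes, lesionMean = d$lesionMean,
                            amplitude = d$amplitude, corrLength = d$corrLength,
                            supersample = supersample, seed = d$seed)
        ph <- generatePhantom(spec)
        list(id = sprintf("P%03d", i), volume = ph$volume, mask = ph$mask,
             spec = spec)
    })
}

#' Specification for a feature table with injected voxel-size drift
#'
#' Ground-truth generator for correction-recovery experiments: patient
#' baselines f0 are drawn from a lognormal distribution and feature values
#' follow \code{value(p, v) = f0(p) * (1 + d_p(v)) * (1 + eps)} with
#' \code{d_p(v) = g_p * sum_m coef[m] * (vref - v)^m} and
#' \code{eps ~ N(0, sigma^2)}.  \code{g_p = 1} for a pure
#' voxel-size-dependent (surface-correctable) drift; with
#' \code{patientSpread > 0}, \code{g_p ~ N(1, patientSpread)} makes the
#' drift patient-specific, the failure mode no (feature value, voxel size)
#' surface can correct.
#'
#' @param coef numeric drift polynomial coefficients in powers 1..M of
#'   (vref - v); d(vref) = 0 by construction.
#' @param sigma multiplicative noise SD (fraction of the value).
#' @param vref reference voxel size in mm.
#' @param meanlog,sdlog lognormal parameters of the baseline distribution.
#' @param patientSpread SD of the per-patient drift multiplier g_p (0 = pure
#'   surface drift).
#' @return list of class "DriftSpec".
#' @export
driftSpec <- function(coef = 1 / 3, sigma = 0.01, vref = 2.7,
                      meanlog = log(100), sdlog = 0.3, patientSpread = 0) {
    spec <- list(coef = as.numeric(coef), sigma = sigma, vref = vref,
                 meanlog = meanlog, sdlog = sdlog,
                 patientSpread = patientSpread)
    class(spec) <- "DriftSpec"
    spec
}

#' Evaluate a drift specification at voxel sizes
#'
#' @param spec a \code{\link{driftSpec}}.
#' @param v numeric voxel sizes (mm).
#' @return fractional drift d(v) with d(vref) = 0.
#' @export
driftAt <- function(spec, v) {
    u <- spec$vref - v
    out <- 0
    for (m in seq_along(spec$coef)) out <- out + spec$coef[m] * u^m
    out
}

#' Generate a feature table with known injected drift
#'
#' @param nPatients number of patients.
#' @param drift a \code{\link{driftSpec}}.
#' @param ladder numeric voxel sizes (mm); must include the reference.
#' @param seed integer seed.
#' @param feature feature name used in the table.
#' @param interpolator interpolator tag recorded in the table.
#' @return list with \code{table} (feature table) and \code{baselines}
#'   (named numeric of ground-truth f0 per patient).
#' @export
generateDriftedFeatureTable <- function(nPatients, drift,
                                        ladder = c(1.5, 1.8, 2.0, 2.2, 2.5, 2.7),
                                        seed = 1L,
                                        feature = "synthetic-drifted",
                                        interpolator = "trilinear") {
    stopifnot(inherits(drift, "DriftSpec"))
    if (!any(abs(ladder - drift$vref) < 1e-9))
        stop("voxel ladder must include the reference size")
    d <- driftAt(drift, ladder)
    if (any(1 + d <= 0))
        stop("1 + d(v) must stay positive over the voxel ladder")
    .withSeed(seed, {
        ids <- sprintf("P%03d", seq_len(nPatients))
        f0 <- setNames(exp(rnorm(nPatients, drift$meanlog, drift$sdlog)), ids)
        g <- if (drift$patientSpread > 0)
            rnorm(nPatients, 1, drift$patientSpread) else rep(1, nPatients)
        rows <- expand.grid(patient = ids, voxel_size_mm = ladder,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        p <- match(rows$patient, ids)
        dv <- driftAt(drift, rows$voxel_size_mm) * g[p]
        eps <- if (drift$sigma > 0) rnorm(nrow(rows), 0, drift$sigma) else 0
        val <- f0[p] * (1 + dv) * (1 + eps)
        tab <- featureTable(rows$patient, rows$voxel_size_mm,
                            interpolator, feature, val)
        list(table = tab, baselines = f0)
    })
}
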