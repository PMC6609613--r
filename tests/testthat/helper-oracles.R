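# Brute-force reference implementations, written as plain nested loops so
# they stay independent of the package's computational path.

.dirs26 <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
.dirs26 <- .dirs26[rowSums(abs(.dirs26)) > 0, ]
.dirs13 <- .dirs26[1:13, ]   # one representative per +/- pair

oracle_glcm <- function(lev) {
    d <- dim(lev)
    ng <- max(lev)
    m <- matrix(0, ng, ng)
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
        g <- lev[i, j, k]
        if (g == 0) next
        for (r in seq_len(nrow(.dirs26))) {
            ii <- i + .dirs26[r, 1]; jj <- j + .dirs26[r, 2]
            kk <- k + .dirs26[r, 3]
            if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] ||
                kk > d[3]) next
            h <- lev[ii, jj, kk]
            if (h > 0) m[g, h] <- m[g, h] + 1
        }
    }
    m
}

# run enumeration via rle over every grid line of every direction
oracle_glrlm <- function(lev) {
    d <- dim(lev)
    ng <- max(lev)
    m <- matrix(0, ng, max(d))
    for (r in seq_len(nrow(.dirs13))) {
        v <- .dirs13[r, ]
        for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
            # line starts where the backward step leaves the grid
            p <- c(i, j, k) - v
            if (all(p >= 1 & p <= d)) next
            seqv <- integer()
            q <- c(i, j, k)
            while (all(q >= 1 & q <= d)) {
                seqv <- c(seqv, lev[q[1], q[2], q[3]])
                q <- q + v
            }
            rl <- rle(seqv)
            for (t in seq_along(rl$values))
                if (rl$values[t] > 0)
                    m[rl$values[t], rl$lengths[t]] <-
                        m[rl$values[t], rl$lengths[t]] + 1
        }
    }
    m[, seq_len(max(which(colSums(m) > 0))), drop = FALSE]
}

# 26-connected equal-level zones by repeated region growing
oracle_zones <- function(lev) {
    d <- dim(lev)
    seen <- array(FALSE, d)
    zones <- list()
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
        if (lev[i, j, k] == 0 || seen[i, j, k]) next
        g <- lev[i, j, k]
        members <- matrix(c(i, j, k), 1)
        seen[i, j, k] <- TRUE
        queue <- list(c(i, j, k))
        while (length(queue)) {
            q <- queue[[1]]; queue <- queue[-1]
            for (r in seq_len(nrow(.dirs26))) {
                p <- q + .dirs26[r, ]
                if (any(p < 1) || any(p > d)) next
                if (!seen[p[1], p[2], p[3]] && lev[p[1], p[2], p[3]] == g) {
                    seen[p[1], p[2], p[3]] <- TRUE
                    members <- rbind(members, p)
                    queue <- c(queue, list(p))
                }
            }
        }
        zones[[length(zones) + 1]] <- list(level = g, members = members)
    }
    zones
}

oracle_glszm <- function(lev) {
    z <- oracle_zones(lev)
    ng <- max(lev)
    m <- matrix(0, ng, max(vapply(z, function(x) nrow(x$members), 1L)))
    for (zi in z)
        m[zi$level, nrow(zi$members)] <- m[zi$level, nrow(zi$members)] + 1
    m
}

# exhaustive minimum city-block distance to any point outside the mask
# (voxels with mask 0, or positions beyond the grid)
oracle_border_distance <- function(mask) {
    d <- dim(mask)
    outIdx <- which(mask == 0, arr.ind = TRUE)
    dist <- array(0L, d)
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
        if (mask[i, j, k] == 0) next
        best <- min(i, d[1] - i + 1, j, d[2] - j + 1, k, d[3] - k + 1)
        if (nrow(outIdx))
            best <- min(best, min(abs(outIdx[, 1] - i) + abs(outIdx[, 2] - j) +
                                      abs(outIdx[, 3] - k)))
        dist[i, j, k] <- best
    }
    dist
}

oracle_gldzm <- function(lev) {
    z <- oracle_zones(lev)
    dist <- oracle_border_distance((lev > 0) * 1L)
    ng <- max(lev)
    dz <- vapply(z, function(zi)
        min(apply(zi$members, 1, function(p) as.numeric(dist[p[1], p[2], p[3]]))),
        numeric(1))
    m <- matrix(0, ng, max(dz))
    for (t in seq_along(z))
        m[z[[t]]$level, dz[t]] <- m[z[[t]]$level, dz[t]] + 1
    m
}

oracle_ngtdm <- function(lev) {
    d <- dim(lev)
    ng <- max(lev)
    out <- matrix(0, ng, 2, dimnames = list(NULL, c("n", "s")))
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
        g <- lev[i, j, k]
        if (g == 0) next
        nb <- numeric()
        for (r in seq_len(nrow(.dirs26))) {
            p <- c(i, j, k) + .dirs26[r, ]
            if (any(p < 1) || any(p > d)) next
            h <- lev[p[1], p[2], p[3]]
            if (h > 0) nb <- c(nb, h)
        }
        if (!length(nb)) next
        out[g, "n"] <- out[g, "n"] + 1
        out[g, "s"] <- out[g, "s"] + abs(g - mean(nb))
    }
    out
}

# explicit two-way ANOVA sums for the ICC oracle
oracle_icc <- function(x, model) {
    n <- nrow(x); k <- ncol(x)
    gm <- 0
    for (i in 1:n) for (j in 1:k) gm <- gm + x[i, j]
    gm <- gm / (n * k)
    SSR <- 0
    for (i in 1:n) SSR <- SSR + k * (sum(x[i, ]) / k - gm)^2
    SSC <- 0
    for (j in 1:k) SSC <- SSC + n * (sum(x[, j]) / n - gm)^2
    SST <- 0
    for (i in 1:n) for (j in 1:k) SST <- SST + (x[i, j] - gm)^2
    SSE <- SST - SSR - SSC
    MSR <- SSR / (n - 1); MSC <- SSC / (k - 1); MSE <- SSE / ((n - 1) * (k - 1))
    if (model == "ICC(2,1)")
        (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
    else
        (MSR - MSE) / (MSR + (k - 1) * MSE)
}

# random small VOI: dims <= 6, levels 0 (outside) .. maxLevel, guaranteed
# non-empty
random_voi <- function(maxDim = 6, maxLevel = 4) {
    d <- sample(2:maxDim, 3, replace = TRUE)
    lev <- array(sample(0:maxLevel, prod(d), replace = TRUE,
                        prob = c(0.3, rep(0.7 / maxLevel, maxLevel))), d)
    if (all(lev == 0)) lev[1, 1, 1] <- 1L
    # relabel so levels are 1..ng without gaps is NOT required by the
    # builders; keep raw draws
    storage.mode(lev) <- "integer"
    lev
}

dvoi_from_levels <- function(lev, spacing = c(1, 1, 1)) {
    # build a DiscretisedVOI directly from a level array: SUV = (lev-0.5)*w
    w <- 0.5
    suv <- array(0, dim(lev))
    suv[lev > 0] <- (lev[lev > 0] - 0.5) * w
    vol <- imageVolume(suv, spacing = spacing)
    msk <- binaryMask((lev > 0) * 1, spacing = spacing)
    discretiseFBS(vol, msk, binWidth = w, lowerBound = 0)
}

# a small deterministic phantom cohort, built once per test run; callers
# take the first n of a cached 6-patient cohort
.cohortCache <- new.env(parent = emptyenv())
small_cohort <- function(n = 4) {
    if (is.null(.cohortCache$c6))
        .cohortCache$c6 <- generateCohort(
            6, dims = c(28L, 28L, 22L), supersample = 2L,
            ranges = list(halfAxisA = c(9, 14), lesionMean = c(4, 8),
                          amplitude = c(0.5, 1.2), corrLength = c(4, 8)),
            seed = 404L)
    .cohortCache$c6[seq_len(n)]
}
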