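test_that("target grid dims follow the per-axis ceiling rule", {
    vol <- imageVolume(array(0, c(64, 64, 32)), spacing = c(2.73, 2.73, 3.27))
    g <- targetGrid(vol, 2.7)
    expect_equal(gridDims(g), c(65L, 65L, 39L))
    # grid centres coincide
    cs <- worldOrigin(vol) + (c(64, 64, 32) - 1) * c(2.73, 2.73, 3.27) / 2
    ct <- worldOrigin(g) + (gridDims(g) - 1) * 2.7 / 2
    expect_equal(ct, cs, tolerance = 1e-12)
})

test_that("an already-isotropic source maps to the identity grid", {
    vol <- imageVolume(array(rnorm(4 * 4 * 4), c(4, 4, 4)),
                       spacing = c(2, 2, 2), origin = c(5, 6, 7))
    g <- targetGrid(vol, 2)
    expect_equal(gridDims(g), c(4L, 4L, 4L))
    expect_equal(worldOrigin(g), c(5, 6, 7))
    for (m in c("trilinear", "spline"))
        expect_equal(voxelData(resampleImage(vol, g, m)), voxelData(vol),
                     tolerance = 1e-9)
})

test_that("degenerate 1x1x1 volumes stay a single voxel", {
    vol <- imageVolume(array(3, c(1, 1, 1)), spacing = c(2, 2, 2))
    expect_equal(gridDims(targetGrid(vol, 2.5)), c(1L, 1L, 1L))
})

test_that("trilinear reproduces an affine field at interior target centres", {
    dims <- c(20, 18, 16)
    sp <- c(2.73, 2.73, 3.27)
    idx <- expand.grid(i = 1:dims[1], j = 1:dims[2], k = 1:dims[3])
    w <- cbind((idx$i - 1) * sp[1], (idx$j - 1) * sp[2], (idx$k - 1) * sp[3])
    aff <- function(x, y, z) 2 + 0.1 * x - 0.05 * y + 0.02 * z
    vol <- imageVolume(array(aff(w[, 1], w[, 2], w[, 3]), dims), spacing = sp)
    for (s in c(1.5, 2.0, 2.7)) {
        g <- targetGrid(vol, s)
        out <- resampleImage(vol, g, "trilinear")
        d <- gridDims(g)
        ti <- expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3])
        tw <- sweep(sweep(as.matrix(ti) - 1, 2, rep(s, 3), "*"), 2,
                    worldOrigin(g), "+")
        expected <- aff(tw[, 1], tw[, 2], tw[, 3])
        # interior: strictly inside the source voxel-centre hull
        src_lo <- worldOrigin(vol)
        src_hi <- worldOrigin(vol) + (dims - 1) * sp
        interior <- tw[, 1] > src_lo[1] & tw[, 1] < src_hi[1] &
            tw[, 2] > src_lo[2] & tw[, 2] < src_hi[2] &
            tw[, 3] > src_lo[3] & tw[, 3] < src_hi[3]
        expect_lt(max(abs(as.numeric(voxelData(out))[interior] -
                              expected[interior])), 1e-9)
    }
})

test_that("cubic spline reproduces constant and linear fields", {
    dims <- c(30, 30, 24)
    sp <- c(2, 2, 2)
    vol <- imageVolume(array(4.2, dims), spacing = sp)
    g <- targetGrid(vol, 1.5)
    expect_lt(max(abs(voxelData(resampleImage(vol, g, "spline")) - 4.2)), 1e-6)

    idx <- expand.grid(i = 1:dims[1], j = 1:dims[2], k = 1:dims[3])
    lin <- 1 + 0.3 * (idx$i - 1) + 0.2 * (idx$j - 1) - 0.1 * (idx$k - 1)
    voll <- imageVolume(array(lin, dims), spacing = sp)
    out <- resampleImage(voll, g, "spline")
    d <- gridDims(g)
    ti <- expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3])
    tw <- sweep(sweep(as.matrix(ti) - 1, 2, rep(1.5, 3), "*"), 2,
                worldOrigin(g), "+")
    expected <- 1 + 0.3 * tw[, 1] / 2 + 0.2 * tw[, 2] / 2 - 0.1 * tw[, 3] / 2
    # mirror boundary bends the spline near the edges; the deviation decays
    # geometrically (pole 0.27), so test the deep interior
    margin <- 9 * sp
    src_lo <- worldOrigin(voll) + margin
    src_hi <- worldOrigin(voll) + (dims - 1) * sp - margin
    interior <- tw[, 1] > src_lo[1] & tw[, 1] < src_hi[1] &
        tw[, 2] > src_lo[2] & tw[, 2] < src_hi[2] &
        tw[, 3] > src_lo[3] & tw[, 3] < src_hi[3]
    expect_lt(max(abs(as.numeric(voxelData(out))[interior] -
                          expected[interior])), 1e-6)
})

test_that("trilinear output is bounded by the source range", {
    set.seed(11)
    vol <- imageVolume(array(runif(10 * 10 * 10), c(10, 10, 10)),
                       spacing = c(2.5, 2.5, 3))
    g <- targetGrid(vol, 1.8)
    out <- voxelData(resampleImage(vol, g, "trilinear"))
    expect_gte(min(out), min(voxelData(vol)))
    expect_lte(max(out), max(voxelData(vol)))
})

test_that("mask resampling is strictly binary and conserves sphere volume", {
    dims <- c(40L, 40L, 34L)
    sp <- c(2.73, 2.73, 3.27)
    ctr <- (dims + 1) / 2 * sp - sp / 2
    idx <- expand.grid(i = 1:dims[1], j = 1:dims[2], k = 1:dims[3])
    w <- cbind((idx$i - 1) * sp[1], (idx$j - 1) * sp[2], (idx$k - 1) * sp[3])
    r2 <- (w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2 + (w[, 3] - ctr[3])^2
    mask <- binaryMask(array(as.numeric(r2 <= 40^2), dims), spacing = sp)
    srcVol <- sum(voxelData(mask)) * prod(sp)
    g <- targetGrid(mask, 1.5)
    out <- resampleMask(mask, g)
    vals <- unique(as.numeric(voxelData(out)))
    expect_true(all(vals %in% c(0, 1)))
    newVol <- sum(voxelData(out)) * 1.5^3
    expect_lt(abs(newVol - srcVol) / srcVol, 0.05)

    ones <- binaryMask(array(1, c(6, 6, 6)), spacing = c(2, 2, 2))
    go <- targetGrid(ones, 1.3)
    expect_true(all(voxelData(resampleMask(ones, go)) == 1))
})

test_that("a single-voxel mask can empty under down-sampling, with a flag", {
    arr <- array(0, c(5, 5, 5))
    arr[2, 2, 2] <- 1
    m <- binaryMask(arr, spacing = c(1, 1, 1))
    g <- targetGrid(m, 2)
    expect_warning(out <- resampleMask(m, g), "empty")
    expect_true(isEmptyMask(out))
})

test_that("grids from a different source geometry are rejected", {
    a <- imageVolume(array(0, c(8, 8, 8)), spacing = c(2, 2, 2))
    b <- imageVolume(array(0, c(9, 8, 8)), spacing = c(2, 2, 2))
    g <- targetGrid(a, 1.5)
    expect_error(resampleImage(b, g, "trilinear"), "geometry")
})
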