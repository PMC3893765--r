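test_that("NRRD write/read round-trips values, spacing and origin exactly", {
    set.seed(11)
    g <- voxelGrid3D(array(rnorm(5 * 4 * 3), c(5, 4, 3)),
                     spacing = c(0.7, 1.1, 2.5), origin = c(-3, 0.25, 12))
    path <- withr::local_tempfile(fileext = ".nrrd")
    writeGrid(g, path)
    h <- readGrid(path)
    expect_identical(gridValues(h), gridValues(g))
    expect_identical(gridSpacing(h), gridSpacing(g))
    expect_identical(gridOrigin(h), gridOrigin(g))

    writeGrid(g, path, encoding = "ascii")
    h2 <- readGrid(path)
    expect_equal(gridValues(h2), gridValues(g), tolerance = 1e-15)
})

test_that("reading an externally authored anisotropic NRRD yields its metadata", {
    # fixture verified independently with SimpleITK: spacing (1, 1, 2.5),
    # origin (-0.5, 1.5, 10), values 1..24 in x-fastest order
    g <- readGrid(test_path("anisotropic.nrrd"))
    expect_equal(gridSpacing(g), c(1, 1, 2.5))
    expect_equal(gridOrigin(g), c(-0.5, 1.5, 10))
    expect_equal(gridShape(g), c(2L, 3L, 4L))
    expect_equal(as.numeric(gridValues(g)), as.numeric(1:24))
    expect_equal(gridValues(g)[2, 3, 4], 24)
})

test_that("degenerate raster inputs fail loudly", {
    path <- withr::local_tempfile(fileext = ".nrrd")
    writeLines(c("NRRD0004", "type: double", "dimension: 2", "sizes: 3 3",
                 "encoding: ascii", "", rep("1", 9)), path)
    expect_error(readGrid(path), "non-3D")

    writeLines(c("NRRD0004", "type: double", "dimension: 3",
                 "sizes: 2 2 2", "encoding: ascii", "", rep("1", 8)), path)
    expect_error(readGrid(path), "spacing")

    expect_error(readGrid(withr::local_tempfile(fileext = ".xyz")),
                 "file not found|unsupported")
})

test_that("resampling is the identity on the same grid and for constants", {
    set.seed(2)
    dose <- voxelGrid3D(array(runif(6^3, 0, 30), c(6, 6, 6)), spacing = 2,
                        origin = c(0, 0, 0))
    same <- resampleDoseToStructure(dose, dose)
    expect_equal(gridValues(same), gridValues(dose))

    flat <- voxelGrid3D(array(16, c(9, 9, 9)), spacing = 2,
                        origin = c(-2, -2, -2))
    target <- voxelGrid3D(array(0, c(5, 5, 5)), spacing = 1.5,
                          origin = c(1, 1, 1))
    out <- resampleDoseToStructure(flat, target)
    expect_true(all(abs(gridValues(out) - 16) < 1e-12))
})

test_that("trilinear resampling reproduces an affine dose field exactly", {
    # D(x, y, z) = 2x is affine, so trilinear interpolation is exact
    nx <- 8L
    src <- voxelGrid3D(
        array(rep(2 * (0:(nx - 1)) * 1.5, times = nx * nx), c(nx, nx, nx)),
        spacing = 1.5, origin = c(0, 0, 0))
    dst_geom <- voxelGrid3D(array(0, c(6, 6, 6)), spacing = 1.1,
                            origin = c(0.7, 0.3, 0.9))
    out <- resampleDoseToStructure(src, dst_geom)
    xs <- 0.7 + (0:5) * 1.1
    expected <- array(rep(2 * xs, times = 36), c(6, 6, 6))
    expect_lt(max(abs(gridValues(out) - expected)), 1e-9)
})

test_that("out-of-extent voxels get 0 Gy with a warning; disjoint grids error", {
    src <- voxelGrid3D(array(10, c(4, 4, 4)), spacing = 1, origin = c(0, 0, 0))
    big <- voxelGrid3D(array(0, c(10, 10, 10)), spacing = 1,
                       origin = c(-3, -3, -3))
    expect_warning(out <- resampleDoseToStructure(src, big), "0 Gy")
    v <- gridValues(out)
    expect_equal(v[1, 1, 1], 0)           # centre at (-3,-3,-3), outside
    expect_equal(v[5, 5, 5], 10)          # centre at (1,1,1), inside

    far <- voxelGrid3D(array(0, c(4, 4, 4)), spacing = 1,
                       origin = c(100, 100, 100))
    expect_error(resampleDoseToStructure(src, far), "disjoint")
})

test_that("distance map is zero inside and exact on axis-aligned cases", {
    all1 <- structureMask(array(1, c(4, 4, 4)), spacing = 1)
    expect_true(all(gridValues(distanceToTarget(all1)) == 0))

    v <- array(0, c(9, 9, 9)); v[3, 5, 5] <- 1
    m <- structureMask(v, spacing = 1)
    d <- gridValues(distanceToTarget(m))
    expect_equal(d[6, 5, 5], 3)
    expect_equal(d[3, 5, 5], 0)
    expect_equal(d[3, 5, 9], 4)

    expect_error(distanceToTarget(structureMask(array(0, c(3, 3, 3)))),
                 "empty mask")
})

test_that("distance transform matches the exhaustive oracle on random masks", {
    set.seed(7)
    for (sp in list(c(1, 1, 1), c(0.8, 1.2, 2.4))) {
        v <- array(as.numeric(runif(20^3) < 0.03), c(20, 20, 20))
        if (sum(v) == 0) v[10, 10, 10] <- 1
        m <- structureMask(v, spacing = sp)
        fast <- gridValues(distanceToTarget(m))
        slow <- brute_force_distance(m)
        expect_lt(max(abs(fast - slow)), 1e-6)
    }
})

test_that("sphere distance map lands in the digitization band", {
    m <- small_sphere_mask(radius = 10, extent = 17)
    d <- gridValues(distanceToTarget(m))
    # voxel centre 15 mm from the sphere centre, along an axis
    expect_gte(d[18 + 15, 18, 18], 4.0)
    expect_lte(d[18 + 15, 18, 18], 6.0)
})

test_that("masked volumes are counts times voxel volume and additive", {
    m <- structureMask(array(rep(c(0, 1), 500), c(10, 10, 10)), spacing = 1)
    expect_equal(maskedVolume(m), 500)

    empty <- structureMask(array(0, c(5, 5, 5)), spacing = 1)
    expect_equal(maskedVolume(empty), 0)

    sph <- makeEllipsoidMask(c(0, 0, 0), 10, shape = c(49, 49, 49),
                             spacing = 0.5, origin = rep(-12, 3))
    expect_lt(abs(maskedVolume(sph) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
              0.02)

    # disjoint parts add up
    v1 <- array(0, c(8, 8, 8)); v1[1:2, , ] <- 1
    v2 <- array(0, c(8, 8, 8)); v2[6:8, , ] <- 1
    u <- structureMask(pmax(v1, v2), spacing = c(1, 2, 1))
    expect_equal(maskedVolume(u),
                 maskedVolume(structureMask(v1, spacing = c(1, 2, 1))) +
                 maskedVolume(structureMask(v2, spacing = c(1, 2, 1))))
})
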