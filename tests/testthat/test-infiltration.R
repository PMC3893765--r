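test_that("no-infiltration density normalizes the in-target cell count", {
    mask <- small_sphere_mask(radius = 5, extent = 8)
    rho <- clonogenDensity(mask, config = infiltrationConfig("none"))
    total <- sum(gridValues(rho)) * voxelVolume(rho)
    expect_lt(abs(total - 1e6) / 1e6, 1e-6)
    expect_true(all(gridValues(rho)[gridValues(mask) == 0] == 0))

    v <- array(0, c(5, 5, 5)); v[3, 3, 3] <- 1
    single <- structureMask(v, spacing = 1)
    r1 <- clonogenDensity(single, config = infiltrationConfig("none"))
    expect_equal(gridValues(r1)[3, 3, 3], 1e6)

    double <- clonogenDensity(mask,
        config = infiltrationConfig("none", clonogens = 2e6))
    expect_equal(gridValues(double), 2 * gridValues(rho))
})

test_that("continuous density decays as exp(-d) and cuts off at dMax", {
    mask <- small_sphere_mask(radius = 5, extent = 17)
    dmap <- distanceToTarget(mask)
    cfg <- infiltrationConfig("continuous")       # dMax 10 mm, decay 1 mm
    rho <- clonogenDensity(mask, dmap, cfg)
    r0 <- rho0(rho)
    d <- gridValues(dmap)
    v <- gridValues(rho)

    inT <- gridValues(mask) != 0
    expect_true(all(v[inT] == r0))                # relative density 1 inside

    near10 <- which(d > 9.9 & d <= 10)
    expect_gt(length(near10), 0)
    expect_equal(v[near10], r0 * exp(-d[near10]), tolerance = 1e-12)
    expect_lt(max(v[near10]) / r0, 5.1e-5)        # exp(-10) ~ 4.54e-5 scale

    expect_true(all(v[d > 10] == 0))              # hard cutoff past 10 mm
    expect_true(all(v[d > 10.4 & d < 10.6] == 0))

    # continuity at the border: density -> rho0 as d -> 0+
    nearb <- which(d > 0 & d <= 1.5)
    expect_gt(length(nearb), 0)
    expect_gte(min(v[nearb]) / r0, exp(-1.5))

    # monotone non-increasing in d
    ord <- order(d[!inT])
    vo <- v[!inT][ord]
    expect_true(all(diff(vo) <= 1e-12))
})

test_that("scenario densities agree on the target and in expectation outside", {
    mask <- small_sphere_mask(radius = 4, extent = 12)
    dmap <- distanceToTarget(mask)
    inT <- gridValues(mask) != 0

    none <- clonogenDensity(mask, config = infiltrationConfig("none"))
    cont <- clonogenDensity(mask, dmap, infiltrationConfig("continuous"))
    het <- clonogenDensity(mask, dmap,
                           infiltrationConfig("heterogeneous", seed = 3))
    expect_equal(gridValues(cont)[inT], gridValues(none)[inT])
    expect_equal(gridValues(het)[inT], gridValues(none)[inT])

    # heterogeneous voxels are either empty or at full density
    out_v <- gridValues(het)[!inT]
    expect_true(all(out_v %in% c(0, rho0(het))))
})

test_that("heterogeneous occupancy is seed-deterministic and Bernoulli in mean", {
    mask <- small_sphere_mask(radius = 4, extent = 12)
    dmap <- distanceToTarget(mask)

    a <- clonogenDensity(mask, dmap, infiltrationConfig("heterogeneous", seed = 42))
    b <- clonogenDensity(mask, dmap, infiltrationConfig("heterogeneous", seed = 42))
    expect_identical(gridValues(a), gridValues(b))
    c2 <- clonogenDensity(mask, dmap, infiltrationConfig("heterogeneous", seed = 43))
    expect_false(identical(gridValues(a), gridValues(c2)))

    # the heterogeneous draw must not disturb the caller's RNG stream
    set.seed(99); before <- runif(3)
    set.seed(99); invisible(clonogenDensity(mask, dmap,
        infiltrationConfig("heterogeneous", seed = 7)))
    expect_identical(runif(3), before)

    # mean occupancy at a probe voxel with d ~ 1 mm: Bernoulli(exp(-d))
    d <- gridValues(dmap)
    probe <- which(d > 0.9 & d < 1.1)[1]
    dp <- d[probe]
    n_seeds <- 200
    occ <- vapply(seq_len(n_seeds), function(s) {
        m <- clonogenDensity(mask, dmap,
                             infiltrationConfig("heterogeneous", seed = s))
        as.numeric(gridValues(m)[probe] > 0)
    }, numeric(1))
    p <- exp(-dp)
    se <- sqrt(p * (1 - p) / n_seeds)
    expect_lt(abs(mean(occ) - p), 3 * se)

    # beyond the cutoff: zero in every realization
    far <- which(d > 10)
    for (s in 1:5) {
        m <- clonogenDensity(mask, dmap,
                             infiltrationConfig("heterogeneous", seed = s))
        expect_true(all(gridValues(m)[far] == 0))
    }
})

test_that("infiltration inputs are validated", {
    mask <- small_sphere_mask(radius = 3, extent = 6)
    other <- small_sphere_mask(radius = 3, extent = 7)
    dmap_other <- distanceToTarget(other)
    expect_error(clonogenDensity(mask, dmap_other,
                                 infiltrationConfig("continuous")),
                 "grid mismatch")
    expect_error(clonogenDensity(mask, NULL, infiltrationConfig("continuous")),
                 "DistanceMap")
    expect_error(infiltrationConfig("heterogeneous"), "seed")
    expect_error(infiltrationConfig("continuous", dMax = -1), "dMax")
})
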