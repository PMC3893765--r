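test_that("LQ survival matches the closed form and is monotone", {
    p <- radiosensitivityParams()                 # alpha 0.24, beta 0.03
    expect_equal(lqSurvival(0, p), 1.0)
    expect_equal(lqSurvival(16, p), exp(-(0.24 * 16 + 0.03 * 16^2)))
    expect_equal(lqSurvival(16, p), 9.9295043e-06, tolerance = 1e-6)

    ladder <- seq(0, 40, by = 0.5)
    expect_true(all(diff(lqSurvival(ladder, p)) < 0))
    expect_error(lqSurvival(-1, p), "negative dose")
    expect_error(radiosensitivityParams(0, 0), "both be zero")
    expect_equal(alphaBeta(p), 8)
})

test_that("survival maps are voxelwise LQ and antitone to dose", {
    zero <- voxelGrid3D(array(0, c(4, 4, 4)), spacing = 1)
    expect_true(all(gridValues(survivalMap(zero)) == 1))

    mask <- small_sphere_mask(radius = 5, extent = 10)
    plan <- fitShotToTarget(mask, coverageFactor = 1.0)
    dose <- composeDose(plan)
    sf <- survivalMap(dose)
    dv <- gridValues(dose); sv <- gridValues(sf)
    expect_equal(max(dv), 32)
    expect_equal(min(sv), lqSurvival(32))         # at the max-dose voxel
    # at voxels within 0.2 Gy of the prescription isodose, SF ~ SF(16 Gy)
    near16 <- abs(dv - 16) < 0.2
    expect_true(any(near16))
    expect_equal(sv[near16], lqSurvival(dv[near16]))
    expect_lt(max(abs(sv[near16] - lqSurvival(16))),
              lqSurvival(15.8) - lqSurvival(16))
    # antitone: higher dose, lower survival
    ord <- order(dv)
    expect_true(all(diff(sv[ord]) <= 1e-18))
})

test_that("computeTCP reproduces Poisson closed forms", {
    # no cells anywhere -> certain control
    v <- array(0, c(3, 3, 3)); v[2, 2, 2] <- 1
    m <- structureMask(v, spacing = 1)
    none <- random_density_map(m, array(0, c(3, 3, 3)))
    flat0 <- voxelGrid3D(array(0, c(3, 3, 3)), spacing = 1)
    r <- computeTCP(flat0, none)
    expect_equal(expectedSurvivors(r), 0)
    expect_equal(tcp(r), 1)

    # zero dose, N cells -> N survivors, TCP ~ 0
    rho <- clonogenDensity(m, config = infiltrationConfig("none"))
    r0 <- computeTCP(flat0, rho)
    expect_equal(expectedSurvivors(r0), 1e6)
    expect_equal(tcp(r0), 0)                      # exp(-1e6) underflows to 0

    # one voxel with rho*V*SF(D) = ln 2 -> TCP exactly 1/2
    p <- radiosensitivityParams()
    target_sf <- log(2) / 1e6
    D <- Re(polyroot(c(log(target_sf), 0.24, 0.03)))
    D <- D[D > 0][1]
    dose <- voxelGrid3D(array(0, c(3, 3, 3)), spacing = 1)
    dose@values[2, 2, 2] <- D
    r2 <- computeTCP(dose, rho, p)
    expect_equal(tcp(r2), 0.5, tolerance = 1e-10)
})

test_that("computeTCP equals brute-force summation and splits additively", {
    set.seed(5)
    for (rep in 1:3) {
        sh <- sample(3:6, 3, replace = TRUE)
        v <- array(as.numeric(runif(prod(sh)) < 0.4), sh)
        if (sum(v) == 0) v[1, 1, 1] <- 1
        m <- structureMask(v, spacing = c(1, 1.5, 2))
        dens <- random_density_map(m, array(runif(prod(sh), 0, 50), sh))
        dose <- voxelGrid3D(array(runif(prod(sh), 0, 35), sh),
                            spacing = c(1, 1.5, 2))
        got <- computeTCP(dose, dens)
        want <- brute_force_tcp(gridValues(dose), gridValues(dens),
                                voxelVolume(dose), 0.24, 0.03)
        expect_equal(expectedSurvivors(got), want$expected_survivors,
                     tolerance = 1e-12)
        expect_equal(tcp(got), want$tcp, tolerance = 1e-12)
        expect_equal(got@survivorsInTarget + got@survivorsOutsideTarget,
                     expectedSurvivors(got))
    }
})

test_that("TCP is monotone in dose and in clonogen burden", {
    set.seed(8)
    mask <- small_sphere_mask(radius = 3, extent = 6)
    dmap <- distanceToTarget(mask)
    dose <- composeDose(fitShotToTarget(mask, coverageFactor = 1.1))
    rho <- clonogenDensity(mask, dmap, infiltrationConfig("continuous"))
    base <- tcp(computeTCP(dose, rho))
    for (i in 1:20) {
        # raising one voxel's dose never decreases TCP
        d2 <- dose
        idx <- sample(length(d2@values), 1)
        d2@values[idx] <- d2@values[idx] + runif(1, 0, 10)
        expect_gte(tcp(computeTCP(d2, rho)), base)
        # adding density to one voxel never increases TCP
        r2 <- rho
        r2@values[idx] <- r2@values[idx] + runif(1, 0, rho0(rho))
        expect_lte(tcp(computeTCP(dose, r2)), base)
    }
    wrong <- composeDose(fitShotToTarget(small_sphere_mask(3, 7),
                                         coverageFactor = 1))
    expect_error(computeTCP(wrong, rho), "grid mismatch")
})
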