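# Independent oracles and small fixture builders used across the suite.

# exhaustive nearest-target-voxel Euclidean distance (triple loop over
# voxels, full scan over target centres)
brute_force_distance <- function(mask) {
    v <- gridValues(mask)
    sp <- gridSpacing(mask)
    d <- dim(v)
    tgt <- which(v != 0, arr.ind = TRUE)
    tgt_mm <- sweep(tgt - 1, 2, sp, "*")
    out <- array(0, dim = d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
        p <- (c(i, j, k) - 1) * sp
        out[i, j, k] <- sqrt(min(colSums((t(tgt_mm) - p)^2)))
    }
    out
}

# direct triple-loop evaluation of the Poisson TCP sum
brute_force_tcp <- function(dose_vals, dens_vals, vox_vol, alpha, beta) {
    d <- dim(dose_vals)
    acc <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
        D <- dose_vals[i, j, k]
        acc <- acc + dens_vals[i, j, k] * vox_vol * exp(-alpha * D - beta * D^2)
    }
    list(expected_survivors = acc, tcp = exp(-acc))
}

# small centred sphere target with surrounding air, 1 mm grid
small_sphere_mask <- function(radius = 5, extent = 15) {
    n <- 2L * extent + 1L
    makeEllipsoidMask(c(0, 0, 0), radius, shape = c(n, n, n), spacing = 1,
                      origin = rep(-extent, 3))
}

# read a mask grid file back as a StructureMask
read_mask <- function(path) {
    g <- readGrid(path)
    structureMask(gridValues(g), spacing = gridSpacing(g),
                  origin = gridOrigin(g))
}

# random density map on a random small target (for oracle tests);
# values are arbitrary non-negative, constructed directly
random_density_map <- function(mask, rng_vals) {
    new("ClonogenDensityMap", values = rng_vals,
        spacing = gridSpacing(mask), origin = gridOrigin(mask),
        rho0 = max(max(rng_vals), 1), mask = mask, scenario = "none")
}
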