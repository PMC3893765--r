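# Clonogen-density maps for the three infiltration scenarios. In every
# scenario the target carries the uniform reference density
# rho0 = clonogens / target volume; the scenarios differ only outside the
# target, and density is exactly zero wherever the distance to the target
# exceeds dMax. Infiltrating cells are additional to the in-target
# population (only the in-target count is normalized to `clonogens`).

.rho0 <- function(mask, config) config@clonogens / maskedVolume(mask)

#' Build a clonogen-density map for an infiltration scenario
#'
#' Dispatches on \code{config@scenario}:
#' \describe{
#'   \item{none}{rho0 on target voxels, 0 everywhere else. The total cell
#'     count equals \code{config@clonogens} exactly.}
#'   \item{continuous}{rho0 inside; rho0 * exp(-d / decayLength) for
#'     0 < d <= dMax; 0 beyond dMax.}
#'   \item{heterogeneous}{rho0 inside; outside, each voxel with
#'     0 < d <= dMax is independently occupied with probability
#'     exp(-d / decayLength); occupied voxels carry the full density rho0,
#'     unoccupied ones 0, so the per-voxel expectation equals the
#'     continuous scenario. Deterministic given \code{config@seed}; the
#'     global RNG state is left untouched.}
#' }
#'
#' @param mask a non-empty [StructureMask].
#' @param dmap the [DistanceMap] of \code{mask} (required for the two
#'   infiltration scenarios; may be NULL for \code{"none"}).
#' @param config an [InfiltrationConfig].
#' @return a [ClonogenDensityMap].
#' @examples
#' m <- makeEllipsoidMask(c(0, 0, 0), 5, shape = c(31, 31, 31),
#'                        spacing = 1, origin = c(-15, -15, -15))
#' d <- distanceToTarget(m)
#' rho <- clonogenDensity(m, d, infiltrationConfig("continuous"))
#' rho0(rho) * exp(-3)   # density 3 mm outside the target
#' @export
clonogenDensity <- function(mask, dmap = NULL, config = infiltrationConfig()) {
    stopifnot(is(mask, "StructureMask"), is(config, "InfiltrationConfig"))
    if (nTargetVoxels(mask) < 1L) stop("empty mask")
    switch(config@scenario,
        none = .density_none(mask, config),
        continuous = .density_continuous(mask, dmap, config),
        heterogeneous = .density_heterogeneous(mask, dmap, config))
}

.density_none <- function(mask, config) {
    r0 <- .rho0(mask, config)
    new("ClonogenDensityMap", values = r0 * mask@values,
        spacing = mask@spacing, origin = mask@origin, rho0 = r0,
        mask = mask, scenario = "none")
}

.check_dmap <- function(mask, dmap) {
    if (is.null(dmap))
        stop("a DistanceMap is required for infiltration scenarios")
    stopifnot(is(dmap, "DistanceMap"))
    .stop_unless_same_geometry(mask, dmap, "mask and distance map")
    if (any(dmap@values[mask@values != 0] != 0))
        stop("distance map was not computed from this mask ",
             "(nonzero distance on target voxels)")
    invisible(TRUE)
}

.density_continuous <- function(mask, dmap, config) {
    .check_dmap(mask, dmap)
    r0 <- .rho0(mask, config)
    d <- dmap@values
    vals <- r0 * exp(-d / config@decayLength)
    vals[d > config@dMax] <- 0
    vals[mask@values != 0] <- r0
    new("ClonogenDensityMap", values = vals, spacing = mask@spacing,
        origin = mask@origin, rho0 = r0, mask = mask,
        scenario = "continuous")
}

.density_heterogeneous <- function(mask, dmap, config) {
    .check_dmap(mask, dmap)
    if (is.na(config@seed))
        stop("heterogeneous scenario requires a seed in the config")
    r0 <- .rho0(mask, config)
    d <- dmap@values
    fringe <- which(mask@values == 0 & d > 0 & d <= config@dMax)
    p <- exp(-d[fringe] / config@decayLength)
    u <- .with_local_seed(config@seed, runif(length(fringe)))
    vals <- array(0, dim = dim(mask@values))
    vals[fringe] <- r0 * as.numeric(u < p)
    vals[mask@values != 0] <- r0
    new("ClonogenDensityMap", values = vals, spacing = mask@spacing,
        origin = mask@origin, rho0 = r0, mask = mask,
        scenario = "heterogeneous")
}

# run expr under set.seed(seed) without disturbing the caller's RNG stream
.with_local_seed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}
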