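# Linear-quadratic survival and the Poisson TCP:
#   TCP = exp(-sum_i rho_i * V_i * exp(-alpha*D_i - beta*D_i^2))
# where the sum runs over all voxels, rho_i is the clonogen density, V_i
# the voxel volume and D_i the dose.

#' Linear-quadratic surviving fraction
#'
#' SF(D) = exp(-alpha * D - beta * D^2), the fraction of clonogens
#' surviving a single-fraction dose D. No proliferation or repopulation
#' term (single-fraction radiosurgery).
#'
#' @param dose dose in Gy, vectorized, all >= 0.
#' @param params a [RadiosensitivityParams].
#' @return surviving fraction(s) in (0, 1].
#' @examples
#' lqSurvival(16)   # about 9.9e-6 for the glioma defaults
#' @export
lqSurvival <- function(dose, params = radiosensitivityParams()) {
    stopifnot(is(params, "RadiosensitivityParams"))
    if (any(dose < 0)) stop("negative dose")
    exp(-params@alpha * dose - params@beta * dose^2)
}

#' Per-voxel survival map
#'
#' Applies [lqSurvival()] voxelwise to a dose grid, giving the surviving
#' fraction of cells at every voxel. The map rises steeply just outside
#' the volume enclosed by the prescription isodose.
#'
#' @param dose a [VoxelGrid3D] of dose (Gy).
#' @param params a [RadiosensitivityParams].
#' @return a [VoxelGrid3D] of surviving fractions in (0, 1].
#' @export
survivalMap <- function(dose, params = radiosensitivityParams()) {
    stopifnot(is(dose, "VoxelGrid3D"))
    voxelGrid3D(lqSurvival(dose@values, params), spacing = dose@spacing,
                origin = dose@origin)
}

#' Poisson tumour control probability
#'
#' Expected survivors = sum over voxels of density * voxel volume *
#' SF(dose); TCP = exp(-expected survivors). The sum is accumulated in
#' extended precision (per-voxel survivor counts span many orders of
#' magnitude between the target core and the infiltration fringe). The
#' survivor count is split into in-target and out-of-target parts using
#' the mask carried by the density map.
#'
#' @param dose a [VoxelGrid3D] of dose (Gy) on the density map's geometry
#'   (resample first otherwise).
#' @param density a [ClonogenDensityMap].
#' @param params a [RadiosensitivityParams].
#' @return a [TCPResult].
#' @examples
#' m <- makeEllipsoidMask(c(0, 0, 0), 5, shape = c(13, 13, 13),
#'                        spacing = 1, origin = c(-6, -6, -6))
#' rho <- clonogenDensity(m, config = infiltrationConfig("none"))
#' flat <- voxelGrid3D(array(20, c(13, 13, 13)), spacing = 1,
#'                     origin = c(-6, -6, -6))
#' computeTCP(flat, rho)
#' @export
computeTCP <- function(dose, density, params = radiosensitivityParams()) {
    stopifnot(is(dose, "VoxelGrid3D"), is(density, "ClonogenDensityMap"),
              is(params, "RadiosensitivityParams"))
    .stop_unless_same_geometry(dose, density, "dose and density")
    if (any(density@values < 0)) stop("negative density")
    if (any(dose@values < 0)) stop("negative dose")
    sf <- exp(-params@alpha * dose@values - params@beta * dose@values^2)
    per_voxel <- density@values * voxelVolume(density) * sf
    inT <- density@mask@values != 0
    s_in <- sum(per_voxel[inT])
    s_out <- sum(per_voxel[!inT])
    total <- s_in + s_out
    new("TCPResult", tcp = exp(-total), expectedSurvivors = total,
        survivorsInTarget = s_in, survivorsOutsideTarget = s_out)
}
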