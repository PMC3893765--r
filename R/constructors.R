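#' Create a VoxelGrid3D
#'
#' @param values 3D numeric array.
#' @param spacing voxel spacing (dx, dy, dz) in mm; a scalar is recycled.
#' @param origin physical coordinate (mm) of the centre of voxel (1,1,1);
#'   default c(0, 0, 0).
#' @return a [VoxelGrid3D].
#' @examples
#' g <- voxelGrid3D(array(0, c(4, 4, 4)), spacing = 1)
#' gridShape(g)
#' @export
voxelGrid3D <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    new("VoxelGrid3D", values = values, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' Create a StructureMask
#'
#' @param values 3D array with values in \{0, 1\} (logical arrays are
#'   coerced).
#' @inheritParams voxelGrid3D
#' @return a [StructureMask].
#' @export
structureMask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    if (is.logical(values)) {
        storage.mode(values) <- "double"
    }
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    new("StructureMask", values = values, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' Create radiosensitivity parameters for the LQ model
#'
#' @param alpha Gy^-1 (default 0.24, glioma).
#' @param beta Gy^-2 (default 0.03, glioma).
#' @return a [RadiosensitivityParams].
#' @examples
#' radiosensitivityParams()          # alpha/beta = 8 Gy
#' @export
radiosensitivityParams <- function(alpha = 0.24, beta = 0.03) {
    new("RadiosensitivityParams", alpha = alpha, beta = beta)
}

#' Create an infiltration configuration
#'
#' @param scenario infiltration scenario: \code{"none"} (clonogens confined
#'   to the target), \code{"continuous"} (density decays as
#'   exp(-d/decayLength) with distance d from the target, zero beyond
#'   dMax) or \code{"heterogeneous"} (each outside voxel within dMax is
#'   occupied at full density with probability exp(-d/decayLength)).
#' @param dMax maximum infiltration distance in mm (default 10).
#' @param decayLength exponential decay length in mm (default 1).
#' @param seed integer seed for the heterogeneous scenario.
#' @param clonogens number of clonogenic cells in the target (default 1e6).
#' @return an [InfiltrationConfig].
#' @examples
#' infiltrationConfig("continuous")
#' @export
infiltrationConfig <- function(scenario = c("none", "continuous",
                                            "heterogeneous"),
                               dMax = 10, decayLength = 1, seed = NULL,
                               clonogens = 1e6) {
    scenario <- match.arg(scenario)
    new("InfiltrationConfig", scenario = scenario, dMax = dMax,
        decayLength = decayLength,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        clonogens = clonogens)
}

#' Create a shot specification
#'
#' @param centre shot centre (x, y, z) in mm.
#' @param sigma Gaussian sigma per axis in mm; a scalar gives an isotropic
#'   shot.
#' @param weight relative intensity (> 0).
#' @return a [ShotSpec].
#' @export
shotSpec <- function(centre, sigma, weight = 1) {
    if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
    new("ShotSpec", centre = as.numeric(centre), sigma = as.numeric(sigma),
        weight = weight)
}

#' Create a plan specification
#'
#' @param shots a [ShotSpec] or list of them.
#' @param prescriptionDose prescription dose in Gy (default 16).
#' @param isodoseFraction isodose fraction the prescription refers to,
#'   in (0, 1] (default 0.5: "16 Gy at the 50\% isodose").
#' @param shape grid shape (nx, ny, nz).
#' @param spacing voxel spacing in mm; scalar recycled.
#' @param origin centre of the first voxel, mm.
#' @return a [PlanSpec].
#' @export
planSpec <- function(shots, prescriptionDose = 16, isodoseFraction = 0.5,
                     shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    if (is(shots, "ShotSpec")) shots <- list(shots)
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    new("PlanSpec", shots = shots, prescriptionDose = prescriptionDose,
        isodoseFraction = isodoseFraction, shape = as.integer(shape),
        spacing = as.numeric(spacing), origin = as.numeric(origin))
}
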