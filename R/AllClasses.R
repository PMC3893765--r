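#' VoxelGrid3D: a 3D scalar field on a regular axis-aligned grid
#'
#' The basic carrier object of the package. Holds a 3D numeric array of
#' values (Gy for dose, cells/mm^3 for clonogen density, mm for distance
#' maps, dimensionless for survival maps), the voxel spacing (dx, dy, dz)
#' in mm and the physical position of the centre of the first voxel
#' (\code{origin}, mm). Every voxel of one grid has the identical volume
#' \code{prod(spacing)} mm^3.
#'
#' @slot values 3D numeric array.
#' @slot spacing numeric(3), voxel spacing in mm, all > 0.
#' @slot origin numeric(3), physical coordinate (mm) of the centre of
#'   voxel (1, 1, 1).
#'
#' @seealso [voxelGrid3D()], [readGrid()], [writeGrid()]
#' @export
setClass("VoxelGrid3D",
    representation(values = "array", spacing = "numeric", origin = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(dim(object@values)) != 3L)
            msg <- c(msg, "values must be a 3D array")
        if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
            any(object@spacing <= 0))
            msg <- c(msg, "spacing must be 3 strictly positive finite numbers")
        if (length(object@origin) != 3L || any(!is.finite(object@origin)))
            msg <- c(msg, "origin must be 3 finite numbers")
        if (!is.numeric(object@values))
            msg <- c(msg, "values must be numeric")
        if (length(msg)) msg else TRUE
    })

#' StructureMask: binary 3D mask of the delineated target
#'
#' A [VoxelGrid3D] whose values are exactly 0 or 1; value-1 voxels make up
#' the delineated target. A usable target has at least one voxel.
#'
#' @seealso [structureMask()], [makeEllipsoidMask()], [distanceToTarget()],
#'   [maskedVolume()]
#' @export
setClass("StructureMask", contains = "VoxelGrid3D",
    validity = function(object) {
        v <- object@values
        if (!all(v == 0 | v == 1))
            return("mask values must be exactly 0 or 1")
        TRUE
    })

#' DistanceMap: per-voxel Euclidean distance to the target
#'
#' A [VoxelGrid3D] holding, for every voxel, the Euclidean distance (mm,
#' respecting anisotropic spacing) from the voxel centre to the centre of
#' the nearest target voxel; exactly 0 on all target voxels.
#'
#' @seealso [distanceToTarget()]
#' @export
setClass("DistanceMap", contains = "VoxelGrid3D",
    validity = function(object) {
        if (any(object@values < 0)) return("distances must be >= 0")
        TRUE
    })

#' ClonogenDensityMap: per-voxel density of clonogenic cells
#'
#' A [VoxelGrid3D] in cells/mm^3, together with the reference in-target
#' density \code{rho0} (clonogen number divided by target volume) and the
#' [StructureMask] it was built from, kept so that downstream TCP results
#' can be split into in-target and out-of-target survivor counts.
#'
#' @slot rho0 reference density in cells/mm^3 on every target voxel.
#' @slot mask the [StructureMask] the map was built from.
#' @slot scenario one of \code{"none"}, \code{"continuous"},
#'   \code{"heterogeneous"}.
#' @seealso [clonogenDensity()]
#' @export
setClass("ClonogenDensityMap", contains = "VoxelGrid3D",
    representation(rho0 = "numeric", mask = "StructureMask",
                   scenario = "character"),
    validity = function(object) {
        msg <- character()
        if (length(object@rho0) != 1L || object@rho0 <= 0)
            msg <- c(msg, "rho0 must be a single positive number")
        if (any(object@values < 0))
            msg <- c(msg, "densities must be >= 0")
        if (!identical(dim(object@values), dim(object@mask@values)))
            msg <- c(msg, "density and mask grids differ in shape")
        if (length(msg)) msg else TRUE
    })

#' RadiosensitivityParams: linear-quadratic model parameters
#'
#' Radiosensitivity of the clonogen population under the linear-quadratic
#' (LQ) survival model SF(D) = exp(-alpha*D - beta*D^2). Defaults are the
#' glioma values alpha = 0.24 Gy^-1, beta = 0.03 Gy^-2. The alpha/beta
#' ratio is derived output, not an input.
#'
#' @slot alpha numeric, Gy^-1, >= 0.
#' @slot beta numeric, Gy^-2, >= 0. Not both zero.
#' @seealso [radiosensitivityParams()], [lqSurvival()]
#' @export
setClass("RadiosensitivityParams",
    representation(alpha = "numeric", beta = "numeric"),
    validity = function(object) {
        if (length(object@alpha) != 1L || length(object@beta) != 1L)
            return("alpha and beta must be single numbers")
        if (object@alpha < 0 || object@beta < 0)
            return("alpha and beta must be >= 0")
        if (object@alpha == 0 && object@beta == 0)
            return("alpha and beta cannot both be zero")
        TRUE
    })

#' InfiltrationConfig: infiltration scenario and its parameters
#'
#' Selects one of the three infiltration scenarios and fixes the cutoff
#' distance, the exponential decay length, the in-target clonogen number
#' and the random seed used by the heterogeneous scenario.
#'
#' @slot scenario \code{"none"}, \code{"continuous"} or
#'   \code{"heterogeneous"}.
#' @slot dMax maximum infiltration distance in mm (default 10): density is
#'   exactly zero wherever the distance to the target exceeds dMax.
#' @slot decayLength decay length in mm of f(d) = exp(-d/decayLength)
#'   (default 1 mm, i.e. f(d) = exp(-d) with d in mm).
#' @slot seed integer seed for the heterogeneous scenario.
#' @slot clonogens number of clonogenic cells inside the target
#'   (default 1e6).
#' @seealso [infiltrationConfig()], [clonogenDensity()]
#' @export
setClass("InfiltrationConfig",
    representation(scenario = "character", dMax = "numeric",
                   decayLength = "numeric", seed = "integer",
                   clonogens = "numeric"),
    validity = function(object) {
        msg <- character()
        if (!object@scenario %in% c("none", "continuous", "heterogeneous"))
            msg <- c(msg, "scenario must be none, continuous or heterogeneous")
        if (object@dMax <= 0) msg <- c(msg, "dMax must be > 0")
        if (object@decayLength <= 0) msg <- c(msg, "decayLength must be > 0")
        if (object@clonogens <= 0) msg <- c(msg, "clonogens must be > 0")
        if (object@scenario == "heterogeneous" && is.na(object@seed))
            msg <- c(msg, "heterogeneous scenario requires a seed")
        if (length(msg)) msg else TRUE
    })

#' ShotSpec: one Gaussian shot of a synthetic plan
#'
#' Stand-in for a radiosurgery shot: an anisotropic 3D Gaussian dose kernel
#' with centre (mm), per-axis sigma (mm) and a relative weight.
#'
#' @slot centre numeric(3) mm.
#' @slot sigma numeric(3) mm, all > 0.
#' @slot weight single positive number, relative intensity.
#' @seealso [shotSpec()], [composeDose()]
#' @export
setClass("ShotSpec",
    representation(centre = "numeric", sigma = "numeric", weight = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(object@centre) != 3L) msg <- c(msg, "centre must be length 3")
        if (length(object@sigma) != 3L || any(object@sigma <= 0))
            msg <- c(msg, "sigma must be 3 strictly positive numbers")
        if (length(object@weight) != 1L || object@weight <= 0)
            msg <- c(msg, "weight must be a single positive number")
        if (length(msg)) msg else TRUE
    })

#' PlanSpec: a synthetic Gamma-Knife-like plan
#'
#' One or more Gaussian shots plus the prescription (dose in Gy and the
#' isodose fraction it is prescribed at) and the geometry of the dose grid.
#' After normalization the maximum dose on the grid equals
#' \code{prescriptionDose / isodoseFraction} (32 Gy under the 16-Gy-at-50%
#' defaults).
#'
#' @slot shots list of [ShotSpec] (>= 1).
#' @slot prescriptionDose Gy (default 16).
#' @slot isodoseFraction in (0, 1] (default 0.5).
#' @slot shape integer(3) grid shape.
#' @slot spacing numeric(3) mm.
#' @slot origin numeric(3) mm.
#' @seealso [planSpec()], [composeDose()], [fitShotToTarget()]
#' @export
setClass("PlanSpec",
    representation(shots = "list", prescriptionDose = "numeric",
                   isodoseFraction = "numeric", shape = "integer",
                   spacing = "numeric", origin = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(object@shots) < 1L)
            msg <- c(msg, "at least one shot is required")
        if (!all(vapply(object@shots, is, logical(1), "ShotSpec")))
            msg <- c(msg, "shots must all be ShotSpec objects")
        if (object@prescriptionDose <= 0)
            msg <- c(msg, "prescriptionDose must be > 0")
        if (object@isodoseFraction <= 0 || object@isodoseFraction > 1)
            msg <- c(msg, "isodoseFraction must be in (0, 1]")
        if (length(object@shape) != 3L || any(object@shape < 1L))
            msg <- c(msg, "shape must be 3 positive integers")
        if (length(object@spacing) != 3L || any(object@spacing <= 0))
            msg <- c(msg, "spacing must be 3 positive numbers")
        if (length(object@origin) != 3L)
            msg <- c(msg, "origin must be length 3")
        if (length(msg)) msg else TRUE
    })

#' TCPResult: Poisson tumour control probability and survivor counts
#'
#' The result of [computeTCP()]: the TCP (probability that no clonogen
#' survives, exp(-expected survivors)) and the expected number of surviving
#' clonogens, split into in-target and out-of-target contributions.
#'
#' @slot tcp probability in [0, 1].
#' @slot expectedSurvivors expected surviving clonogens, >= 0.
#' @slot survivorsInTarget expected survivors on target voxels.
#' @slot survivorsOutsideTarget expected survivors elsewhere.
#' @export
setClass("TCPResult",
    representation(tcp = "numeric", expectedSurvivors = "numeric",
                   survivorsInTarget = "numeric",
                   survivorsOutsideTarget = "numeric"),
    validity = function(object) {
        msg <- character()
        if (object@tcp < 0 || object@tcp > 1)
            msg <- c(msg, "tcp must be in [0, 1]")
        if (object@expectedSurvivors < 0)
            msg <- c(msg, "expectedSurvivors must be >= 0")
        tot <- object@survivorsInTarget + object@survivorsOutsideTarget
        if (abs(tot - object@expectedSurvivors) >
            1e-9 * max(1, object@expectedSurvivors))
            msg <- c(msg, "survivor split does not sum to the total")
        if (length(msg)) msg else TRUE
    })

#' ConformityResult: coverage-type conformity index
#'
#' Ratio of the target volume covered by the prescription isodose to the
#' total target volume; in [0, 1].
#'
#' @slot ci the conformity index.
#' @slot vTarget target volume, mm^3.
#' @slot vTargetCovered target volume receiving at least the prescription
#'   dose, mm^3.
#' @slot prescriptionDose Gy.
#' @seealso [conformityIndex()]
#' @export
setClass("ConformityResult",
    representation(ci = "numeric", vTarget = "numeric",
                   vTargetCovered = "numeric", prescriptionDose = "numeric"),
    validity = function(object) {
        if (object@ci < 0 || object@ci > 1) return("ci must be in [0, 1]")
        TRUE
    })

#' EvaluationReport: per-scenario TCP report for one plan
#'
#' One row per requested infiltration scenario (TCP, expected survivors,
#' in/out-of-target split), the conformity index, the fully resolved
#' configuration (sufficient to reproduce every number) and paths of any
#' exported maps.
#'
#' @slot scenarios data.frame, one row per scenario in the order requested.
#' @slot ci a [ConformityResult].
#' @slot config resolved configuration list (echo).
#' @slot paths character vector of written artifact paths.
#' @seealso [evaluatePlan()]
#' @export
setClass("EvaluationReport",
    representation(scenarios = "data.frame", ci = "ConformityResult",
                   config = "list", paths = "character"),
    validity = function(object) {
        ok <- object@scenarios$scenario %in%
            c("none", "continuous", "heterogeneous")
        if (!all(ok)) return("unknown scenario name in report")
        TRUE
    })
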