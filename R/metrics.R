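#' Coverage-type conformity index
#'
#' The ratio of the target volume covered by the prescription isodose
#' volume to the total target volume. A target voxel counts as covered
#' when its dose is greater than or equal to the prescription dose (ties
#' at exactly the prescription count as covered).
#'
#' @param dose a [VoxelGrid3D] of dose (Gy) on the mask geometry
#'   (resample first otherwise).
#' @param mask a non-empty [StructureMask].
#' @param prescriptionDose prescription dose in Gy (> 0; default 16).
#' @return a [ConformityResult].
#' @examples
#' m <- makeEllipsoidMask(c(0, 0, 0), 10, shape = c(41, 41, 41),
#'                        spacing = 1, origin = c(-20, -20, -20))
#' plan <- fitShotToTarget(m, coverageFactor = 1.3)
#' conformity(conformityIndex(composeDose(plan), m))   # 1: full coverage
#' @export
conformityIndex <- function(dose, mask, prescriptionDose = 16) {
    stopifnot(is(dose, "VoxelGrid3D"), is(mask, "StructureMask"))
    if (prescriptionDose <= 0) stop("prescriptionDose must be > 0")
    if (nTargetVoxels(mask) < 1L) stop("empty mask")
    .stop_unless_same_geometry(dose, mask, "dose and mask")
    inT <- mask@values != 0
    vv <- voxelVolume(mask)
    v_target <- sum(inT) * vv
    v_covered <- sum(dose@values[inT] >= prescriptionDose) * vv
    new("ConformityResult", ci = v_covered / v_target, vTarget = v_target,
        vTargetCovered = v_covered, prescriptionDose = prescriptionDose)
}
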