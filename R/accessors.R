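#' Accessors for VoxelGrid3D objects
#'
#' @param x a [VoxelGrid3D] (or subclass).
#' @return `gridValues`: the 3D numeric array; `gridSpacing`, `gridOrigin`:
#'   numeric(3) in mm; `gridShape`: integer(3); `voxelVolume`: the common
#'   voxel volume in mm^3.
#' @name VoxelGrid3D-accessors
#' @aliases gridValues gridSpacing gridOrigin gridShape voxelVolume
NULL

#' @rdname VoxelGrid3D-accessors
setMethod("gridValues", "VoxelGrid3D", function(x) x@values)

#' @rdname VoxelGrid3D-accessors
setMethod("gridSpacing", "VoxelGrid3D", function(x) x@spacing)

#' @rdname VoxelGrid3D-accessors
setMethod("gridOrigin", "VoxelGrid3D", function(x) x@origin)

#' @rdname VoxelGrid3D-accessors
setMethod("gridShape", "VoxelGrid3D", function(x) dim(x@values))

#' @rdname VoxelGrid3D-accessors
setMethod("voxelVolume", "VoxelGrid3D", function(x) prod(x@spacing))

#' Accessors for StructureMask objects
#'
#' @param x a [StructureMask].
#' @return `nTargetVoxels`: the number of value-1 voxels.
#' @name StructureMask-accessors
#' @aliases nTargetVoxels
NULL

#' @rdname StructureMask-accessors
setMethod("nTargetVoxels", "StructureMask", function(x) sum(x@values != 0))

#' Accessors for ClonogenDensityMap objects
#'
#' @param x a [ClonogenDensityMap].
#' @return `rho0`: the in-target reference density (cells/mm^3);
#'   `targetMask`: the [StructureMask] the map was built from.
#' @name ClonogenDensityMap-accessors
#' @aliases rho0 targetMask
NULL

#' @rdname ClonogenDensityMap-accessors
setMethod("rho0", "ClonogenDensityMap", function(x) x@rho0)

#' @rdname ClonogenDensityMap-accessors
setMethod("targetMask", "ClonogenDensityMap", function(x) x@mask)

#' Accessors for TCPResult objects
#'
#' @param x a [TCPResult].
#' @param digits decimals for `tcpPercent` (default 1; use 0 for the
#'   integer-percent presentation of scenario tables).
#' @return `tcp`: probability in [0, 1]; `tcpPercent`: the same on the
#'   percent scale, rounded; `expectedSurvivors`: the Poisson mean.
#' @name TCPResult-accessors
#' @aliases tcp tcpPercent expectedSurvivors
NULL

#' @rdname TCPResult-accessors
setMethod("tcp", "TCPResult", function(x) x@tcp)

#' @rdname TCPResult-accessors
setMethod("tcpPercent", "TCPResult",
    function(x, digits = 1) round(100 * x@tcp, digits))

#' @rdname TCPResult-accessors
setMethod("expectedSurvivors", "TCPResult", function(x) x@expectedSurvivors)

#' Accessors for ConformityResult objects
#'
#' @param x a [ConformityResult].
#' @return `conformity`: the conformity index in [0, 1].
#' @name ConformityResult-accessors
#' @aliases conformity
NULL

#' @rdname ConformityResult-accessors
setMethod("conformity", "ConformityResult", function(x) x@ci)

#' Accessors for RadiosensitivityParams objects
#'
#' @param x a [RadiosensitivityParams].
#' @return `alphaBeta`: the derived alpha/beta ratio in Gy (Inf when
#'   beta = 0).
#' @name RadiosensitivityParams-accessors
#' @aliases alphaBeta
NULL

#' @rdname RadiosensitivityParams-accessors
setMethod("alphaBeta", "RadiosensitivityParams",
    function(x) x@alpha / x@beta)

setMethod("show", "VoxelGrid3D", function(object) {
    d <- dim(object@values)
    cat(sprintf("%s: %d x %d x %d voxels\n", class(object), d[1], d[2], d[3]))
    cat(sprintf("  spacing: %s mm; origin: %s mm\n",
        paste(format(object@spacing), collapse = " x "),
        paste(format(object@origin), collapse = ", ")))
    rng <- range(object@values)
    cat(sprintf("  values in [%g, %g]\n", rng[1], rng[2]))
})

setMethod("show", "StructureMask", function(object) {
    d <- dim(object@values)
    cat(sprintf("StructureMask: %d x %d x %d voxels, %d in target (%.1f mm^3)\n",
        d[1], d[2], d[3], nTargetVoxels(object),
        nTargetVoxels(object) * prod(object@spacing)))
})

setMethod("show", "ClonogenDensityMap", function(object) {
    d <- dim(object@values)
    cat(sprintf(
        "ClonogenDensityMap (%s): %d x %d x %d voxels, rho0 = %.4g cells/mm^3\n",
        object@scenario, d[1], d[2], d[3], object@rho0))
    cat(sprintf("  total cells: %.6g\n",
        sum(object@values) * prod(object@spacing)))
})

setMethod("show", "TCPResult", function(object) {
    cat(sprintf("TCPResult: TCP = %.6g (%.1f%%)\n",
        object@tcp, 100 * object@tcp))
    cat(sprintf(
        "  expected survivors: %.6g (in target %.6g, outside %.6g)\n",
        object@expectedSurvivors, object@survivorsInTarget,
        object@survivorsOutsideTarget))
})

setMethod("show", "ConformityResult", function(object) {
    cat(sprintf(
        "ConformityResult: CI = %.3f (%.1f of %.1f mm^3 covered at %g Gy)\n",
        object@ci, object@vTargetCovered, object@vTarget,
        object@prescriptionDose))
})

setMethod("show", "RadiosensitivityParams", function(object) {
    cat(sprintf(
        "RadiosensitivityParams: alpha = %g Gy^-1, beta = %g Gy^-2 (alpha/beta = %.3g Gy)\n",
        object@alpha, object@beta, object@alpha / object@beta))
})

setMethod("show", "InfiltrationConfig", function(object) {
    cat(sprintf(
        "InfiltrationConfig: scenario = %s, dMax = %g mm, decayLength = %g mm, clonogens = %g\n",
        object@scenario, object@dMax, object@decayLength, object@clonogens))
    if (!is.na(object@seed)) cat(sprintf("  seed = %d\n", object@seed))
})

setMethod("show", "PlanSpec", function(object) {
    cat(sprintf(
        "PlanSpec: %d shot(s), %g Gy at the %g%% isodose (max %g Gy)\n",
        length(object@shots), object@prescriptionDose,
        100 * object@isodoseFraction,
        object@prescriptionDose / object@isodoseFraction))
    cat(sprintf("  grid: %s voxels at %s mm\n",
        paste(object@shape, collapse = " x "),
        paste(format(object@spacing), collapse = " x ")))
})

setMethod("show", "EvaluationReport", function(object) {
    cat("EvaluationReport\n")
    cat(sprintf("  CI = %.3f at %g Gy\n", object@ci@ci,
        object@ci@prescriptionDose))
    print(object@scenarios, row.names = FALSE)
})
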