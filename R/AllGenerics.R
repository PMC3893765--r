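#' @rdname VoxelGrid3D-accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname VoxelGrid3D-accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname VoxelGrid3D-accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname VoxelGrid3D-accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname VoxelGrid3D-accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname StructureMask-accessors
#' @export
setGeneric("nTargetVoxels", function(x) standardGeneric("nTargetVoxels"))

#' @rdname ClonogenDensityMap-accessors
#' @export
setGeneric("rho0", function(x) standardGeneric("rho0"))

#' @rdname ClonogenDensityMap-accessors
#' @export
setGeneric("targetMask", function(x) standardGeneric("targetMask"))

#' @rdname TCPResult-accessors
#' @export
setGeneric("tcp", function(x) standardGeneric("tcp"))

#' @rdname TCPResult-accessors
#' @export
setGeneric("tcpPercent", function(x, digits = 1) standardGeneric("tcpPercent"))

#' @rdname TCPResult-accessors
#' @export
setGeneric("expectedSurvivors", function(x) standardGeneric("expectedSurvivors"))

#' @rdname ConformityResult-accessors
#' @export
setGeneric("conformity", function(x) standardGeneric("conformity"))

#' @rdname RadiosensitivityParams-accessors
#' @export
setGeneric("alphaBeta", function(x) standardGeneric("alphaBeta"))
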