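# Grid geometry helpers ------------------------------------------------

# physical coordinates of voxel centres along one axis (mm)
.axis_coords <- function(grid, axis) {
    n <- dim(grid@values)[axis]
    grid@origin[axis] + (seq_len(n) - 1) * grid@spacing[axis]
}

.same_geometry <- function(a, b, tol = 1e-9) {
    identical(dim(a@values), dim(b@values)) &&
        all(abs(a@spacing - b@spacing) <= tol) &&
        all(abs(a@origin - b@origin) <= tol)
}

.stop_unless_same_geometry <- function(a, b, what) {
    if (!.same_geometry(a, b))
        stop("grid mismatch: ", what,
             " must share shape, spacing and origin")
    invisible(TRUE)
}

# Raster I/O ------------------------------------------------------------

#' Read a 3D raster into a VoxelGrid3D
#'
#' Reads NRRD (attached raw, gzip or ascii data) or NIfTI files. The file
#' must be 3D and must carry voxel spacing in its metadata; anything else
#' fails loudly. For NIfTI, the grid origin is taken from the translation
#' part of the stored transform and the axes are required to be grid
#' aligned (no oblique orientations).
#'
#' @param path file path (.nrrd, .nii or .nii.gz).
#' @param format \code{"auto"} (by extension), \code{"nrrd"} or
#'   \code{"nifti"}.
#' @return a [VoxelGrid3D].
#' @seealso [writeGrid()]
#' @export
readGrid <- function(path, format = c("auto", "nrrd", "nifti")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "auto") {
        format <- if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
            else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
            else stop("unsupported format for ", path,
                      " (expected .nrrd, .nii or .nii.gz)")
    }
    if (format == "nrrd") return(.read_nrrd(path))
    img <- RNifti::readNifti(path)
    vals <- as.array(img)
    if (length(dim(vals)) != 3L)
        stop("non-3D data: NIfTI image has ", length(dim(vals)), " dimensions")
    spacing <- RNifti::pixdim(img)[1:3]
    if (any(!is.finite(spacing)) || any(spacing <= 0))
        stop("non-positive spacing in NIfTI header")
    xf <- RNifti::xform(img)
    rot <- abs(xf[1:3, 1:3])
    if (any(rot - diag(diag(rot)) > 1e-6 * max(rot)))
        stop("oblique NIfTI orientations are not supported")
    origin <- as.numeric(xf[1:3, 4])
    voxelGrid3D(array(as.numeric(vals), dim = dim(vals)),
                spacing = as.numeric(spacing), origin = origin)
}

#' Write a VoxelGrid3D as NRRD
#'
#' Writes an NRRD0004 file with axis-aligned \code{space directions} and
#' \code{space origin} so that spacing and origin round-trip exactly.
#'
#' @param grid a [VoxelGrid3D].
#' @param path output path (.nrrd).
#' @param encoding \code{"raw"} (little-endian double, default) or
#'   \code{"ascii"}.
#' @return the path, invisibly.
#' @export
writeGrid <- function(grid, path, encoding = c("raw", "ascii")) {
    stopifnot(is(grid, "VoxelGrid3D"))
    .write_nrrd(grid, path, match.arg(encoding))
}

# Resampling ------------------------------------------------------------

#' Resample a dose grid onto a structure grid
#'
#' Redefines a dose distribution on the geometry (shape, spacing, origin)
#' of the structure grid by trilinear interpolation at the structure voxel
#' centres. Trilinear interpolation is exact for affine dose fields.
#' Structure voxel centres falling outside the dose grid's physical extent
#' receive 0 Gy (SRS dose grids are local; surrounding tissue receives
#' negligible dose); a warning reports how many voxels were zero-filled.
#'
#' @param dose a [VoxelGrid3D] of dose values (Gy).
#' @param structureGrid a [VoxelGrid3D] (or [StructureMask]) defining the
#'   output geometry.
#' @return a [VoxelGrid3D] of dose on the structure geometry.
#' @export
resampleDoseToStructure <- function(dose, structureGrid) {
    stopifnot(is(dose, "VoxelGrid3D"), is(structureGrid, "VoxelGrid3D"))
    if (.same_geometry(dose, structureGrid)) {
        return(voxelGrid3D(dose@values, spacing = structureGrid@spacing,
                           origin = structureGrid@origin))
    }
    nd <- dim(dose@values)
    # fractional 0-based index of each structure voxel centre per axis
    tfrac <- lapply(1:3, function(a)
        (.axis_coords(structureGrid, a) - dose@origin[a]) / dose@spacing[a])
    eps <- 1e-9
    inside <- lapply(1:3, function(a)
        tfrac[[a]] >= -eps & tfrac[[a]] <= (nd[a] - 1) + eps)
    if (!any(inside[[1]]) || !any(inside[[2]]) || !any(inside[[3]]))
        stop("disjoint physical extents: structure grid does not overlap ",
             "the dose grid")
    # lower corner index (1-based), clamped so i0+1 stays in range
    i0 <- lapply(1:3, function(a) {
        i <- floor(tfrac[[a]]) + 1
        pmin(pmax(i, 1L), max(nd[a] - 1L, 1L))
    })
    fr <- lapply(1:3, function(a) {
        f <- tfrac[[a]] - (i0[[a]] - 1)
        pmin(pmax(f, 0), 1)
    })
    ns <- dim(structureGrid@values)
    out <- array(0, dim = ns)
    V <- dose@values
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
        wx <- if (a == 0) 1 - fr[[1]] else fr[[1]]
        wy <- if (b == 0) 1 - fr[[2]] else fr[[2]]
        wz <- if (cc == 0) 1 - fr[[3]] else fr[[3]]
        ix <- pmin(i0[[1]] + a, nd[1])
        iy <- pmin(i0[[2]] + b, nd[2])
        iz <- pmin(i0[[3]] + cc, nd[3])
        w <- outer(outer(wx, wy), wz)
        out <- out + w * V[ix, iy, iz, drop = FALSE]
    }
    keep <- outer(outer(inside[[1]], inside[[2]]), inside[[3]])
    nout <- sum(!keep)
    if (nout > 0) {
        out[!keep] <- 0
        warning(nout, " structure voxel centre(s) outside the dose grid ",
                "extent were assigned 0 Gy")
    }
    voxelGrid3D(out, spacing = structureGrid@spacing,
                origin = structureGrid@origin)
}

# Distance map ----------------------------------------------------------

#' Euclidean distance map to the target
#'
#' For every voxel centre, the Euclidean distance in mm (respecting
#' anisotropic spacing) to the centre of the nearest target voxel; exactly
#' 0 on target voxels. Computed with the exact separable lower-envelope
#' distance transform.
#'
#' @param mask a [StructureMask] with at least one target voxel.
#' @return a [DistanceMap] on the mask geometry.
#' @export
distanceToTarget <- function(mask) {
    stopifnot(is(mask, "StructureMask"))
    if (nTargetVoxels(mask) < 1L)
        stop("empty mask: the target has no voxels")
    d2 <- .edt3d_sq(as.numeric(mask@values), dim(mask@values), mask@spacing)
    new("DistanceMap", values = array(sqrt(d2), dim = dim(mask@values)),
        spacing = mask@spacing, origin = mask@origin)
}

# Volumes ---------------------------------------------------------------

#' Volume of a structure mask
#'
#' Number of target voxels times the voxel volume.
#'
#' @param mask a [StructureMask].
#' @return volume in mm^3.
#' @export
maskedVolume <- function(mask) {
    stopifnot(is(mask, "StructureMask"))
    nTargetVoxels(mask) * voxelVolume(mask)
}
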