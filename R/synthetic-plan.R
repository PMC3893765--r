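# Synthetic Gamma-Knife-like plans: ellipsoidal targets and Gaussian-shot
# dose fields normalized to the prescription at a given isodose fraction.

#' Rasterize an ellipsoid target mask
#'
#' A voxel belongs to the target iff its centre satisfies the ellipsoid
#' inequality sum(((x_i - c_i) / a_i)^2) <= 1.
#'
#' @param centre ellipsoid centre (x, y, z), mm.
#' @param semiAxes semi-axes (a, b, c), mm, all > 0; a scalar gives a
#'   sphere.
#' @param shape grid shape (nx, ny, nz).
#' @param spacing voxel spacing, mm (scalar recycled).
#' @param origin centre of the first voxel, mm.
#' @return a [StructureMask].
#' @examples
#' m <- makeEllipsoidMask(c(0, 0, 0), 10, shape = c(25, 25, 25),
#'                        spacing = 1, origin = c(-12, -12, -12))
#' maskedVolume(m)   # close to 4/3 * pi * 10^3
#' @export
makeEllipsoidMask <- function(centre, semiAxes, shape, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0)) {
    if (length(semiAxes) == 1L) semiAxes <- rep(semiAxes, 3L)
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    stopifnot(all(semiAxes > 0), all(spacing > 0), length(shape) == 3L)
    ref <- voxelGrid3D(array(0, dim = shape), spacing = spacing,
                       origin = origin)
    q <- lapply(1:3, function(a)
        ((.axis_coords(ref, a) - centre[a]) / semiAxes[a])^2)
    s <- outer(outer(q[[1]], q[[2]], "+"), q[[3]], "+")
    inside <- s <= 1
    if (!any(inside))
        stop("empty mask: the ellipsoid contains no voxel centre of the grid")
    structureMask(array(as.numeric(inside), dim = shape), spacing = spacing,
                  origin = origin)
}

#' Compose the dose field of a synthetic plan
#'
#' The raw field is the weighted sum of the plan's Gaussian shots evaluated
#' at voxel centres; it is then scaled so the grid maximum equals
#' prescriptionDose / isodoseFraction (32 Gy for 16 Gy prescribed at the
#' 50\% isodose). Normalizing to the grid maximum mirrors what a treatment
#' planning system export contains.
#'
#' @param plan a [PlanSpec].
#' @return a [VoxelGrid3D] of dose in Gy.
#' @export
composeDose <- function(plan) {
    stopifnot(is(plan, "PlanSpec"))
    ref <- voxelGrid3D(array(0, dim = plan@shape), spacing = plan@spacing,
                       origin = plan@origin)
    raw <- array(0, dim = plan@shape)
    for (shot in plan@shots) {
        g <- lapply(1:3, function(a)
            exp(-(.axis_coords(ref, a) - shot@centre[a])^2 /
                    (2 * shot@sigma[a]^2)))
        raw <- raw + shot@weight * outer(outer(g[[1]], g[[2]]), g[[3]])
    }
    mx <- max(raw)
    if (!is.finite(mx) || mx <= 0)
        stop("all-zero raw dose field: no shot contributes on the grid")
    dmax <- plan@prescriptionDose / plan@isodoseFraction
    voxelGrid3D(raw * (dmax / mx), spacing = plan@spacing,
                origin = plan@origin)
}

#' Fit a single isotropic shot to a target
#'
#' Returns a single-shot plan centred at the target centroid whose
#' prescription isodose surface is a sphere of radius
#' \code{coverageFactor} times the target's equivalent-sphere radius.
#' For a Gaussian shot with maximum Dmax = prescriptionDose/isodoseFraction
#' the prescription isodose radius is sigma * sqrt(2 * log(1/isodoseFraction)),
#' which fixes sigma. Factors > 1 produce plans with margin (the whole
#' target above prescription), factors < 1 under-covering plans.
#'
#' @param mask a non-empty [StructureMask].
#' @param coverageFactor ratio of prescription isodose radius to the
#'   target's equivalent-sphere radius (default 1).
#' @param prescriptionDose Gy (default 16).
#' @param isodoseFraction in (0, 1) (default 0.5).
#' @return a [PlanSpec] on the mask's grid geometry.
#' @export
fitShotToTarget <- function(mask, coverageFactor = 1, prescriptionDose = 16,
                            isodoseFraction = 0.5) {
    stopifnot(is(mask, "StructureMask"))
    if (nTargetVoxels(mask) < 1L) stop("empty mask")
    if (isodoseFraction <= 0 || isodoseFraction >= 1)
        stop("isodoseFraction must be in (0, 1) to define an isodose radius")
    idx <- which(mask@values != 0, arr.ind = TRUE)
    centroid <- vapply(1:3, function(a)
        mean(mask@origin[a] + (idx[, a] - 1) * mask@spacing[a]), numeric(1))
    vol <- maskedVolume(mask)
    rEq <- (3 * vol / (4 * pi))^(1 / 3)
    rIso <- coverageFactor * rEq
    sigma <- rIso / sqrt(2 * log(1 / isodoseFraction))
    planSpec(shotSpec(centroid, sigma), prescriptionDose = prescriptionDose,
             isodoseFraction = isodoseFraction, shape = dim(mask@values),
             spacing = mask@spacing, origin = mask@origin)
}
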