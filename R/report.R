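# End-to-end plan evaluation: resampling -> distance map -> per-scenario
# clonogen density -> TCP, plus the conformity index, assembled into an
# EvaluationReport and optionally written to disk as JSON + CSV (+ NRRD
# maps).

.default_config <- function() {
    list(
        prescription = list(dose_gy = 16, isodose_fraction = 0.5),
        radiobiology = list(alpha = 0.24, beta = 0.03, clonogens = 1e6),
        infiltration = list(d_max_mm = 10, decay_length_mm = 1, seed = 1L),
        output = list(maps = FALSE, rounding = 0L))
}

# deep-merge user config over defaults
.merge_config <- function(user, base = .default_config()) {
    for (k in names(user)) {
        if (is.list(user[[k]]) && is.list(base[[k]]))
            base[[k]] <- .merge_config(user[[k]], base[[k]])
        else base[[k]] <- user[[k]]
    }
    base
}

.load_config <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    if (!is.list(config)) stop("config must be a list or a YAML file path")
    .merge_config(config)
}

.as_mask <- function(x) {
    if (is(x, "StructureMask")) return(x)
    if (is.character(x)) x <- readGrid(x)
    if (is(x, "VoxelGrid3D")) {
        v <- x@values
        if (!all(v %in% c(0, 1))) {
            if (all(abs(v - round(v)) < 1e-6) && all(round(v) %in% c(0, 1)))
                v <- round(v)
            else stop("target grid is not a binary mask")
        }
        return(structureMask(array(as.numeric(v), dim = dim(v)),
                             spacing = x@spacing, origin = x@origin))
    }
    stop("cannot interpret target input of class ", class(x)[1])
}

.as_dose <- function(x) {
    if (is(x, "PlanSpec")) return(composeDose(x))
    if (is.character(x)) return(readGrid(x))
    if (is(x, "VoxelGrid3D")) return(x)
    stop("cannot interpret dose input of class ", class(x)[1])
}

#' Evaluate a radiosurgery plan under infiltration scenarios
#'
#' Runs the full pipeline: the dose is resampled onto the target grid, the
#' distance map computed, a clonogen-density map built per requested
#' scenario, and the Poisson TCP and the conformity index evaluated. For
#' the heterogeneous scenario with \code{replicates > 1}, seeds
#' \code{seed, seed+1, ...} are used and the row reports the mean TCP with
#' its standard deviation.
#'
#' @param dose a [VoxelGrid3D], a [PlanSpec] (composed on the fly) or the
#'   path of an NRRD/NIfTI dose file.
#' @param target a [StructureMask], binary [VoxelGrid3D] or mask file path.
#' @param config a configuration list or YAML file path with (optional)
#'   blocks \code{prescription\{dose_gy, isodose_fraction\}},
#'   \code{radiobiology\{alpha, beta, clonogens\}},
#'   \code{infiltration\{d_max_mm, decay_length_mm, seed\}},
#'   \code{output\{maps, rounding\}}; missing entries take the package
#'   defaults (16 Gy at 50\%, alpha 0.24, beta 0.03, 1e6 clonogens,
#'   10 mm cutoff, 1 mm decay length).
#' @param scenarios character vector of scenarios to evaluate, in report
#'   order; subset of \code{c("none", "continuous", "heterogeneous")}.
#' @param replicates number of seeds for the heterogeneous scenario
#'   (default 1).
#' @param outDir if non-NULL, write \code{report.json}, \code{report.csv}
#'   and (when \code{output$maps} is TRUE) the resampled dose, distance,
#'   survival and density maps as NRRD into this directory.
#' @param verbose emit key=value progress messages (default TRUE).
#' @return an [EvaluationReport].
#' @export
evaluatePlan <- function(dose, target, config = list(),
                         scenarios = c("none", "continuous",
                                       "heterogeneous"),
                         replicates = 1L, outDir = NULL, verbose = TRUE) {
    if (length(scenarios) < 1L)
        stop("no scenarios requested")
    bad <- setdiff(scenarios, c("none", "continuous", "heterogeneous"))
    if (length(bad))
        stop("unknown scenario name: ", paste(bad, collapse = ", "))
    cfg <- .load_config(config)
    mask <- .as_mask(target)
    dose_raw <- .as_dose(dose)
    dose_g <- resampleDoseToStructure(dose_raw, mask)
    params <- radiosensitivityParams(cfg$radiobiology$alpha,
                                     cfg$radiobiology$beta)
    note <- function(...) if (verbose) message(sprintf(...))
    note("n_voxels=%d n_target_voxels=%d target_volume_mm3=%.1f",
         length(mask@values), nTargetVoxels(mask), maskedVolume(mask))
    note("min_dose=%.3f max_dose=%.3f total_cells_in_target=%g",
         min(dose_g@values), max(dose_g@values), cfg$radiobiology$clonogens)

    dmap <- if (any(scenarios != "none")) distanceToTarget(mask) else NULL
    mkcfg <- function(scn, seed)
        infiltrationConfig(scn, dMax = cfg$infiltration$d_max_mm,
                           decayLength = cfg$infiltration$decay_length_mm,
                           seed = seed,
                           clonogens = cfg$radiobiology$clonogens)

    rows <- lapply(scenarios, function(scn) {
        if (scn == "heterogeneous" && replicates > 1L) {
            seeds <- as.integer(cfg$infiltration$seed) + seq_len(replicates) - 1L
            res <- lapply(seeds, function(s)
                computeTCP(dose_g,
                           clonogenDensity(mask, dmap, mkcfg(scn, s)),
                           params))
            tcps <- vapply(res, tcp, numeric(1))
            surv <- vapply(res, expectedSurvivors, numeric(1))
            data.frame(scenario = scn, tcp = mean(tcps),
                       tcp_sd = sd(tcps),
                       expected_survivors = mean(surv),
                       survivors_in_target =
                           mean(vapply(res, function(r)
                               r@survivorsInTarget, numeric(1))),
                       survivors_outside_target =
                           mean(vapply(res, function(r)
                               r@survivorsOutsideTarget, numeric(1))))
        } else {
            r <- computeTCP(dose_g,
                            clonogenDensity(mask, dmap,
                                mkcfg(scn, cfg$infiltration$seed)),
                            params)
            data.frame(scenario = scn, tcp = tcp(r), tcp_sd = NA_real_,
                       expected_survivors = expectedSurvivors(r),
                       survivors_in_target = r@survivorsInTarget,
                       survivors_outside_target = r@survivorsOutsideTarget)
        }
    })
    tab <- do.call(rbind, rows)
    tab$tcp_percent <- round(100 * tab$tcp, 1)
    tab$tcp_percent_int <- as.integer(round(100 * tab$tcp))
    for (i in seq_len(nrow(tab)))
        note("scenario=%s tcp=%.6g tcp_percent_int=%d survivors=%.6g",
             tab$scenario[i], tab$tcp[i], tab$tcp_percent_int[i],
             tab$expected_survivors[i])

    ci <- conformityIndex(dose_g, mask, cfg$prescription$dose_gy)
    note("ci=%.4f", conformity(ci))

    echo <- cfg
    echo$scenarios <- scenarios
    echo$replicates <- replicates
    paths <- character()
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        jpath <- file.path(outDir, "report.json")
        cpath <- file.path(outDir, "report.csv")
        jsonlite::write_json(list(
            scenarios = tab,
            conformity = list(ci = conformity(ci), v_target = ci@vTarget,
                              v_target_covered = ci@vTargetCovered,
                              prescription_dose = ci@prescriptionDose),
            config = echo), jpath, auto_unbox = TRUE, digits = NA,
            pretty = TRUE)
        write.csv(tab, cpath, row.names = FALSE)
        paths <- c(jpath, cpath)
        if (isTRUE(cfg$output$maps)) {
            mp <- c(dose = "dose_resampled.nrrd", distance = "distance.nrrd",
                    survival = "survival.nrrd")
            writeGrid(dose_g, file.path(outDir, mp["dose"]))
            if (!is.null(dmap)) writeGrid(dmap, file.path(outDir, mp["distance"]))
            writeGrid(survivalMap(dose_g, params),
                      file.path(outDir, mp["survival"]))
            paths <- c(paths, file.path(outDir,
                mp[c(TRUE, !is.null(dmap), TRUE)]))
        }
    }
    new("EvaluationReport", scenarios = tab, ci = ci, config = echo,
        paths = paths)
}

#' Generate a deterministic synthetic plan fixture on disk
#'
#' Writes a dose grid, a target mask (both NRRD) and a YAML configuration
#' for one of the built-in presets. Output bytes are identical for
#' identical preset and seed.
#'
#' \describe{
#'   \item{sphere-conformal}{10 mm sphere, single shot, prescription
#'     isodose exactly at the target surface (coverage factor 1.0).}
#'   \item{sphere-margin}{10 mm sphere, coverage factor 1.4: the whole
#'     target sits well above the prescription dose (minimum target dose
#'     above 22 Gy).}
#'   \item{ellipsoid-undercovered}{12 x 10 x 8 mm ellipsoid, coverage
#'     factor 0.8: part of the target falls below prescription.}
#' }
#'
#' @param preset preset name (see Details).
#' @param outDir output directory (created if needed).
#' @param seed integer seed recorded in the config for the heterogeneous
#'   scenario.
#' @return invisibly, a named list of written paths (dose, mask, config).
#' @export
generateFixture <- function(preset = c("sphere-conformal", "sphere-margin",
                                       "ellipsoid-undercovered"),
                            outDir, seed = 1L) {
    preset <- match.arg(preset)
    geom <- list(shape = c(55L, 55L, 55L), spacing = c(1, 1, 1),
                 origin = c(-27, -27, -27))
    spec <- switch(preset,
        "sphere-conformal" = list(semi = c(10, 10, 10), cf = 1.0),
        "sphere-margin" = list(semi = c(10, 10, 10), cf = 1.4),
        "ellipsoid-undercovered" = list(semi = c(12, 10, 8), cf = 0.8))
    mask <- makeEllipsoidMask(c(0, 0, 0), spec$semi, shape = geom$shape,
                              spacing = geom$spacing, origin = geom$origin)
    plan <- fitShotToTarget(mask, coverageFactor = spec$cf)
    dose <- composeDose(plan)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(dose = file.path(outDir, "dose.nrrd"),
                  mask = file.path(outDir, "mask.nrrd"),
                  config = file.path(outDir, "config.yaml"))
    writeGrid(dose, paths$dose)
    writeGrid(mask, paths$mask)
    cfg <- .default_config()
    cfg$infiltration$seed <- as.integer(seed)
    cfg$preset <- preset
    cfg$coverage_factor <- spec$cf
    yaml::write_yaml(cfg, paths$config)
    invisible(paths)
}
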