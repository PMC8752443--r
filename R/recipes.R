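## Experiment recipes: named bundles of simulation conditions, replicates
## and analyses, run to a deterministic output directory tree.

.recipeAnalyses <- c("composition", "slice", "hotspots", "timecourse")

#' Define an experiment recipe
#'
#' A recipe enumerates a grid of simulation conditions (growth modes x
#' driver acquisition probabilities x necrosis settings), a replicate
#' count, and the analyses to run on each simulation. Replicate seeds are
#' enumerated deterministically from the master seed (consecutive
#' integers in run order).
#'
#' @param name recipe name (used in output paths).
#' @param baseConfig a [SimulationConfig-class] supplying all parameters
#'   not varied by the grid.
#' @param growthModes character vector of growth modes.
#' @param pDrivers numeric vector of driver acquisition probabilities.
#' @param necrosis logical vector of necrosis settings.
#' @param replicates replicate simulations per condition.
#' @param analyses subset of \code{c("composition", "slice", "hotspots",
#'   "timecourse")}.
#' @param masterSeed master seed; run i uses seed masterSeed + i - 1.
#' @return list of class \code{ExperimentRecipe}.
#' @export
experimentRecipe <- function(name, baseConfig, growthModes = "surface",
                             pDrivers = 2e-4, necrosis = FALSE,
                             replicates = 1, analyses = "composition",
                             masterSeed = 1) {
  unknown <- setdiff(analyses, .recipeAnalyses)
  if (length(unknown))
    stop("unknown analysis name(s): ", paste(unknown, collapse = ", "))
  stopifnot(all(growthModes %in% c("surface", "volume")), replicates >= 1)
  structure(list(name = name, baseConfig = baseConfig,
                 growthModes = growthModes, pDrivers = pDrivers,
                 necrosis = necrosis, replicates = as.integer(replicates),
                 analyses = analyses, masterSeed = as.integer(masterSeed)),
            class = "ExperimentRecipe")
}

#' Run an experiment recipe
#'
#' Executes every (growth mode, pDriver, necrosis, replicate) combination,
#' writing per-run step logs, snapshots (if the base configuration
#' requests them) and an aggregated metrics CSV. Runs are conditioned on
#' non-extinction via [runUntilEstablished()]. Failures of individual runs
#' are collected and reported at the end instead of aborting the grid.
#'
#' @param recipe an \code{ExperimentRecipe}.
#' @param outDir output directory (created if needed).
#' @return Invisibly, the aggregated metrics data.frame; attribute
#'   \code{failures} lists failed runs, if any.
#' @export
runRecipe <- function(recipe, outDir) {
  stopifnot(inherits(recipe, "ExperimentRecipe"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  grid <- expand.grid(growthMode = recipe$growthModes,
                      pDriver = recipe$pDrivers,
                      necrosis = recipe$necrosis,
                      replicate = seq_len(recipe$replicates),
                      stringsAsFactors = FALSE)
  manifest <- list(recipe = recipe$name, masterSeed = recipe$masterSeed,
                   rng = recipe$baseConfig@rngKind,
                   package = "cloneCA",
                   version = as.character(utils::packageVersion("cloneCA")),
                   conditions = nrow(grid))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(outDir, "manifest.json"))
  rows <- list()
  failures <- list()
  for (i in seq_len(nrow(grid))) {
    cfg <- recipe$baseConfig
    cfg@growthMode <- grid$growthMode[i]
    cfg@pDriver <- grid$pDriver[i]
    cfg@necrosisEnabled <- grid$necrosis[i]
    cfg@seed <- as.integer(recipe$masterSeed + i - 1L)
    runDir <- file.path(outDir, sprintf("run_%03d", i))
    dir.create(runDir, showWarnings = FALSE)
    res <- tryCatch({
      out <- runUntilEstablished(cfg)
      st <- out$state
      write.table(st@log, file.path(runDir, "steps.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      if (cfg@snapshotEvery > 0L)
        for (s in seq_along(out$snapshots))
          writeSnapshot(out$snapshots[[s]],
                        file.path(runDir, sprintf("snapshot_%04d.tsv",
                                                  out$snapshots[[s]]@step)))
      row <- data.frame(run = i, growth_mode = cfg@growthMode,
                        p_driver = cfg@pDriver,
                        necrosis = cfg@necrosisEnabled, seed = out$seed,
                        steps = st@step, n_voxels = nVoxels(st),
                        n_clones = nrow(st@clones))
      if ("composition" %in% recipe$analyses) {
        comp <- composition(st)
        row$n_detectable <- nrow(detectableClones(comp))
        row$shannon <- shannonIndex(comp)
        row$ccf_parental <- comp$ccf[comp$clone_id == 1L][1]
        writeComposition(comp, file.path(runDir, "composition.csv"))
      }
      if (any(c("slice", "hotspots") %in% recipe$analyses)) {
        sl <- extractSlice(st)
        row$mean_fitness <- tumourFitness(sl)
        row$mean_drivers <- meanDrivers(sl)
        row$circularity <- if (nrow(sl@contour) >= 3L) circularity(sl)
                           else NA_real_
        if ("hotspots" %in% recipe$analyses) {
          hs <- hotspotsAndDistances(microdiversityMap(sl), sl)
          row$n_hotspots <- nrow(hs)
          utils::write.csv(hs, file.path(runDir, "hotspots.csv"),
                           row.names = FALSE)
        }
      }
      if ("timecourse" %in% recipe$analyses && length(out$snapshots)) {
        tc <- timeCourse(out$snapshots)
        utils::write.csv(tc, file.path(runDir, "timecourse.csv"),
                         row.names = FALSE)
      }
      row
    }, error = function(e) e)
    if (inherits(res, "error"))
      failures[[length(failures) + 1L]] <- list(run = i,
                                                message = conditionMessage(res))
    else rows[[length(rows) + 1L]] <- res
  }
  agg <- if (length(rows))
    do.call(rbind, lapply(rows, function(r) {
      all <- unique(unlist(lapply(rows, names)))
      r[setdiff(all, names(r))] <- NA
      r[all]
    })) else data.frame()
  utils::write.csv(agg, file.path(outDir, "metrics.csv"), row.names = FALSE)
  if (length(failures))
    warning(length(failures), " run(s) failed; see attr(, 'failures')")
  attr(agg, "failures") <- failures
  invisible(agg)
}
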