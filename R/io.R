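## Snapshots and serialisation: lossless TSV + JSON-sidecar round trips,
## and JSON simulation configurations.

## genotype bitmask over panel order, hex encoded (LSB = event 1)
.genoHex <- function(pres) {
  n8 <- as.integer(ceiling(length(pres) / 8) * 8)
  r <- packBits(c(as.logical(pres), rep(FALSE, n8 - length(pres))), "raw")
  paste(sprintf("%02x", as.integer(r)), collapse = "")
}

.genoFromHex <- function(hex, nev) {
  r <- as.raw(strtoi(substring(hex, seq(1, nchar(hex), 2),
                               seq(2, nchar(hex), 2)), 16L))
  as.logical(rawToBits(r))[seq_len(nev)]
}

.configToList <- function(config) {
  adv <- config@advantage
  list(L = config@L, pDeath = config@pDeath, pDriver = config@pDriver,
       growthMode = config@growthMode,
       necrosisEnabled = config@necrosisEnabled,
       pNecrosis = config@pNecrosis, dNecrosis = config@dNecrosis,
       stopSize = config@stopSize, maxSteps = config@maxSteps,
       seed = config@seed, snapshotEvery = config@snapshotEvery,
       rngKind = config@rngKind,
       advantage = list(model = adv@model, s = adv@s, pInit = adv@pInit,
                        minSk = adv@minSk, deltaSk = adv@deltaSk),
       panel = config@panel@events)
}

.configFromList <- function(x) {
  adv <- new("AdvantageModel", model = x$advantage$model,
             s = x$advantage$s, pInit = x$advantage$pInit,
             minSk = x$advantage$minSk, deltaSk = x$advantage$deltaSk)
  ev <- as.data.frame(x$panel)
  ev$id <- as.integer(ev$id)
  ev$rank <- as.integer(ev$rank)
  panel <- new("DriverPanel", events = ev)
  validObject(panel)
  simulationConfig(L = x$L, pDeath = x$pDeath, pDriver = x$pDriver,
                   growthMode = x$growthMode, advantage = adv, panel = panel,
                   necrosisEnabled = x$necrosisEnabled,
                   pNecrosis = x$pNecrosis, dNecrosis = x$dNecrosis,
                   stopSize = x$stopSize, maxSteps = x$maxSteps,
                   seed = x$seed, snapshotEvery = x$snapshotEvery,
                   rngKind = x$rngKind)
}

.configJSON <- function(config)
  as.character(jsonlite::toJSON(.configToList(config), auto_unbox = TRUE,
                                digits = NA))

#' Write a simulation configuration to JSON
#' @param config a [SimulationConfig-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSimulationConfig <- function(config, path) {
  writeLines(jsonlite::toJSON(.configToList(config), auto_unbox = TRUE,
                              digits = NA, pretty = TRUE), path)
  invisible(path)
}

#' Read a simulation configuration from JSON
#' @param path path to a configuration JSON file.
#' @return A validated [SimulationConfig-class].
#' @export
readSimulationConfig <- function(path) {
  .configFromList(jsonlite::fromJSON(path))
}

#' Take a snapshot of the full tumour state
#'
#' Records the positions, clone identities, birth steps and genotypes (hex
#' bitmask over panel order) of all tumour voxels, plus the clone registry,
#' allele table, RNG state and configuration. Restoring reproduces the
#' lattice state exactly.
#'
#' @param state a [TumourState-class].
#' @return A [Snapshot-class].
#' @export
takeSnapshot <- function(state) {
  idx <- which(state@occ != 0L)
  co <- arrayInd(idx, .dims(state))
  cid <- state@occ[idx]
  hexPerClone <- apply(state@genotypes, 1L, .genoHex)
  new("Snapshot", step = state@step,
      voxels = data.frame(x = co[, 1], y = co[, 2], z = co[, 3],
                          clone_id = cid, birth_step = state@birth[idx],
                          genotype = hexPerClone[cid],
                          stringsAsFactors = FALSE),
      clones = state@clones, alleles = state@alleles,
      nextAllele = state@nextAllele, rngState = state@rngState,
      config = .configToList(state@config),
      configHash = .configJSON(state@config))
}

## rebuild the clones x events genotype matrix from the registry
.genotypesFromRegistry <- function(clones, nev) {
  K <- nrow(clones)
  G <- matrix(FALSE, K, nev)
  for (i in seq_len(K)) {
    ids <- as.integer(strsplit(clones$new_events[i], ";", fixed = TRUE)[[1]])
    g <- if (clones$parent_id[i] > 0L) G[clones$parent_id[i], ] else rep(FALSE, nev)
    g[ids] <- TRUE
    G[i, ] <- g
  }
  G
}

#' Restore a tumour state from a snapshot
#'
#' @param snapshot a [Snapshot-class].
#' @return A [TumourState-class] identical to the state the snapshot was
#'   taken from (including the RNG stream).
#' @export
restoreState <- function(snapshot) {
  cfg <- .configFromList(snapshot@config)
  L <- cfg@L
  occ <- array(0L, dim = c(L, L, L))
  birth <- array(0L, dim = c(L, L, L))
  founder <- array(0L, dim = c(L, L, L))
  v <- snapshot@voxels
  idx <- v$x + L * (v$y - 1L) + L * L * (v$z - 1L)
  occ[idx] <- as.integer(v$clone_id)
  birth[idx] <- as.integer(v$birth_step)
  cl <- snapshot@clones
  alive <- which(cl$founder_alive)
  if (length(alive)) {
    fidx <- cl$origin_x[alive] + L * (cl$origin_y[alive] - 1L) +
      L * L * (cl$origin_z[alive] - 1L)
    founder[fidx] <- cl$clone_id[alive]
  }
  G <- .genotypesFromRegistry(cl, nEvents(cfg@panel))
  new("TumourState", config = cfg, occ = occ, birth = birth,
      founder = founder, step = snapshot@step, clones = cl,
      genotypes = G, alleles = snapshot@alleles,
      growthProb = cloneGrowthProbs(G, cfg@advantage, cfg@panel),
      nextAllele = snapshot@nextAllele, rngState = snapshot@rngState,
      log = data.frame(step = snapshot@step, n_voxels = nrow(v),
                       births = 0L, deaths = 0L, necrotic_deaths = 0L,
                       new_clones = 0L))
}

#' Write a snapshot to a TSV file with a JSON sidecar
#'
#' The TSV holds the voxel table (x, y, z, clone_id, birth_step, genotype
#' hex bitmask); the sidecar \code{<path>.json} holds the clone registry,
#' allele table, RNG state and configuration. The round trip
#' write/read/write is byte-identical.
#'
#' @param snapshot a [Snapshot-class].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeSnapshot <- function(snapshot, path) {
  write.table(snapshot@voxels, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  side <- list(step = snapshot@step, clones = snapshot@clones,
               alleles = snapshot@alleles, nextAllele = snapshot@nextAllele,
               rngState = snapshot@rngState, config = snapshot@config,
               configHash = snapshot@configHash)
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' Read a snapshot written by [writeSnapshot()]
#'
#' @param path path to the snapshot TSV (the sidecar \code{<path>.json}
#'   must sit next to it).
#' @return A [Snapshot-class].
#' @export
readSnapshot <- function(path) {
  v <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = c("integer", "integer", "integer", "integer",
                                 "integer", "character"))
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  cl <- as.data.frame(side$clones)
  for (col in c("clone_id", "parent_id", "birth_step",
                "origin_x", "origin_y", "origin_z"))
    cl[[col]] <- as.integer(cl[[col]])
  al <- as.data.frame(side$alleles)
  if (nrow(al)) for (col in names(al)) al[[col]] <- as.integer(al[[col]])
  cfg <- side$config
  cfg$panel <- as.data.frame(cfg$panel)
  new("Snapshot", step = as.integer(side$step), voxels = v, clones = cl,
      alleles = al, nextAllele = as.integer(side$nextAllele),
      rngState = as.integer(side$rngState), config = cfg,
      configHash = side$configHash)
}
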