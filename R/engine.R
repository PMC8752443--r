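## Simulation engine: initialisation, the per-step phases (death, growth,
## driver acquisition, necrosis), the run loop, snapshots and replay.
##
## All stochastic phases draw from a single RNG stream that is stored in the
## state between calls; C++ code uses R's unif_rand() so the stream is shared
## across the R/C++ boundary and trajectories are bit-reproducible.

.setRNG <- function(rngState) assign(".Random.seed", rngState, envir = globalenv())
.getRNG <- function() get(".Random.seed", envir = globalenv())

#' Construct a simulation configuration
#'
#' Defaults mirror the standard model parameterisation: 200^3 lattice,
#' p_death = 0.05, saturated advantage with p_init = 0.25, necrosis (when
#' enabled) with p_necrosis = 0.5 beyond d_necrosis = 15 mm, and a stopping
#' size of 10^6 voxels. \code{pDriver} is typically varied over
#' [2e-4, 1e-3].
#'
#' @param L lattice side length in voxels (1 voxel = 1 mm).
#' @param pDeath per-step death probability.
#' @param pDriver driver acquisition probability.
#' @param growthMode "surface" (proliferation requires an empty
#'   26-neighbour) or "volume" (all voxels proliferate; children push
#'   occupied rays outward towards the nearest surface).
#' @param advantage an [AdvantageModel-class].
#' @param panel a [DriverPanel-class].
#' @param necrosisEnabled enable depth-dependent necrotic death.
#' @param pNecrosis necrotic death probability.
#' @param dNecrosis necrosis depth threshold in mm.
#' @param stopSize stop once the tumour reaches this many voxels.
#' @param maxSteps guard on the number of steps.
#' @param seed RNG seed.
#' @param snapshotEvery snapshot interval in steps (0 = final only).
#' @param rngKind RNG algorithm passed to [set.seed()].
#' @return A validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(L = 60L, stopSize = 2e4, seed = 1L)
#' cfg
#' @export
simulationConfig <- function(L = 200L, pDeath = 0.05, pDriver = 2e-4,
                             growthMode = c("surface", "volume"),
                             advantage = saturatedModel(),
                             panel = defaultPanel(),
                             necrosisEnabled = FALSE, pNecrosis = 0.5,
                             dNecrosis = 15, stopSize = 1e6,
                             maxSteps = 100000L, seed = 1L,
                             snapshotEvery = 0L,
                             rngKind = "Mersenne-Twister") {
  growthMode <- match.arg(growthMode)
  cfg <- new("SimulationConfig", L = as.integer(L), pDeath = pDeath,
             pDriver = pDriver, growthMode = growthMode,
             advantage = advantage, panel = panel,
             necrosisEnabled = necrosisEnabled, pNecrosis = pNecrosis,
             dNecrosis = dNecrosis, stopSize = as.numeric(stopSize),
             maxSteps = as.integer(maxSteps), seed = as.integer(seed),
             snapshotEvery = as.integer(snapshotEvery), rngKind = rngKind)
  validObject(cfg)
  cfg
}

.dims <- function(state) dim(state@occ)

#' Number of tumour voxels in a state
#' @param state a [TumourState-class].
#' @return integer voxel count.
#' @export
nVoxels <- function(state) sum(state@occ != 0L)

#' Lattice centre used for the founder voxel
#' @param L lattice side length.
#' @return integer coordinate of the centre along one axis.
#' @export
latticeCentre <- function(L) as.integer(ceiling(L / 2))

#' Initialise a simulation
#'
#' Places a single founder voxel harbouring the truncal events (VHL
#' mutation and 3p loss) at the centre of the lattice and seeds the RNG
#' stream.
#'
#' @param config a [SimulationConfig-class].
#' @return A [TumourState-class] at step 0 with one voxel.
#' @examples
#' st <- newTumourState(simulationConfig(L = 20L, stopSize = 50, seed = 7L))
#' nVoxels(st)
#' @export
newTumourState <- function(config) {
  validObject(config)
  L <- config@L
  c0 <- latticeCentre(L)
  occ <- array(0L, dim = c(L, L, L))
  birth <- array(0L, dim = c(L, L, L))
  founder <- array(0L, dim = c(L, L, L))
  occ[c0, c0, c0] <- 1L
  founder[c0, c0, c0] <- 1L
  fg <- founderGenotype(config@panel)
  clones <- data.frame(clone_id = 1L, parent_id = 0L, birth_step = 0L,
                       origin_x = c0, origin_y = c0, origin_z = c0,
                       founder_alive = TRUE,
                       new_events = paste(which(fg@presence), collapse = ";"),
                       stringsAsFactors = FALSE)
  genotypes <- matrix(fg@presence, nrow = 1)
  alleles <- data.frame(allele_id = fg@alleles$allele_id,
                        event_id = fg@alleles$event_id,
                        clone_id = rep(1L, nrow(fg@alleles)))
  set.seed(config@seed, kind = config@rngKind)
  new("TumourState", config = config, occ = occ, birth = birth,
      founder = founder, step = 0L, clones = clones, genotypes = genotypes,
      alleles = alleles,
      growthProb = cloneGrowthProbs(genotypes, config@advantage, config@panel),
      nextAllele = as.integer(max(c(0L, alleles$allele_id)) + 1L),
      rngState = .getRNG(),
      log = data.frame(step = 0L, n_voxels = 1L, births = 0L, deaths = 0L,
                       necrotic_deaths = 0L, new_clones = 0L))
}

#' Depth field: distance from each voxel to the tumour surface
#'
#' Exact Euclidean distance from every lattice site to the tumour surface,
#' in mm. The surface is the exterior empty region (empty sites 6-connected
#' to the lattice boundary); transient interior holes left by cell death
#' are not surface. Exterior sites have depth 0; tumour voxels have depth
#' >= 1. The same field drives volume-mode child placement (pushing towards
#' the nearest surface) and necrosis.
#'
#' @param state a [TumourState-class].
#' @return Numeric array of the lattice dimensions.
#' @export
depthField <- function(state) {
  d <- cpp_depth_field(as.integer(state@occ), .dims(state))
  array(d, dim = .dims(state))
}

## mark clone founders at removed sites as dead; return updated pieces
.retireFounders <- function(clones, founder, removedIdx) {
  f <- founder[removedIdx]
  hit <- f[f > 0L]
  if (length(hit)) clones$founder_alive[hit] <- FALSE
  founder[removedIdx] <- 0L
  list(clones = clones, founder = founder)
}

#' Death phase
#'
#' Each living voxel is independently removed with probability
#' \code{pDeath}; freed sites immediately become available for new voxels.
#'
#' @param state a [TumourState-class].
#' @return A list with the updated \code{state} and the linear indices of
#'   \code{removed} voxels.
#' @export
deathPhase <- function(state) {
  .setRNG(state@rngState)
  occIdx <- which(state@occ != 0L)
  removed <- occIdx[runif(length(occIdx)) < state@config@pDeath]
  if (length(removed)) {
    rf <- .retireFounders(state@clones, state@founder, removed)
    state@clones <- rf$clones
    state@founder <- rf$founder
    state@occ[removed] <- 0L
    state@birth[removed] <- 0L
  }
  state@rngState <- .getRNG()
  list(state = state, removed = removed)
}

#' Eligible parent voxels
#'
#' Surface mode: voxels with at least one empty site among their 26
#' neighbours. Volume mode: all tumour voxels.
#'
#' @param state a [TumourState-class].
#' @param mode "surface" or "volume" (defaults to the state's growth mode).
#' @return data.frame of eligible voxels (\code{x}, \code{y}, \code{z},
#'   \code{index}).
#' @export
eligibleParents <- function(state, mode = state@config@growthMode) {
  idx <- cpp_eligible_parents(as.integer(state@occ), .dims(state),
                              as.integer(mode == "surface"))
  co <- arrayInd(idx, .dims(state))
  data.frame(x = co[, 1], y = co[, 2], z = co[, 3], index = idx)
}

## growth phase over all eligible parents; forceSites (linear indices) makes
## exactly those sites proliferate, used by the single-placement ops.
.growthPhase <- function(state, depth, forceSites = integer()) {
  .setRNG(state@rngState)
  mode <- if (state@config@growthMode == "surface") 0L else 1L
  gp <- cpp_growth_phase(as.integer(state@occ), as.integer(state@birth),
                         as.integer(state@founder), .dims(state),
                         as.numeric(depth), state@growthProb, mode,
                         state@step + 1L, 10L, as.integer(forceSites))
  if (nzchar(gp$error))
    stop("lattice boundary reached at step ", state@step + 1L, ": ",
         gp$error, " (enlarge L or lower stopSize)", call. = FALSE)
  dims <- .dims(state)
  state@occ <- array(gp$occ, dim = dims)
  state@birth <- array(gp$birth, dim = dims)
  state@founder <- array(gp$founder, dim = dims)
  ## pushes can move clone-founding voxels: refresh recorded origins
  fidx <- which(state@founder != 0L)
  if (length(fidx)) {
    cids <- state@founder[fidx]
    co <- arrayInd(fidx, dims)
    state@clones$origin_x[cids] <- co[, 1]
    state@clones$origin_y[cids] <- co[, 2]
    state@clones$origin_z[cids] <- co[, 3]
  }
  state@rngState <- .getRNG()
  list(state = state,
       daughters = data.frame(site = gp$daughter_site,
                              parent_clone = gp$daughter_clone))
}

#' Place one child of a surface-mode parent
#'
#' The child occupies a uniformly chosen empty site among the parent's 26
#' neighbours; the parent keeps its site. Errors if the parent is fully
#' enclosed.
#'
#' @param state a [TumourState-class].
#' @param parent linear lattice index (or c(x, y, z)) of the parent voxel.
#' @return list(state, child) where \code{child} is the linear index of the
#'   new voxel.
#' @export
placeChildSurface <- function(state, parent) {
  idx <- .asIndex(state, parent)
  occBefore <- sum(state@occ != 0L)
  st <- state
  st@config@growthMode <- "surface"
  res <- .growthPhase(st, depth = numeric(length(state@occ)),
                      forceSites = idx)
  if (sum(res$state@occ != 0L) == occBefore)
    stop("parent has no empty neighbour")
  res$state@config@growthMode <- state@config@growthMode
  list(state = res$state, child = res$daughters$site[1])
}

#' Place one child of a volume-mode parent, pushing voxels outward
#'
#' Ten of the 26 orientations are sampled without replacement; the
#' candidate site closest to the tumour surface (by the depth field) is
#' selected, ties broken uniformly. Occupied sites along that orientation
#' are shifted one step outward until the first empty site absorbs the
#' displacement, then the child is placed adjacent to the parent. A push
#' that would exit the lattice aborts with a boundary error.
#'
#' @inheritParams placeChildSurface
#' @return list(state, child) with the child's final linear index.
#' @export
placeChildVolume <- function(state, parent) {
  idx <- .asIndex(state, parent)
  st <- state
  st@config@growthMode <- "volume"
  depth <- depthField(state)
  res <- .growthPhase(st, depth = depth, forceSites = idx)
  res$state@config@growthMode <- state@config@growthMode
  list(state = res$state, child = res$daughters$site[1])
}

.asIndex <- function(state, pos) {
  if (length(pos) == 3L) {
    dims <- .dims(state)
    as.integer(pos[1] + dims[1] * (pos[2] - 1) + dims[1] * dims[2] * (pos[3] - 1))
  } else as.integer(pos)
}

#' Driver acquisition phase
#'
#' For each daughter voxel born this step and each panel event not already
#' harboured, the event is acquired with probability \code{pDriver} (gene
#' mutations) or the genotype's SCNA acquisition probability (0.001 pDriver,
#' or pDriver with PBRM1/BAP1). Each gene-mutation acquisition draws a fresh
#' unique allele id. A daughter acquiring one or more events founds a new
#' clone.
#'
#' @param state a [TumourState-class].
#' @param daughters data.frame with columns \code{site} (linear index) and
#'   \code{parent_clone}, as returned by the growth phase.
#' @return A list with the updated \code{state} and \code{newClones}, the
#'   ids of clones founded this phase.
#' @export
driverPhase <- function(state, daughters) {
  .setRNG(state@rngState)
  newClones <- integer()
  nd <- nrow(daughters)
  if (nd > 0L && state@config@pDriver > 0) {
    panel <- state@config@panel
    ev <- panel@events
    nev <- nrow(ev)
    pDriver <- state@config@pDriver
    G <- state@genotypes
    pc <- daughters$parent_clone
    harb <- G[pc, , drop = FALSE]
    enh <- ev$enhances_scna_rate
    scnaRate <- ifelse(rowSums(harb[, enh, drop = FALSE]) > 0,
                       pDriver, 0.001 * pDriver)
    isGene <- ev$event_class == "gene_mutation"
    P <- matrix(rep(ifelse(isGene, pDriver, NA_real_), each = nd), nd, nev)
    P[, !isGene] <- scnaRate # recycled down columns: one rate per daughter
    U <- matrix(runif(nd * nev), nd, nev)
    acq <- (U < P) & !harb
    rows <- which(rowSums(acq) > 0L)
    if (length(rows)) {
      dims <- .dims(state)
      stepNo <- state@step + 1L
      addG <- vector("list", length(rows))
      for (k in seq_along(rows)) {
        r <- rows[k]
        newId <- nrow(state@clones) + 1L
        gained <- which(acq[r, ])
        site <- daughters$site[r]
        co <- arrayInd(site, dims)
        state@clones <- rbind(state@clones, data.frame(
          clone_id = newId, parent_id = pc[r], birth_step = stepNo,
          origin_x = co[1], origin_y = co[2], origin_z = co[3],
          founder_alive = TRUE,
          new_events = paste(gained, collapse = ";"),
          stringsAsFactors = FALSE))
        geneGain <- gained[isGene[gained]]
        if (length(geneGain)) {
          ids <- state@nextAllele + seq_along(geneGain) - 1L
          state@alleles <- rbind(state@alleles, data.frame(
            allele_id = ids, event_id = geneGain,
            clone_id = rep(newId, length(geneGain))))
          state@nextAllele <- state@nextAllele + length(geneGain)
        }
        g <- G[pc[r], ]
        g[gained] <- TRUE
        addG[[k]] <- g
        state@occ[site] <- newId
        state@founder[site] <- newId
        newClones <- c(newClones, newId)
      }
      newG <- do.call(rbind, addG)
      state@genotypes <- rbind(state@genotypes, newG)
      state@growthProb <- c(state@growthProb,
                            cloneGrowthProbs(newG, state@config@advantage,
                                             panel))
    }
  }
  state@rngState <- .getRNG()
  list(state = state, newClones = newClones)
}

#' Necrosis phase
#'
#' Voxels deeper than \code{dNecrosis} mm from the tumour surface are
#' removed independently with probability \code{pNecrosis}; freed sites
#' become reusable.
#'
#' @param state a [TumourState-class].
#' @param depth optional precomputed depth field (the step loop shares one
#'   field per step between placement and necrosis).
#' @return list(state, removed).
#' @export
necrosisPhase <- function(state, depth = depthField(state)) {
  if (!state@config@necrosisEnabled)
    return(list(state = state, removed = integer()))
  .setRNG(state@rngState)
  occIdx <- which(state@occ != 0L)
  deep <- occIdx[depth[occIdx] > state@config@dNecrosis]
  removed <- deep[runif(length(deep)) < state@config@pNecrosis]
  if (length(removed)) {
    rf <- .retireFounders(state@clones, state@founder, removed)
    state@clones <- rf$clones
    state@founder <- rf$founder
    state@occ[removed] <- 0L
    state@birth[removed] <- 0L
  }
  state@rngState <- .getRNG()
  list(state = state, removed = removed)
}

#' Advance the simulation by one step
#'
#' Phase order: death, depth-field refresh, proliferation over eligible
#' parents in a fresh random permutation, driver acquisition on the step's
#' daughters, then necrosis (if enabled). Sites freed by this step's deaths
#' are immediately reusable for placement.
#'
#' @param state a [TumourState-class].
#' @return The successor [TumourState-class].
#' @export
simStep <- function(state) {
  dp <- deathPhase(state)
  state <- dp$state
  depth <- depthField(state)
  gp <- .growthPhase(state, depth)
  state <- gp$state
  drv <- driverPhase(state, gp$daughters)
  state <- drv$state
  np <- necrosisPhase(state, depth)
  state <- np$state
  state@step <- state@step + 1L
  state@log <- rbind(state@log, data.frame(
    step = state@step, n_voxels = nVoxels(state),
    births = nrow(gp$daughters), deaths = length(dp$removed),
    necrotic_deaths = length(np$removed),
    new_clones = length(drv$newClones)))
  state
}

## shared run loop; stops at stopSize, maxSteps, or extinction
.runLoop <- function(state, snapshots = list()) {
  cfg <- state@config
  every <- cfg@snapshotEvery
  extinct <- FALSE
  repeat {
    n <- nVoxels(state)
    if (n >= cfg@stopSize) break
    if (n == 0L) { extinct <- TRUE; break }
    if (state@step >= cfg@maxSteps)
      stop("maxSteps (", cfg@maxSteps, ") exceeded at ", n, " voxels",
           call. = FALSE)
    state <- simStep(state)
    if (every > 0L && state@step %% every == 0L)
      snapshots[[length(snapshots) + 1L]] <- takeSnapshot(state)
  }
  last <- length(snapshots)
  if (last == 0L || snapshots[[last]]@step != state@step)
    snapshots[[last + 1L]] <- takeSnapshot(state)
  list(state = state, snapshots = snapshots, extinct = extinct)
}

#' Run a simulation to its stopping size
#'
#' Steps the automaton until the tumour reaches \code{stopSize} voxels.
#' Snapshots are emitted every \code{snapshotEvery} steps and at
#' termination. A tumour whose last voxel dies before establishment is
#' returned with \code{extinct = TRUE} rather than an error, so ensembles
#' can condition on non-extinction.
#'
#' @param config a [SimulationConfig-class].
#' @return list(state, snapshots, extinct).
#' @examples
#' cfg <- simulationConfig(L = 24L, stopSize = 100, seed = 2L, pDriver = 0)
#' res <- runSimulation(cfg)
#' nVoxels(res$state)
#' @export
runSimulation <- function(config) {
  state <- newTumourState(config)
  snaps <- list()
  if (config@snapshotEvery > 0L) snaps[[1L]] <- takeSnapshot(state)
  .runLoop(state, snaps)
}

#' Run a simulation, retrying extinct seeds deterministically
#'
#' Stochastic extinction of the founder lineage is common at baseline
#' parameters (p_death/p_growth = 0.2); analyses condition on tumours that
#' reach the stopping size. On extinction the seed is advanced by a fixed
#' offset (1e6) and the run restarted, deterministically, up to
#' \code{maxTries} times.
#'
#' @param config a [SimulationConfig-class].
#' @param maxTries maximum number of seeds to try.
#' @return As [runSimulation()], with the used seed in \code{seed}.
#' @export
runUntilEstablished <- function(config, maxTries = 25L) {
  seed <- config@seed
  for (i in seq_len(maxTries)) {
    config@seed <- as.integer(seed + (i - 1L) * 1e6)
    res <- runSimulation(config)
    if (!res$extinct) { res$seed <- config@seed; return(res) }
  }
  stop("all ", maxTries, " seeds went extinct", call. = FALSE)
}

#' Replay a snapshot under new random seeds
#'
#' Reconstructs \code{length(seeds)} replicate tumours from the same
#' evolutionary snapshot and simulates each to the stopping size under its
#' own unique seed. With \code{seeds = NULL} a single replicate continues
#' the snapshot's stored RNG stream, which reproduces the uninterrupted run
#' exactly.
#'
#' @param snapshot a [Snapshot-class].
#' @param seeds integer vector of distinct seeds, or NULL to resume the
#'   stored stream.
#' @param stopSize optional override of the stopping size.
#' @return A list of run results as returned by [runSimulation()].
#' @export
replaySimulation <- function(snapshot, seeds = NULL, stopSize = NULL) {
  if (!is.null(seeds) && anyDuplicated(seeds))
    stop("replay seeds must be distinct")
  nrep <- if (is.null(seeds)) 1L else length(seeds)
  lapply(seq_len(nrep), function(i) {
    state <- restoreState(snapshot)
    if (!is.null(stopSize)) state@config@stopSize <- as.numeric(stopSize)
    if (!is.null(seeds)) {
      set.seed(seeds[i], kind = state@config@rngKind)
      state@rngState <- .getRNG()
    }
    .runLoop(state)
  })
}
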