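## S4 class definitions for the simulation and analysis layer.

#' DriverPanel: the ccRCC driver-event catalogue
#'
#' Holds an ordered table of driver events. The default ccRCC panel has 26
#' events: mutations in 12 genes and 14 somatic copy-number alterations
#' (SCNAs). Each event carries a tier for the saturated advantage model
#' (\code{initial}, \code{moderate}, \code{maximal}), a rank 1..n for the
#' additive model (1 = weakest), and flags marking truncal events, events
#' enhancing the SCNA acquisition rate (PBRM1/BAP1), and the strongest
#' SCNAs.
#'
#' @slot events data.frame with columns \code{id}, \code{name},
#'   \code{event_class}, \code{tier}, \code{rank}, \code{is_truncal},
#'   \code{enhances_scna_rate}, \code{is_strongest}.
#' @seealso [defaultPanel()], [loadPanel()]
#' @export
setClass("DriverPanel", representation(events = "data.frame"))

setValidity("DriverPanel", function(object) {
  ev <- object@events
  need <- c("id", "name", "event_class", "tier", "rank", "is_truncal",
            "enhances_scna_rate", "is_strongest")
  if (!all(need %in% names(ev)))
    return(paste("missing columns:", paste(setdiff(need, names(ev)), collapse = ", ")))
  n <- nrow(ev)
  if (n < 1L) return("panel must contain at least one event")
  if (!identical(as.integer(ev$id), seq_len(n)))
    return("event ids must be 1..n in order")
  if (anyDuplicated(ev$name)) return("duplicate event names")
  if (!all(ev$event_class %in% c("gene_mutation", "scna")))
    return("event_class must be 'gene_mutation' or 'scna'")
  if (!all(ev$tier %in% c("initial", "moderate", "maximal")))
    return("tier must be 'initial', 'moderate' or 'maximal'")
  if (!identical(sort(as.integer(ev$rank)), seq_len(n)))
    return("ranks must form a permutation of 1..n")
  for (fl in c("is_truncal", "enhances_scna_rate", "is_strongest"))
    if (!is.logical(ev[[fl]]) || anyNA(ev[[fl]]))
      return(paste0("flag column '", fl, "' must be logical without NA"))
  TRUE
})

#' AdvantageModel: driver selective-advantage model
#'
#' Maps a genotype (set of harboured driver events) to a per-step growth
#' probability. Two models are supported. The \emph{saturated} model assigns
#' one of three levels \{p_init, (1+s) p_init, (1+s)^2 p_init\} according to
#' the highest tier harboured, saturating at 1. The \emph{additive} model
#' returns p_init + sum_k s_k(rank_k) p_init over harboured drivers, with
#' s_k(r) = min_sk + (r - 1) delta_sk, capped at 1.
#'
#' @slot model "saturated" or "additive".
#' @slot s selective coefficient in [0, 1] (saturated model).
#' @slot pInit baseline growth probability p_growth(initial), default 0.25.
#' @slot minSk additive model: s_k of the weakest driver (rank 1).
#' @slot deltaSk additive model: increment in s_k between consecutive ranks.
#' @seealso [saturatedModel()], [additiveModel()], [growthProbability()]
#' @export
setClass("AdvantageModel",
         representation(model = "character", s = "numeric", pInit = "numeric",
                        minSk = "numeric", deltaSk = "numeric"))

setValidity("AdvantageModel", function(object) {
  if (!object@model %in% c("saturated", "additive"))
    return("model must be 'saturated' or 'additive'")
  if (object@pInit < 0 || object@pInit > 1)
    return("pInit must lie in [0, 1]")
  if (object@model == "saturated" && (object@s < 0 || object@s > 1))
    return("s must lie in [0, 1]")
  if (object@model == "additive" && (object@minSk < 0 || object@deltaSk < 0))
    return("minSk and deltaSk must be non-negative")
  TRUE
})

#' Genotype: driver events harboured by a tumour voxel
#'
#' Presence vector over the panel events plus allele identifiers for each
#' gene-mutation acquisition. A second mutation of the same gene never
#' occurs in the same voxel, so at most one allele id per gene event.
#'
#' @slot presence logical vector over panel events.
#' @slot alleles data.frame with columns \code{event_id}, \code{allele_id}.
#' @seealso [newGenotype()], [founderGenotype()]
#' @export
setClass("Genotype",
         representation(presence = "logical", alleles = "data.frame"))

setValidity("Genotype", function(object) {
  al <- object@alleles
  if (nrow(al) > 0) {
    if (anyDuplicated(al$event_id))
      return("at most one allele id per gene event per genotype")
    if (!all(al$event_id %in% which(object@presence)))
      return("allele recorded for an event not present")
  }
  TRUE
})

#' SimulationConfig: parameters of one lattice simulation
#'
#' Defaults follow the standard model parameterisation: a 200^3 lattice of
#' 1 mm^3 voxels, per-step baseline probabilities p_growth = 0.25 (held in
#' the advantage model) and p_death = 0.05, necrosis with p_necrosis = 0.5
#' beyond d_necrosis = 15 mm from the tumour surface, and a stopping size of
#' 10^6 voxels (equivalent spherical diameter of roughly 12 cm).
#'
#' @slot L lattice side length in voxels.
#' @slot pDeath per-voxel per-step death probability.
#' @slot pDriver per-daughter per-event driver acquisition probability
#'   (gene mutations; SCNAs use 0.001 pDriver unless PBRM1/BAP1 is present).
#' @slot growthMode "surface" or "volume".
#' @slot advantage an [AdvantageModel-class] object.
#' @slot panel a [DriverPanel-class] object.
#' @slot necrosisEnabled logical.
#' @slot pNecrosis necrotic death probability for deep voxels.
#' @slot dNecrosis depth threshold (mm) for necrosis.
#' @slot stopSize stop once the voxel count reaches this value.
#' @slot maxSteps guard on the number of simulation steps.
#' @slot seed master RNG seed.
#' @slot snapshotEvery emit a snapshot every this many steps (0 = only at
#'   termination).
#' @slot rngKind RNG algorithm (pinned for cross-run determinism).
#' @seealso [simulationConfig()], [runSimulation()]
#' @export
setClass("SimulationConfig",
         representation(L = "integer", pDeath = "numeric", pDriver = "numeric",
                        growthMode = "character", advantage = "AdvantageModel",
                        panel = "DriverPanel", necrosisEnabled = "logical",
                        pNecrosis = "numeric", dNecrosis = "numeric",
                        stopSize = "numeric", maxSteps = "integer",
                        seed = "integer", snapshotEvery = "integer",
                        rngKind = "character"))

setValidity("SimulationConfig", function(object) {
  if (object@L < 3L) return("L must be at least 3")
  for (p in c(object@pDeath, object@pDriver, object@pNecrosis))
    if (p < 0 || p > 1) return("probabilities must lie in [0, 1]")
  if (!object@growthMode %in% c("surface", "volume"))
    return("growthMode must be 'surface' or 'volume'")
  if (object@stopSize < 1 || object@stopSize > as.numeric(object@L)^3)
    return("stopSize must lie in [1, L^3]")
  if (object@dNecrosis <= 0) return("dNecrosis must be positive")
  TRUE
})

#' TumourState: full state of a lattice simulation
#'
#' Occupancy, per-voxel birth steps, subclone-founder marks, the clone
#' registry (phylogeny plus founding events and allele ids), per-clone
#' genotypes and cached growth probabilities, and the RNG state. All
#' stochastic phases consume a single RNG stream stored in the state, so a
#' given (config, seed) pair reproduces bit-identical trajectories.
#'
#' @slot config the [SimulationConfig-class].
#' @slot occ integer L^3 array of clone ids (0 = empty site).
#' @slot birth integer array of per-voxel birth steps.
#' @slot founder integer array marking each clone's founding voxel.
#' @slot step current simulation step.
#' @slot clones clone registry data.frame (\code{clone_id},
#'   \code{parent_id}, \code{birth_step}, \code{origin_x/y/z},
#'   \code{founder_alive}, \code{new_events}).
#' @slot genotypes logical clones x events matrix.
#' @slot alleles data.frame of gene-mutation alleles (\code{allele_id},
#'   \code{event_id}, \code{clone_id}).
#' @slot growthProb cached per-clone growth probability.
#' @slot nextAllele next free allele id.
#' @slot rngState saved \code{.Random.seed}.
#' @slot log per-step data.frame of counts (voxels, births, deaths,
#'   necrotic deaths, new clones).
#' @export
setClass("TumourState",
         representation(config = "SimulationConfig", occ = "array",
                        birth = "array", founder = "array", step = "integer",
                        clones = "data.frame", genotypes = "matrix",
                        alleles = "data.frame", growthProb = "numeric",
                        nextAllele = "integer", rngState = "integer",
                        log = "data.frame"))

setValidity("TumourState", function(object) {
  if (!identical(dim(object@occ), dim(object@birth)) ||
      !identical(dim(object@occ), dim(object@founder)))
    return("occ, birth and founder arrays must share dimensions")
  occ <- object@occ
  ids <- occ[occ != 0L]
  if (length(ids) && max(ids) > nrow(object@clones))
    return("occupancy refers to a clone id missing from the registry")
  if (nrow(object@clones) != nrow(object@genotypes) ||
      nrow(object@clones) != length(object@growthProb))
    return("registry, genotype matrix and growth-probability cache disagree")
  TRUE
})

#' Snapshot: serialisable full tumour state
#'
#' Positions, clone identities, birth steps and genotypes of all tumour
#' voxels, together with the clone registry, allele table, RNG state and the
#' generating configuration. Restoring a snapshot reproduces the lattice
#' state exactly, which is the basis of evolutionary replay.
#'
#' @slot step simulation step at which the snapshot was taken.
#' @slot voxels data.frame (\code{x}, \code{y}, \code{z}, \code{clone_id},
#'   \code{birth_step}, \code{genotype} as a hex bitmask over panel order).
#' @slot clones clone registry copy.
#' @slot alleles allele table copy.
#' @slot nextAllele next free allele id.
#' @slot rngState saved RNG state (continuation stream).
#' @slot config the generating configuration as a plain list.
#' @slot configHash canonical JSON serialisation of the configuration.
#' @seealso [takeSnapshot()], [restoreState()], [replaySimulation()]
#' @export
setClass("Snapshot",
         representation(step = "integer", voxels = "data.frame",
                        clones = "data.frame", alleles = "data.frame",
                        nextAllele = "integer", rngState = "integer",
                        config = "list", configHash = "character"))

#' TumourSlice: one 2D plane of a tumour
#'
#' All tumour voxels within the plane z = z0, with the slice centre (the
#' centroid of occupied sites), the raw Moore-traced contour and its
#' smoothed counterpart (per-point mean over the point and its adjacent
#' tumour voxels; same point count as the raw contour).
#'
#' @slot z0 the slice plane.
#' @slot sites data.frame (\code{x}, \code{y}, \code{clone_id},
#'   \code{birth_step}).
#' @slot dims lattice extent (Lx, Ly) of the plane.
#' @slot centre centroid (x, y) of occupied sites, in mm.
#' @slot contour raw contour point matrix (columns x, y).
#' @slot contourSmooth smoothed contour point matrix (same row count).
#' @slot clones clone registry of the source state.
#' @slot genotypes per-clone genotype matrix of the source state.
#' @slot panel the driver panel.
#' @slot advantage the advantage model.
#' @seealso [extractSlice()], [circularity()], [microdiversityMap()]
#' @export
setClass("TumourSlice",
         representation(z0 = "integer", sites = "data.frame", dims = "integer",
                        centre = "numeric", contour = "matrix",
                        contourSmooth = "matrix", clones = "data.frame",
                        genotypes = "matrix", panel = "DriverPanel",
                        advantage = "AdvantageModel"))

setValidity("TumourSlice", function(object) {
  if (nrow(object@sites) < 1L) return("slice must contain at least one voxel")
  if (nrow(object@contour) != nrow(object@contourSmooth))
    return("smoothed contour must have the same point count as the raw contour")
  TRUE
})

#' PowerLawFit: bootstrap power-law exponent fit
#'
#' Fit of the cumulative distribution P(D <= d) ~ d^k of normalised
#' hotspot centre-distances, with a bootstrap sample of exponents (default
#' 100 resamples of 400 hotspots each).
#'
#' @slot k point estimate fitted on the full sample.
#' @slot kBoot bootstrap exponent sample.
#' @slot nBoot number of bootstrap resamples.
#' @slot resampleSize hotspots per resample.
#' @slot n number of input d values used.
#' @slot sse residual sum of squares of the point fit.
#' @slot degenerate TRUE when the input distances carry no usable spread.
#' @seealso [fitPowerLaw()]
#' @export
setClass("PowerLawFit",
         representation(k = "numeric", kBoot = "numeric", nBoot = "integer",
                        resampleSize = "integer", n = "integer",
                        sse = "numeric", degenerate = "logical"))

## ---- show methods -------------------------------------------------------

setMethod("show", "DriverPanel", function(object) {
  ev <- object@events
  cat("DriverPanel with", nrow(ev), "events (",
      sum(ev$event_class == "gene_mutation"), "gene mutations,",
      sum(ev$event_class == "scna"), "SCNAs )\n")
  cat("  truncal:", paste(ev$name[ev$is_truncal], collapse = ", "), "\n")
  cat("  strongest:", paste(ev$name[ev$is_strongest], collapse = ", "), "\n")
})

setMethod("show", "AdvantageModel", function(object) {
  if (object@model == "saturated")
    cat(sprintf("AdvantageModel: saturated, s = %g, p_init = %g\n",
                object@s, object@pInit))
  else
    cat(sprintf(
      "AdvantageModel: additive, min s_k = %g, delta s_k = %g, p_init = %g\n",
      object@minSk, object@deltaSk, object@pInit))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d^3 lattice, %s growth, p_death = %g, p_driver = %g\n",
              object@L, object@growthMode, object@pDeath, object@pDriver))
  cat(sprintf("  necrosis: %s (p = %g beyond %g mm), stop at %g voxels, seed %d\n",
              if (object@necrosisEnabled) "on" else "off", object@pNecrosis,
              object@dNecrosis, object@stopSize, object@seed))
})

setMethod("show", "TumourState", function(object) {
  cat(sprintf("TumourState: step %d, %d tumour voxels, %d clones (%s growth)\n",
              object@step, sum(object@occ != 0L), nrow(object@clones),
              object@config@growthMode))
})

setMethod("show", "Snapshot", function(object) {
  cat(sprintf("Snapshot at step %d: %d voxels, %d clones\n",
              object@step, nrow(object@voxels), nrow(object@clones)))
})

setMethod("show", "TumourSlice", function(object) {
  cat(sprintf("TumourSlice z = %d: %d voxels, %d clones present, centre (%.1f, %.1f) mm\n",
              object@z0, nrow(object@sites),
              length(unique(object@sites$clone_id)),
              object@centre[1], object@centre[2]))
})

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("PowerLawFit: k = %.3f (bootstrap median %.3f over %d x %d)%s\n",
              object@k, stats::median(object@kBoot), object@nBoot,
              object@resampleSize,
              if (object@degenerate) " [degenerate]" else ""))
})
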