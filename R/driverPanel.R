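## Driver panel: the 26-event ccRCC catalogue and the two fitness models.

.panelGenes <- c("VHL", "PBRM1", "SETD2", "BAP1", "MTOR", "KDM5C", "PTEN",
                 "TP53", "PIK3CA", "TSC1", "TSC2", "ARID1A")
.panelSCNAs <- c("3p loss", "5q gain", "7q gain", "8q gain", "12p gain",
                 "20q gain", "1p loss", "4q loss", "6q loss", "8p loss",
                 "9p loss", "14q loss", "18p loss", "21q loss")
.strongestSCNAs <- c("7q gain", "20q gain", "4q loss", "8p loss")

#' The built-in 26-event ccRCC driver panel
#'
#' Twelve driver gene mutations and fourteen somatic copy-number alterations
#' (SCNAs). VHL mutation and 3p loss are the truncal events carried by the
#' founder voxel; PBRM1 and BAP1 mutations enhance the SCNA acquisition rate;
#' the four SCNAs most strongly associated with proliferation (7q gain,
#' 20q gain, 4q loss, 8p loss) are the strongest drivers (maximal tier).
#'
#' Saturated-model tiers: gene mutations and the truncal 3p loss sit at the
#' initial tier (no growth advantage beyond baseline, so the parental clone
#' proliferates at p_init), the four strongest SCNAs at the maximal tier, and
#' the remaining SCNAs at the moderate tier. Additive-model ranks order the
#' 26 events from weakest (rank 1) to strongest (rank 26); the default order
#' places truncal events first, gene mutations next, then SCNAs, with the
#' four strongest SCNAs at ranks 23-26. Panel membership beyond the
#' explicitly flagged events, and the default rank order, are package
#' defaults and can be replaced via [loadPanel()].
#'
#' @return A [DriverPanel-class] object with 26 events.
#' @examples
#' panel <- defaultPanel()
#' panel
#' @export
defaultPanel <- function() {
  name <- c(.panelGenes, .panelSCNAs)
  event_class <- c(rep("gene_mutation", length(.panelGenes)),
                   rep("scna", length(.panelSCNAs)))
  tier <- ifelse(event_class == "gene_mutation", "initial",
          ifelse(name %in% .strongestSCNAs, "maximal", "moderate"))
  tier[name == "3p loss"] <- "initial" # truncal, parental clone at baseline
  rankOrder <- c("3p loss", "VHL", "TSC1", "TSC2", "PIK3CA", "ARID1A",
                 "KDM5C", "PTEN", "TP53", "MTOR", "SETD2", "PBRM1", "BAP1",
                 "18p loss", "21q loss", "1p loss", "6q loss", "9p loss",
                 "14q loss", "5q gain", "8q gain", "12p gain",
                 "8p loss", "4q loss", "20q gain", "7q gain")
  ev <- data.frame(
    id = seq_along(name),
    name = name,
    event_class = event_class,
    tier = tier,
    rank = match(name, rankOrder),
    is_truncal = name %in% c("VHL", "3p loss"),
    enhances_scna_rate = name %in% c("PBRM1", "BAP1"),
    is_strongest = name %in% .strongestSCNAs,
    stringsAsFactors = FALSE)
  new("DriverPanel", events = ev)
}

#' Load a driver panel from a JSON file
#'
#' The file holds an array of event records with fields \code{name},
#' \code{event_class}, \code{tier}, \code{rank} and the flags
#' \code{is_truncal}, \code{enhances_scna_rate}, \code{is_strongest}.
#' Validation rejects duplicate names, unknown class or tier labels and
#' rank lists that are not a permutation of 1..n.
#'
#' @param path path to a panel JSON file.
#' @return A validated [DriverPanel-class].
#' @seealso [writePanel()], [defaultPanel()]
#' @export
loadPanel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  ev <- jsonlite::fromJSON(path)
  if (!is.data.frame(ev)) stop("panel file must hold an array of event records")
  ev$id <- seq_len(nrow(ev))
  for (fl in c("is_truncal", "enhances_scna_rate", "is_strongest")) {
    if (is.null(ev[[fl]])) ev[[fl]] <- FALSE
    ev[[fl]] <- as.logical(ev[[fl]])
  }
  ev$rank <- as.integer(ev$rank)
  cols <- c("id", "name", "event_class", "tier", "rank", "is_truncal",
            "enhances_scna_rate", "is_strongest")
  missing <- setdiff(c("name", "event_class", "tier", "rank"), names(ev))
  if (length(missing))
    stop("panel file missing fields: ", paste(missing, collapse = ", "))
  panel <- new("DriverPanel", events = ev[, cols])
  validObject(panel)
  panel
}

#' Write a driver panel to a JSON file
#'
#' @param panel a [DriverPanel-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePanel <- function(panel, path) {
  ev <- panel@events
  jsonlite::write_json(ev[, setdiff(names(ev), "id")], path,
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Number of events in a panel
#' @param panel a [DriverPanel-class].
#' @return integer event count.
#' @export
nEvents <- function(panel) nrow(panel@events)

#' Event names of a panel
#' @param panel a [DriverPanel-class].
#' @return character vector of event names in panel order.
#' @export
eventNames <- function(panel) panel@events$name

.eventIds <- function(panel, names) {
  ids <- match(names, panel@events$name)
  if (anyNA(ids)) stop("unknown event name(s): ",
                       paste(names[is.na(ids)], collapse = ", "))
  ids
}

## ---- advantage models ---------------------------------------------------

#' Saturated driver advantage model
#'
#' Growth probability takes one of three levels according to the highest
#' tier among harboured drivers: p_init (initial), (1+s) p_init (moderate)
#' or (1+s)^2 p_init (maximal), capped at 1. With s = 1 and p_init = 0.25
#' the maximal tier saturates the growth probability at 1.
#'
#' @param s selective coefficient in [0, 1].
#' @param pInit baseline growth probability p_growth(initial).
#' @return An [AdvantageModel-class].
#' @examples
#' saturatedModel(s = 1)
#' @export
saturatedModel <- function(s = 1, pInit = 0.25) {
  m <- new("AdvantageModel", model = "saturated", s = s, pInit = pInit,
           minSk = 0, deltaSk = 0)
  validObject(m)
  m
}

#' Additive driver advantage model
#'
#' Each harboured driver k adds s_k(rank_k) * p_init to the growth
#' probability, with the linear rank schedule
#' s_k(r) = minSk + (r - 1) deltaSk; the total is capped at 1.
#'
#' @param minSk s_k of the weakest driver (rank 1).
#' @param deltaSk difference in s_k between consecutive ranks.
#' @param pInit baseline growth probability.
#' @param preset optionally one of \code{"low"}, \code{"mid"},
#'   \code{"high"}: package presets spanning weak to strong per-driver
#'   increments (strongest driver adds 0.33, 0.65 and 0.99 of p_init to the
#'   baseline respectively); overrides \code{minSk}/\code{deltaSk}.
#' @return An [AdvantageModel-class].
#' @export
additiveModel <- function(minSk = 0.1, deltaSk = 0.1, pInit = 0.25,
                          preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("low", "mid", "high"))
    par <- switch(preset,
                  low  = c(0.05, 0.05),
                  mid  = c(0.10, 0.10),
                  high = c(0.20, 0.15))
    minSk <- par[1]; deltaSk <- par[2]
  }
  m <- new("AdvantageModel", model = "additive", s = 0, pInit = pInit,
           minSk = minSk, deltaSk = deltaSk)
  validObject(m)
  m
}

## ---- genotypes ----------------------------------------------------------

#' Construct a genotype
#'
#' @param panel a [DriverPanel-class].
#' @param events character vector of event names (or integer event ids)
#'   present in the genotype.
#' @param alleleStart first allele id to assign to gene-mutation events.
#' @return A [Genotype-class].
#' @export
newGenotype <- function(panel, events = character(), alleleStart = 1L) {
  ids <- if (is.character(events)) .eventIds(panel, events) else as.integer(events)
  presence <- rep(FALSE, nEvents(panel))
  presence[ids] <- TRUE
  geneIds <- ids[panel@events$event_class[ids] == "gene_mutation"]
  alleles <- data.frame(event_id = as.integer(geneIds),
                        allele_id = seq_along(geneIds) + alleleStart - 1L)
  g <- new("Genotype", presence = presence, alleles = alleles)
  validObject(g)
  g
}

#' The founder genotype: VHL mutation plus 3p loss
#'
#' Every simulation starts from a single founder voxel harbouring these two
#' truncal events.
#'
#' @param panel a [DriverPanel-class].
#' @return A [Genotype-class].
#' @export
founderGenotype <- function(panel) newGenotype(panel, c("VHL", "3p loss"))

.presenceOf <- function(genotype) {
  if (is(genotype, "Genotype")) genotype@presence else as.logical(genotype)
}

## ---- fitness ------------------------------------------------------------

#' Growth probability of a genotype under an advantage model
#'
#' @param genotype a [Genotype-class] or a logical presence vector over
#'   panel events.
#' @param model an [AdvantageModel-class].
#' @param panel a [DriverPanel-class].
#' @return The per-step growth probability, in [pInit, 1].
#' @examples
#' panel <- defaultPanel()
#' growthProbability(founderGenotype(panel), saturatedModel(s = 1), panel)
#' growthProbability(newGenotype(panel, c("VHL", "3p loss", "7q gain")),
#'                   saturatedModel(s = 1), panel)
#' @export
growthProbability <- function(genotype, model, panel) {
  pres <- matrix(.presenceOf(genotype), nrow = 1)
  drop(cloneGrowthProbs(pres, model, panel))
}

#' Per-clone growth probabilities for a genotype matrix
#'
#' Vectorised form of [growthProbability()] used by the engine: one row per
#' clone, one column per panel event.
#'
#' @param genotypes logical clones x events matrix.
#' @param model an [AdvantageModel-class].
#' @param panel a [DriverPanel-class].
#' @return Numeric vector of growth probabilities, one per row.
#' @export
cloneGrowthProbs <- function(genotypes, model, panel) {
  ev <- panel@events
  if (ncol(genotypes) != nrow(ev))
    stop("genotype matrix does not match the panel")
  storage.mode(genotypes) <- "logical"
  if (model@model == "saturated") {
    tierLevel <- c(initial = 0, moderate = 1, maximal = 2)[ev$tier]
    lev <- apply(genotypes, 1L, function(g)
      if (any(g)) max(tierLevel[g]) else 0)
    p <- (1 + model@s)^lev * model@pInit
  } else {
    sk <- model@minSk + (ev$rank - 1) * model@deltaSk
    p <- model@pInit * (1 + as.numeric(genotypes %*% sk))
  }
  pmin(p, 1)
}

#' SCNA acquisition probability of a genotype
#'
#' Gene mutations are acquired with probability \code{pDriver}; SCNAs with
#' 0.001 * \code{pDriver}, raised to \code{pDriver} when the genotype
#' harbours a mutation in PBRM1 or BAP1 (SCNA-rate enhancers).
#'
#' @param genotype a [Genotype-class] or logical presence vector.
#' @param pDriver driver acquisition probability, in (0, 1].
#' @param panel a [DriverPanel-class].
#' @return The per-daughter per-SCNA acquisition probability.
#' @examples
#' panel <- defaultPanel()
#' scnaAcquisitionProbability(founderGenotype(panel), 2e-4, panel)
#' @export
scnaAcquisitionProbability <- function(genotype, pDriver, panel) {
  stopifnot(pDriver > 0, pDriver <= 1)
  pres <- .presenceOf(genotype)
  enh <- panel@events$enhances_scna_rate
  if (any(pres & enh)) pDriver else 0.001 * pDriver
}
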