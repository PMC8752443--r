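## Clone bookkeeping: cancer cell fractions, Shannon diversity, mean driver
## burden, tumour fitness, and the parallel-event catalogue.

#' Clonal composition of a scope
#'
#' Partitions the voxels of a whole tumour, slice or biopsy by their
#' (most-derived) clone label and returns per-clone voxel counts and cancer
#' cell fractions (CCF). Every voxel belongs to exactly one clone, so the
#' CCFs sum to 1.
#'
#' @param x a [TumourState-class], [TumourSlice-class], biopsy (list with a
#'   \code{sites} data.frame) or a data.frame with a \code{clone_id}
#'   column.
#' @return A data.frame of class \code{ClonalComposition} with columns
#'   \code{clone_id}, \code{n}, \code{ccf}, ordered by decreasing CCF;
#'   attribute \code{nVoxels} holds the scope size.
#' @examples
#' comp <- composition(data.frame(clone_id = rep(c(1, 2), c(60, 40))))
#' comp
#' shannonIndex(comp)
#' @export
composition <- function(x) {
  ids <- if (is(x, "TumourState")) x@occ[x@occ != 0L]
         else if (is(x, "TumourSlice")) x@sites$clone_id
         else if (is.data.frame(x)) x$clone_id
         else if (is.list(x) && !is.null(x$sites)) x$sites$clone_id
         else stop("unsupported scope object")
  if (length(ids) == 0L) stop("empty scope")
  tab <- table(ids)
  out <- data.frame(clone_id = as.integer(names(tab)),
                    n = as.integer(tab),
                    ccf = as.numeric(tab) / length(ids))
  out <- out[order(-out$ccf, out$clone_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nVoxels") <- length(ids)
  class(out) <- c("ClonalComposition", "data.frame")
  out
}

#' Detectable clones of a composition
#'
#' By default a clone is detectable when its CCF exceeds the threshold
#' strictly (CCF > 0.01). Counting conventions that include the threshold
#' ("CCF of at least 0.05") are supported with \code{inclusive = TRUE}.
#'
#' @param comp a \code{ClonalComposition} from [composition()].
#' @param threshold CCF threshold (default 0.01).
#' @param inclusive if TRUE, clones at exactly the threshold count.
#' @return The detectable subset of \code{comp}.
#' @export
detectableClones <- function(comp, threshold = 0.01, inclusive = FALSE) {
  keep <- if (inclusive) comp$ccf >= threshold else comp$ccf > threshold
  comp[keep, , drop = FALSE]
}

#' Shannon diversity index of a clonal composition
#'
#' S = sum_i (-f_i ln f_i) over all clones with f_i > 0 (0 ln 0 taken as
#' 0). Zero iff the scope is monoclonal; ln k at k equally frequent clones.
#'
#' @param comp a \code{ClonalComposition} (or any numeric vector of
#'   frequencies summing to 1).
#' @return The Shannon index (natural log).
#' @export
shannonIndex <- function(comp) {
  f <- if (is.data.frame(comp)) comp$ccf else as.numeric(comp)
  f <- f[f > 0]
  -sum(f * log(f))
}

#' Mean fitness of the voxels in a slice
#'
#' Tumour fitness is the average growth probability of tumour voxels in a
#' slice, each voxel's probability determined by its clone's genotype under
#' the slice's advantage model.
#'
#' @param slice a [TumourSlice-class].
#' @return Mean growth probability, in [pInit, 1].
#' @export
tumourFitness <- function(slice) mean(.siteFitness(slice))

#' Mean number of drivers per voxel in a slice
#'
#' Counts gene mutations plus SCNAs harboured by each voxel (via its clone)
#' and averages over the slice. Monotone non-decreasing over a simulation,
#' since drivers are never lost.
#'
#' @param slice a [TumourSlice-class].
#' @return Mean driver count per voxel.
#' @export
meanDrivers <- function(slice) {
  perClone <- rowSums(slice@genotypes)
  mean(perClone[slice@sites$clone_id])
}

## clones carrying an allele: the originating clone and all its descendants
.carrierClones <- function(clones, originId) {
  carriers <- originId
  frontier <- originId
  repeat {
    kids <- clones$clone_id[clones$parent_id %in% frontier]
    if (!length(kids)) break
    carriers <- c(carriers, kids)
    frontier <- kids
  }
  carriers
}

#' Catalogue of parallel mutational events across regions
#'
#' For every gene-mutation allele (independent acquisition of a mutation in
#' a gene), lists the regions (biopsies) in which voxels carrying that
#' allele occur. Distinct alleles of the same gene in different regions are
#' parallel evolution events. For alleles spanning exactly one region, the
#' distance from that region's centre to the tumour margin is reported.
#'
#' @param slice a [TumourSlice-class] (provides the margin contour and the
#'   clone registry).
#' @param biopsies a biopsy list from [sampleBiopsies()], or any list of
#'   lists with \code{centre} and \code{sites}.
#' @param alleles allele table of the source state
#'   (\code{state@alleles}): columns \code{allele_id}, \code{event_id},
#'   \code{clone_id} of the clone in which the allele arose.
#' @return data.frame with one row per allele observed in at least one
#'   region: \code{event_id}, \code{event_name}, \code{allele_id},
#'   \code{n_regions}, \code{regions} (";"-joined indices),
#'   \code{dist_to_margin} (NA unless \code{n_regions == 1}).
#' @export
parallelEventCatalog <- function(slice, biopsies, alleles) {
  ev <- slice@panel@events
  ## truncal alleles of the root clone span every region by construction
  ## and carry no parallel-evolution signal; they are excluded
  alleles <- alleles[alleles$clone_id != 1L, , drop = FALSE]
  if (nrow(alleles) == 0L || length(biopsies) == 0L)
    return(data.frame(event_id = integer(), event_name = character(),
                      allele_id = integer(), n_regions = integer(),
                      regions = character(), dist_to_margin = numeric()))
  rows <- lapply(seq_len(nrow(alleles)), function(i) {
    carriers <- .carrierClones(slice@clones, alleles$clone_id[i])
    inRegion <- vapply(biopsies, function(b)
      any(b$sites$clone_id %in% carriers), logical(1))
    regs <- which(inRegion)
    if (!length(regs)) return(NULL)
    dmar <- if (length(regs) == 1L)
      .distToPoints(biopsies[[regs]]$centre, slice@contourSmooth)
    else NA_real_
    data.frame(event_id = alleles$event_id[i],
               event_name = ev$name[alleles$event_id[i]],
               allele_id = alleles$allele_id[i],
               n_regions = length(regs),
               regions = paste(regs, collapse = ";"),
               dist_to_margin = dmar,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(event_id = integer(), event_name = character(),
                      allele_id = integer(), n_regions = integer(),
                      regions = character(), dist_to_margin = numeric())
  rownames(out) <- NULL
  out
}

#' Export a clonal composition as CSV
#' @param comp a \code{ClonalComposition}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeComposition <- function(comp, path) {
  utils::write.csv(as.data.frame(comp), path, row.names = FALSE)
  invisible(path)
}
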