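## Cohort interface: patient-style multi-region tables (no sequencing
## processing) - hotspot proxies, normalised centre distances, group
## comparisons of power-law exponents, parallel-event span maps.

## polygon centroid (area-weighted; falls back to vertex mean when the
## polygon is degenerate)
.polyCentroid <- function(P) {
  x <- P[, 1]; y <- P[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  if (abs(A) < 1e-9) return(c(mean(x), mean(y)))
  c(sum((x + x2) * cr) / (6 * A), sum((y + y2) * cr) / (6 * A))
}

## minimum distance from point p to the closed polygon boundary
.distToPolygon <- function(p, P) {
  n <- nrow(P)
  P2 <- rbind(P, P[1, , drop = FALSE])
  dmin <- Inf
  for (i in seq_len(n)) {
    a <- P2[i, ]; b <- P2[i + 1L, ]
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), 1e-12)
    t <- min(max(t, 0), 1)
    q <- a + t * ab
    dmin <- min(dmin, sqrt(sum((p - q)^2)))
  }
  dmin
}

#' Load a patient-style region table
#'
#' Delimited text with header columns \code{tumour_id}, \code{region_id},
#' \code{x_mm}, \code{y_mm}, \code{n_clones} and optional
#' \code{n_subclones} (defaults to \code{n_clones - 1}), \code{events}
#' (";"-separated labels) and \code{group}. Margins are supplied either as
#' a second CSV of per-tumour polygon points (\code{tumour_id},
#' \code{x_mm}, \code{y_mm}) or estimated as the convex hull of each
#' tumour's regions.
#'
#' @param path region table CSV path.
#' @param marginPath optional margin polygon CSV path.
#' @return A \code{RegionTable}: list(regions, margins) where margins is a
#'   named list of point matrices (possibly empty; hulls are computed on
#'   demand).
#' @export
loadRegionTable <- function(path, marginPath = NULL) {
  rg <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tumour_id", "region_id", "x_mm", "y_mm", "n_clones")
  missing <- setdiff(need, names(rg))
  if (length(missing))
    stop("region table missing columns: ", paste(missing, collapse = ", "))
  bad <- which(!is.finite(rg$x_mm) | !is.finite(rg$y_mm))
  if (length(bad))
    stop("non-finite coordinates in rows: ", paste(bad, collapse = ", "))
  bad <- which(rg$n_clones < 1)
  if (length(bad))
    stop("clone count below 1 in rows: ", paste(bad, collapse = ", "))
  if (is.null(rg$n_subclones)) rg$n_subclones <- rg$n_clones - 1L
  if (any(rg$n_subclones < 0))
    stop("negative subclone counts")
  margins <- list()
  if (!is.null(marginPath)) {
    mp <- utils::read.csv(marginPath, stringsAsFactors = FALSE)
    margins <- lapply(split(mp, mp$tumour_id), function(d)
      cbind(d$x_mm, d$y_mm))
  }
  structure(list(regions = rg, margins = margins), class = "RegionTable")
}

#' Write a region table (and margins) to CSV
#' @param rt a \code{RegionTable}.
#' @param path regions CSV path.
#' @param marginPath optional margins CSV path.
#' @return \code{path}, invisibly.
#' @export
writeRegionTable <- function(rt, path, marginPath = NULL) {
  utils::write.csv(rt$regions, path, row.names = FALSE)
  if (!is.null(marginPath) && length(rt$margins)) {
    mp <- do.call(rbind, lapply(names(rt$margins), function(id)
      data.frame(tumour_id = id, x_mm = rt$margins[[id]][, 1],
                 y_mm = rt$margins[[id]][, 2])))
    utils::write.csv(mp, marginPath, row.names = FALSE)
  }
  invisible(path)
}

.tumourMargin <- function(rt, id) {
  id <- as.character(id)
  if (!is.null(rt$margins[[id]])) return(rt$margins[[id]])
  d <- rt$regions[rt$regions$tumour_id == id, , drop = FALSE]
  pts <- unique(cbind(d$x_mm, d$y_mm))
  if (nrow(pts) < 3L)
    stop("tumour ", id, ": degenerate margin (fewer than 3 distinct points)")
  pts[chull(pts), , drop = FALSE]
}

#' Hotspot-proxy regions
#'
#' Regions harbouring at least \code{minSubclones} subclones are treated as
#' the patient-data proxy for microdiversity hotspots. The default
#' threshold of 1 follows the model definition on regional data; a
#' stricter reading (at least two subclones) is available by setting
#' \code{minSubclones = 2}.
#'
#' @param rt a \code{RegionTable}.
#' @param minSubclones proxy threshold (default 1).
#' @return The qualifying subset of the region table.
#' @export
hotspotProxy <- function(rt, minSubclones = 1) {
  rt$regions[rt$regions$n_subclones >= minSubclones, , drop = FALSE]
}

#' Normalised centre distances of regions
#'
#' For every region: d1 = distance to the tumour centre (margin-polygon
#' centroid), d2 = distance to the nearest margin point, and
#' d = d1 / (d1 + d2).
#'
#' @param rt a \code{RegionTable}.
#' @param regions optional region subset (e.g. from [hotspotProxy()]).
#' @return \code{regions} with columns \code{d1}, \code{d2}, \code{d}
#'   appended.
#' @export
regionDistances <- function(rt, regions = rt$regions) {
  out <- regions
  out$d1 <- out$d2 <- out$d <- NA_real_
  for (id in unique(regions$tumour_id)) {
    P <- .tumourMargin(rt, id)
    ctr <- .polyCentroid(P)
    rows <- which(regions$tumour_id == id)
    for (r in rows) {
      p <- c(regions$x_mm[r], regions$y_mm[r])
      d1 <- sqrt(sum((p - ctr)^2))
      d2 <- .distToPolygon(p, P)
      out$d1[r] <- d1
      out$d2[r] <- d2
      out$d[r] <- if (d1 + d2 > 0) d1 / (d1 + d2) else 0
    }
  }
  out
}

#' Compare power-law exponents between region groups
#'
#' Splits hotspot-proxy regions by a grouping column, fits the bootstrap
#' power law to each group's normalised centre distances, and compares the
#' bootstrap exponent samples pairwise with the two-sided Wilcoxon rank
#' test.
#'
#' @param rt a \code{RegionTable}.
#' @param grouping grouping column name (default "group").
#' @param minSubclones hotspot-proxy threshold.
#' @param nBoot,resampleSize bootstrap parameters for [fitPowerLaw()].
#' @param minRegions minimum hotspot-proxy regions per group (default 10).
#' @return list(fits = named list of [PowerLawFit-class], tests =
#'   data.frame of pairwise comparisons with p values).
#' @export
compareGroupExponents <- function(rt, grouping = "group", minSubclones = 1,
                                  nBoot = 100, resampleSize = 400,
                                  minRegions = 10) {
  hp <- hotspotProxy(rt, minSubclones)
  if (is.null(hp[[grouping]])) stop("no grouping column '", grouping, "'")
  hp <- regionDistances(rt, hp)
  groups <- split(hp, hp[[grouping]])
  if (length(groups) < 2L) stop("need at least 2 groups")
  small <- names(groups)[vapply(groups, nrow, integer(1)) < minRegions]
  if (length(small))
    stop("insufficient hotspot-proxy regions in group(s): ",
         paste(small, collapse = ", "))
  fits <- lapply(groups, function(g)
    fitPowerLaw(g$d, nBoot = nBoot, resampleSize = resampleSize))
  nm <- names(fits)
  tests <- list()
  for (i in seq_len(length(nm) - 1L)) for (j in (i + 1L):length(nm)) {
    w <- wilcox.test(fits[[i]]@kBoot, fits[[j]]@kBoot)
    tests[[length(tests) + 1L]] <- data.frame(
      group1 = nm[i], group2 = nm[j],
      median_k1 = stats::median(fits[[i]]@kBoot),
      median_k2 = stats::median(fits[[j]]@kBoot),
      p_value = w$p.value, stringsAsFactors = FALSE)
  }
  list(fits = fits, tests = do.call(rbind, tests))
}

#' Distances to margin of single-region mutational events
#'
#' Events spanning exactly one region have had limited clonal expansion;
#' their region's distance to the tumour margin localises them. Reports
#' one row per (tumour, event label) with the span and, for span 1, the
#' distance to the margin; a 10 mm reference distance flags deep
#' single-region events.
#'
#' @param rt a \code{RegionTable} whose regions carry an \code{events}
#'   column of ";"-separated labels.
#' @param reference reference distance in mm (default 10).
#' @return data.frame with columns \code{tumour_id}, \code{event},
#'   \code{n_regions}, \code{dist_to_margin}, \code{beyond_reference};
#'   attribute \code{reference_mm}.
#' @export
singleRegionEventDistances <- function(rt, reference = 10) {
  rg <- rt$regions
  if (is.null(rg$events)) stop("region table has no 'events' column")
  rg <- regionDistances(rt, rg)
  rows <- list()
  for (id in unique(rg$tumour_id)) {
    d <- rg[rg$tumour_id == id, , drop = FALSE]
    evs <- strsplit(ifelse(is.na(d$events), "", d$events), ";", fixed = TRUE)
    labels <- unique(unlist(evs))
    labels <- labels[nzchar(labels)]
    for (lab in labels) {
      hit <- vapply(evs, function(v) lab %in% v, logical(1))
      dm <- if (sum(hit) == 1L) d$d2[hit] else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        tumour_id = id, event = lab, n_regions = sum(hit),
        dist_to_margin = dm,
        beyond_reference = !is.na(dm) && dm > reference,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(tumour_id = character(), event = character(),
                      n_regions = integer(), dist_to_margin = numeric(),
                      beyond_reference = logical())
  attr(out, "reference_mm") <- reference
  out
}
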