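## Deterministic fixtures and synthetic-data generators: null-model
## hotspot samples, planted-exponent region tables, and small lattice
## states with known geometry.

#' Null-model hotspot distances: points uniform in a disc
#'
#' Samples n points uniformly at random within a disc of radius R and
#' returns their normalised centre distances d = r / R. For a point at
#' radius r, d1 = r and d2 = R - r, so d = d1 / (d1 + d2) = r / R with
#' cumulative distribution P(D <= d) = d^2: the null model is a power law
#' with exponent 2.
#'
#' @param n number of hotspots.
#' @param radius disc radius (mm); a non-positive radius collapses all
#'   points onto the centre and is flagged degenerate.
#' @param seed optional RNG seed.
#' @return Numeric vector of n distances in [0, 1]; attribute
#'   \code{degenerate} when radius <= 0.
#' @examples
#' d <- generateNullHotspots(400, seed = 1)
#' median(fitPowerLaw(d)@kBoot) # ~= 2
#' @export
generateNullHotspots <- function(n, radius = 1, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (radius <= 0) {
    warning("degenerate disc: all hotspots at the centre")
    return(structure(rep(0, n), degenerate = TRUE))
  }
  r <- radius * sqrt(runif(n))
  structure(r / radius, degenerate = FALSE)
}

#' Generate a synthetic multi-region table with planted spatial structure
#'
#' Builds a patient-style region table for testing the cohort analyses.
#' Hotspot regions (those with at least one subclone) are placed at
#' normalised centre distances drawn from the planted law P(D <= d) = d^k
#' (k = 2 reproduces spatial uniformity; larger k enriches the margin);
#' the remaining regions are uniform in the disc. Optional planted events
#' attach labels to dedicated regions at chosen depths from the margin,
#' with configured spans.
#'
#' @param spec list with fields \code{n_tumours}, \code{regions_per_tumour},
#'   \code{pattern} ("uniform" or "edge_enriched"), \code{k} (exponent for
#'   edge_enriched), \code{hotspot_fraction} (default 0.5),
#'   \code{margin_radius} mm (default 30), \code{group} optional group
#'   label, and optionally \code{planted_events}: data.frame(tumour_id,
#'   event, span, depth_mm).
#' @param seed RNG seed.
#' @return A \code{RegionTable} with explicit circular margin polygons.
#' @export
generateSyntheticRegionTable <- function(spec, seed = 1) {
  stopifnot(is.list(spec), spec$n_tumours >= 1, spec$regions_per_tumour >= 1)
  pattern <- match.arg(spec$pattern, c("uniform", "edge_enriched"))
  k <- if (pattern == "uniform") 2 else spec$k
  if (is.null(k) || k <= 0) stop("edge_enriched pattern needs exponent k > 0")
  hf <- if (is.null(spec$hotspot_fraction)) 0.5 else spec$hotspot_fraction
  R <- if (is.null(spec$margin_radius)) 30 else spec$margin_radius
  set.seed(seed)
  rows <- list()
  margins <- list()
  theta <- seq(0, 2 * pi, length.out = 73)[-73]
  for (t in seq_len(spec$n_tumours)) {
    tid <- sprintf("T%03d", t)
    m <- spec$regions_per_tumour
    nh <- round(hf * m)
    isHot <- seq_len(m) <= nh
    d <- ifelse(isHot, runif(m)^(1 / k), sqrt(runif(m)))
    ang <- runif(m, 0, 2 * pi)
    rows[[t]] <- data.frame(
      tumour_id = tid, region_id = sprintf("%s_R%03d", tid, seq_len(m)),
      x_mm = R + d * R * cos(ang), y_mm = R + d * R * sin(ang),
      n_clones = ifelse(isHot, 2L + stats::rpois(m, 1), 1L),
      n_subclones = NA_integer_, events = "", group =
        if (is.null(spec$group)) "" else spec$group,
      stringsAsFactors = FALSE)
    rows[[t]]$n_subclones <- rows[[t]]$n_clones - 1L
    margins[[tid]] <- cbind(R + R * cos(theta), R + R * sin(theta))
  }
  rg <- do.call(rbind, rows)
  pe <- spec$planted_events
  if (!is.null(pe)) for (i in seq_len(nrow(pe))) {
    tid <- as.character(pe$tumour_id[i])
    span <- pe$span[i]
    if (span == 1L && !is.null(pe$depth_mm)) {
      ## dedicated region at the planted depth from the margin
      rg <- rbind(rg, data.frame(
        tumour_id = tid,
        region_id = sprintf("%s_E%02d", tid, i),
        x_mm = R + (R - pe$depth_mm[i]), y_mm = R,
        n_clones = 2L, n_subclones = 1L, events = pe$event[i],
        group = rg$group[rg$tumour_id == tid][1],
        stringsAsFactors = FALSE))
    } else {
      rows_t <- which(rg$tumour_id == tid)[seq_len(span)]
      rg$events[rows_t] <- ifelse(nzchar(rg$events[rows_t]),
                                  paste(rg$events[rows_t], pe$event[i],
                                        sep = ";"), pe$event[i])
    }
  }
  structure(list(regions = rg, margins = margins), class = "RegionTable")
}

#' Deterministic lattice fixtures with known geometry
#'
#' Small tumour states used by unit tests and examples:
#' \describe{
#'   \item{cube3}{a 3x3x3 solid cube (27 voxels; the centre voxel is fully
#'     enclosed).}
#'   \item{disc20}{a one-voxel-thick digital disc of radius 20 in the
#'     central plane.}
#'   \item{sphere20}{a solid ball of radius 20 (maximum depth about
#'     20 mm).}
#'   \item{row5}{a 1D row of 5 voxels along x.}
#'   \item{twolobe}{a disc of radius 12 with a budding lobe of radius 6 on
#'     its margin, in the central plane.}
#' }
#' All voxels belong to the parental clone.
#'
#' @param name fixture name.
#' @param L optional lattice side (sensible default per fixture).
#' @return A [TumourState-class].
#' @export
fixtureLattice <- function(name = c("cube3", "disc20", "sphere20", "row5",
                                    "twolobe"), L = NULL) {
  name <- match.arg(name)
  L <- as.integer(if (!is.null(L)) L
                  else switch(name, cube3 = 9, disc20 = 60, sphere20 = 60,
                              row5 = 15, twolobe = 60))
  cfg <- simulationConfig(L = L, stopSize = min(1e6, as.numeric(L)^3),
                          seed = 1L)
  state <- newTumourState(cfg)
  c0 <- latticeCentre(L)
  g <- expand.grid(x = seq_len(L), y = seq_len(L), z = seq_len(L))
  keep <- switch(name,
    cube3 = abs(g$x - c0) <= 1 & abs(g$y - c0) <= 1 & abs(g$z - c0) <= 1,
    disc20 = g$z == c0 & (g$x - c0)^2 + (g$y - c0)^2 <= 20^2,
    sphere20 = (g$x - c0)^2 + (g$y - c0)^2 + (g$z - c0)^2 <= 20^2,
    row5 = g$y == c0 & g$z == c0 & g$x >= c0 - 2 & g$x <= c0 + 2,
    twolobe = g$z == c0 &
      ((g$x - c0)^2 + (g$y - c0)^2 <= 12^2 |
       (g$x - (c0 + 12))^2 + (g$y - c0)^2 <= 6^2))
  idx <- which(keep)
  occ <- array(0L, dim = c(L, L, L))
  occ[cbind(g$x[idx], g$y[idx], g$z[idx])] <- 1L
  state@occ <- occ
  state@birth <- array(0L, dim = c(L, L, L))
  founder <- array(0L, dim = c(L, L, L))
  fpos <- if (occ[c0, c0, c0] == 1L) c(c0, c0, c0) else
    c(g$x[idx[1]], g$y[idx[1]], g$z[idx[1]])
  founder[fpos[1], fpos[2], fpos[3]] <- 1L
  state@founder <- founder
  state@clones$origin_x <- fpos[1]
  state@clones$origin_y <- fpos[2]
  state@clones$origin_z <- fpos[3]
  state
}
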