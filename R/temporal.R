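## Time-course statistics over snapshot series: diversity-size
## trajectories, 2D kernel density estimates, evolutionary flow fields and
## replay divergence.

#' Time course of slice-level statistics over a snapshot series
#'
#' For each snapshot the central (z0) tumour slice is extracted and
#' summarised: equivalent circular diameter 2 sqrt(Area / pi) in mm,
#' detectable clone and subclone counts (slice CCF > \code{ccfThreshold}),
#' mean driver burden, mean fitness, and contour circularity (NA while the
#' contour is degenerate).
#'
#' @param snapshots list of [Snapshot-class] objects from one run.
#' @param z slice plane (default: the lattice centre plane).
#' @param ccfThreshold detection threshold for clone counts (default 0.01,
#'   strict).
#' @return data.frame of class \code{TimeCourse}, one row per snapshot.
#' @export
timeCourse <- function(snapshots, z = NULL, ccfThreshold = 0.01) {
  stopifnot(length(snapshots) >= 1L)
  rows <- lapply(snapshots, function(sn) {
    sl <- snapshotSlice(sn, z)
    comp <- composition(sl)
    det <- detectableClones(comp, ccfThreshold)
    circ <- if (nrow(sl@contour) >= 3L) circularity(sl) else NA_real_
    data.frame(step = sn@step,
               n_voxels_slice = sliceArea(sl),
               diameter = 2 * sqrt(sliceArea(sl) / pi),
               n_clones_detectable = nrow(det),
               n_subclones_detectable = sum(det$clone_id != 1L),
               mean_drivers = meanDrivers(sl),
               mean_fitness = tumourFitness(sl),
               circularity = circ)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("TimeCourse", "data.frame")
  out
}

#' 2D Gaussian kernel density of diversity against slice size
#'
#' Kernel density estimate over (slice diameter, subclone count) pairs
#' pooled across runs and time points, with Scott's-rule bandwidths by
#' default, plus the density level enclosing 90% of the probability mass
#' and its iso-contours.
#'
#' @param diameter numeric vector of slice diameters (mm).
#' @param nSubclones numeric vector of subclone counts (same length).
#' @param bandwidth optional c(hx, hy) kernel standard deviations;
#'   defaults to Scott's rule sd * n^(-1/6) per axis.
#' @param gridSize evaluation grid resolution (default 101).
#' @param mass probability mass for the highlighted contour (default 0.9).
#' @return list(x, y, z = density grid, level = density threshold
#'   enclosing \code{mass}, contours = contour lines at that level,
#'   bandwidth).
#' @export
kdeDiversitySize <- function(diameter, nSubclones, bandwidth = NULL,
                             gridSize = 101, mass = 0.90) {
  stopifnot(length(diameter) == length(nSubclones))
  n <- length(diameter)
  if (n < 10L) stop("need at least 10 points for a density estimate")
  if (sd(diameter) == 0 && sd(nSubclones) == 0)
    stop("degenerate input: all points identical")
  if (is.null(bandwidth)) {
    sc <- function(v) max(sd(v), 1e-6) * n^(-1 / 6)
    bandwidth <- c(sc(diameter), sc(nSubclones))
  }
  pad <- 3 * bandwidth
  ## MASS::kde2d's h is ~4x the Gaussian kernel sd (bandwidth.nrd scale)
  kd <- MASS::kde2d(diameter, nSubclones, h = 4 * bandwidth, n = gridSize,
                    lims = c(range(diameter) + c(-1, 1) * pad[1],
                             range(nSubclones) + c(-1, 1) * pad[2]))
  cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  dens <- sort(as.numeric(kd$z), decreasing = TRUE)
  cum <- cumsum(dens) * cell
  level <- dens[which(cum >= mass * cum[length(cum)])[1]]
  if (is.na(level)) level <- min(dens)
  list(x = kd$x, y = kd$y, z = kd$z, level = level,
       contours = grDevices::contourLines(kd$x, kd$y, kd$z, levels = level),
       bandwidth = bandwidth)
}

#' Evolutionary flow field over (subclone count, driver burden)
#'
#' Bins per-step displacement vectors of time-course trajectories in the
#' (detectable subclone count, mean drivers) plane and averages them per
#' bin. Bins observed fewer than \code{minObs} times are masked.
#'
#' @param trajectories list of \code{TimeCourse} data.frames (or any
#'   data.frames with the two named columns).
#' @param xcol,ycol trajectory columns spanning the plane.
#' @param nBins number of bins per axis (default 10).
#' @param minObs minimum observations per bin (default 3).
#' @return data.frame with bin centres (\code{x}, \code{y}), mean
#'   displacement (\code{dx}, \code{dy}), observation count \code{n} and
#'   \code{masked}.
#' @export
flowField <- function(trajectories, xcol = "n_subclones_detectable",
                      ycol = "mean_drivers", nBins = 10, minObs = 3) {
  segs <- do.call(rbind, lapply(trajectories, function(tc) {
    if (nrow(tc) < 2L) return(NULL)
    data.frame(x = tc[[xcol]][-nrow(tc)], y = tc[[ycol]][-nrow(tc)],
               dx = diff(tc[[xcol]]), dy = diff(tc[[ycol]]))
  }))
  if (is.null(segs) || nrow(segs) == 0L)
    stop("need at least one trajectory with two or more points")
  xb <- seq(min(segs$x), max(segs$x), length.out = nBins + 1L)
  yb <- seq(min(segs$y), max(segs$y), length.out = nBins + 1L)
  xi <- findInterval(segs$x, xb, rightmost.closed = TRUE, all.inside = TRUE)
  yi <- findInterval(segs$y, yb, rightmost.closed = TRUE, all.inside = TRUE)
  key <- paste(xi, yi)
  agg <- aggregate(segs[, c("dx", "dy")], by = list(key = key), FUN = mean)
  cnt <- as.data.frame(table(key), stringsAsFactors = FALSE)
  agg <- merge(agg, cnt, by = "key")
  ij <- do.call(rbind, strsplit(agg$key, " "))
  xi <- as.integer(ij[, 1]); yi <- as.integer(ij[, 2])
  data.frame(x = (xb[xi] + xb[xi + 1L]) / 2, y = (yb[yi] + yb[yi + 1L]) / 2,
             dx = agg$dx, dy = agg$dy, n = agg$Freq,
             masked = agg$Freq < minObs)
}

## clone frequencies keyed by driver-set genotype (allele ids ignored)
.genotypeFreqs <- function(x) {
  if (is(x, "TumourState")) {
    ids <- x@occ[x@occ != 0L]
    G <- x@genotypes
  } else if (is(x, "Snapshot")) {
    ids <- x@voxels$clone_id
    G <- .genotypesFromRegistry(x@clones, nrow(as.data.frame(x@config$panel)))
  } else stop("unsupported replay outcome object")
  keys <- apply(G, 1L, .genoHex)
  tab <- tapply(rep(1, length(ids)), keys[ids], sum)
  tab / sum(tab)
}

.jsDivergence <- function(p, q) {
  keys <- union(names(p), names(q))
  pv <- setNames(rep(0, length(keys)), keys); pv[names(p)] <- p
  qv <- setNames(rep(0, length(keys)), keys); qv[names(q)] <- q
  m <- (pv + qv) / 2
  kl <- function(a, b) { i <- a > 0; sum(a[i] * log(a[i] / b[i])) }
  0.5 * kl(pv, m) + 0.5 * kl(qv, m)
}

#' Divergence between evolutionary-replay outcomes
#'
#' Pairwise Jensen-Shannon divergence (natural log; maximum ln 2) between
#' the final clone-frequency distributions of replay replicates, with
#' clones keyed by their driver event set so that parallel events hitting
#' the same genes compare as equivalent outcomes. The mean pairwise
#' divergence is the (inverse) repeatability score: lower values mean more
#' repeatable evolution.
#'
#' @param states list of final [TumourState-class] objects (elements of
#'   [replaySimulation()] results' \code{state}).
#' @return list(matrix = pairwise divergence matrix, mean = mean pairwise
#'   divergence).
#' @export
replayDivergence <- function(states) {
  stopifnot(length(states) >= 2L)
  freqs <- lapply(states, .genotypeFreqs)
  n <- length(freqs)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    m[i, j] <- m[j, i] <- .jsDivergence(freqs[[i]], freqs[[j]])
  list(matrix = m, mean = mean(m[upper.tri(m)]))
}
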