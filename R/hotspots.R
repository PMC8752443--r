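## Microdiversity mapping, hotspot distances, power-law gradient fitting,
## youngest subclones, fitness gradients and regional biopsy sampling.

.distToPoints <- function(p, pts)
  sqrt(min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2))

#' Sample regional biopsies on a uniform grid
#'
#' Candidate biopsy centres are laid out over the Lx x Ly mm slice plane
#' with the given spacing (anchored at spacing/2 from the lattice origin);
#' each biopsy collects all tumour voxels within \code{radius} mm of its
#' centre. Candidates with no tumour voxel are dropped.
#'
#' @param slice a [TumourSlice-class].
#' @param spacing grid spacing in mm (default 20).
#' @param radius biopsy radius in mm (default 5).
#' @return A list of biopsies, each a list with \code{centre} (x, y) and
#'   \code{sites} (subset of the slice site table).
#' @export
sampleBiopsies <- function(slice, spacing = 20, radius = 5) {
  gx <- seq(spacing / 2, slice@dims[1], by = spacing)
  gy <- seq(spacing / 2, slice@dims[2], by = spacing)
  centres <- expand.grid(x = gx, y = gy)
  s <- slice@sites
  out <- list()
  for (i in seq_len(nrow(centres))) {
    cx <- centres$x[i]; cy <- centres$y[i]
    keep <- (s$x - cx)^2 + (s$y - cy)^2 <= radius^2
    if (any(keep))
      out[[length(out) + 1L]] <- list(centre = c(cx, cy),
                                      sites = s[keep, , drop = FALSE])
  }
  out
}

#' Microdiversity map of a tumour slice
#'
#' Slides a \code{window} x \code{window} mm^2 window (stride 1 mm) over
#' the slice and counts the distinct clones in each window position that
#' contains at least one tumour voxel.
#'
#' @param slice a [TumourSlice-class].
#' @param window window side length in mm (default 3).
#' @return data.frame with window centres (\code{cx}, \code{cy}), clone
#'   count \code{n_clones} and occupied-site count \code{n_sites}.
#' @export
microdiversityMap <- function(slice, window = 3) {
  w <- as.integer(window)
  lab <- matrix(0L, slice@dims[1], slice@dims[2])
  lab[cbind(slice@sites$x, slice@sites$y)] <- slice@sites$clone_id
  xr <- range(slice@sites$x); yr <- range(slice@sites$y)
  x0s <- max(1L, xr[1] - w + 1L):min(slice@dims[1] - w + 1L, xr[2])
  y0s <- max(1L, yr[1] - w + 1L):min(slice@dims[2] - w + 1L, yr[2])
  res <- vector("list", length(x0s) * length(y0s))
  n <- 0L
  for (y0 in y0s) for (x0 in x0s) {
    block <- lab[x0:(x0 + w - 1L), y0:(y0 + w - 1L)]
    occ <- block[block != 0L]
    if (length(occ)) {
      n <- n + 1L
      res[[n]] <- c(x0 + (w - 1) / 2, y0 + (w - 1) / 2,
                    length(unique(occ)), length(occ))
    }
  }
  out <- as.data.frame(do.call(rbind, res[seq_len(n)]))
  names(out) <- c("cx", "cy", "n_clones", "n_sites")
  out
}

#' Microdiversity hotspots and their normalised centre distances
#'
#' Hotspots are sliding-window positions containing \code{minClones} or
#' more distinct clones. For each hotspot, d1 is the distance from the
#' window centre to the tumour centre (slice centroid), d2 the distance to
#' the nearest point of the (smoothed) tumour contour, and
#' d = d1 / (d1 + d2) the normalised distance to the tumour centre
#' (0 = centre, 1 = margin).
#'
#' @param map a microdiversity map from [microdiversityMap()].
#' @param slice the [TumourSlice-class] the map was computed on.
#' @param minClones hotspot threshold (default 5 clones).
#' @return data.frame with columns \code{cx}, \code{cy}, \code{n_clones},
#'   \code{d1}, \code{d2}, \code{d}.
#' @export
hotspotsAndDistances <- function(map, slice, minClones = 5) {
  hs <- map[map$n_clones >= minClones, , drop = FALSE]
  if (nrow(hs) == 0L)
    return(data.frame(cx = numeric(), cy = numeric(), n_clones = integer(),
                      d1 = numeric(), d2 = numeric(), d = numeric()))
  ctr <- slice@centre
  hs$d1 <- sqrt((hs$cx - ctr[1])^2 + (hs$cy - ctr[2])^2)
  hs$d2 <- apply(hs[, c("cx", "cy")], 1L, .distToPoints,
                 pts = slice@contourSmooth)
  hs$d <- ifelse(hs$d1 + hs$d2 > 0, hs$d1 / (hs$d1 + hs$d2), 0)
  hs[, c("cx", "cy", "n_clones", "d1", "d2", "d")]
}

## least-squares fit of the empirical CDF P(D <= d) against d^k
.fitExponent <- function(d) {
  ds <- sort(d)
  P <- seq_along(ds) / length(ds)
  obj <- function(k) sum((P - ds^k)^2)
  opt <- optimize(obj, interval = c(1e-3, 50))
  c(k = opt$minimum, sse = opt$objective)
}

#' Bootstrap power-law fit of hotspot centre-distance distribution
#'
#' Fits P(D <= d) ~ d^k by least squares on the empirical cumulative
#' distribution, and bootstraps the exponent: \code{nBoot} resamples of
#' \code{resampleSize} distances drawn with replacement, one fit per
#' resample. Spatially uniform hotspots in a disc give k = 2; k > 2
#' indicates enrichment towards the tumour margin.
#'
#' @param d normalised centre distances in (0, 1].
#' @param nBoot number of bootstrap resamples (default 100).
#' @param resampleSize distances per resample (default 400).
#' @return A [PowerLawFit-class].
#' @examples
#' d <- sqrt(runif(400)) # uniform in a disc: CDF d^2
#' fitPowerLaw(d)
#' @export
fitPowerLaw <- function(d, nBoot = 100, resampleSize = 400) {
  d <- d[is.finite(d) & d > 0 & d <= 1]
  if (length(d) < 10L)
    stop("need at least 10 distances in (0, 1] to fit a power law")
  degenerate <- diff(range(d)) < 1e-8
  point <- .fitExponent(d)
  kBoot <- vapply(seq_len(nBoot), function(i)
    .fitExponent(sample(d, resampleSize, replace = TRUE))[1], numeric(1))
  if (degenerate)
    warning("degenerate distance sample: all values (nearly) identical")
  new("PowerLawFit", k = unname(point[1]), kBoot = kBoot,
      nBoot = as.integer(nBoot), resampleSize = as.integer(resampleSize),
      n = length(d), sse = unname(point[2]), degenerate = degenerate)
}

#' Log-log linear cross-check of the power-law exponent
#'
#' Ordinary least squares of log P(D <= d) on log d; provided as an
#' independent check on the nonlinear CDF fit.
#'
#' @param d normalised centre distances in (0, 1].
#' @return The slope (exponent estimate).
#' @export
fitPowerLawLogLog <- function(d) {
  d <- d[is.finite(d) & d > 0 & d <= 1]
  ds <- sort(d)
  P <- seq_along(ds) / length(ds)
  keep <- ds < 1
  unname(coef(stats::lm(log(P[keep]) ~ log(ds[keep])))[2])
}

#' Quantile-quantile table against a fitted power law
#'
#' Pairs the empirical quantiles of the distances with the theoretical
#' quantiles of the distribution P(D <= d) = d^k (quantile function
#' p^(1/k)).
#'
#' @param d normalised centre distances.
#' @param k power-law exponent.
#' @return data.frame with columns \code{theoretical} and
#'   \code{empirical}.
#' @export
qqAgainstPowerLaw <- function(d, k) {
  ds <- sort(d)
  n <- length(ds)
  p <- (seq_len(n) - 0.5) / n
  data.frame(theoretical = p^(1 / k), empirical = ds)
}

#' Youngest subclones in a slice and their distances to the margin
#'
#' The \code{n} most recently founded subclones present in the slice
#' (largest birth step; the parental clone is excluded). Each subclone's
#' position is the recorded position of its initiating voxel; the distance
#' is measured from that position to the nearest contour point. If fewer
#' than \code{n} subclones are present, all are returned and the result is
#' flagged.
#'
#' @param slice a [TumourSlice-class].
#' @param n number of youngest subclones to record (default 100).
#' @return list(subclones = data.frame(clone_id, birth_step, x, y,
#'   dist_to_margin), meanDistance, flagged).
#' @export
youngestSubclones <- function(slice, n = 100) {
  present <- unique(slice@sites$clone_id)
  sub <- slice@clones[slice@clones$clone_id %in% setdiff(present, 1L), ,
                      drop = FALSE]
  flagged <- nrow(sub) < n
  ord <- order(-sub$birth_step, -sub$clone_id)
  sub <- sub[head(ord, n), , drop = FALSE]
  if (nrow(sub) == 0L)
    return(list(subclones = data.frame(), meanDistance = NA_real_,
                flagged = flagged))
  dmar <- apply(cbind(sub$origin_x, sub$origin_y), 1L, .distToPoints,
                pts = slice@contourSmooth)
  list(subclones = data.frame(clone_id = sub$clone_id,
                              birth_step = sub$birth_step,
                              x = sub$origin_x, y = sub$origin_y,
                              dist_to_margin = dmar),
       meanDistance = mean(dmar), flagged = flagged)
}

## per-site growth probabilities of a slice
.siteFitness <- function(slice) {
  probs <- cloneGrowthProbs(slice@genotypes, slice@advantage, slice@panel)
  probs[slice@sites$clone_id]
}

#' Spatial fitness gradient of a tumour slice
#'
#' Samples the central-most, marginal-most and a random fraction (default
#' 10%) of slice voxels, by distance to the slice centre and to the nearest
#' contour point respectively, and reports their mean fitness (growth
#' probability) plus the centre-to-margin ratio Ratio_C2M.
#'
#' @param slice a [TumourSlice-class].
#' @param fraction sampled fraction of slice voxels (default 0.10).
#' @return list(central, marginal, random, ratioC2M).
#' @export
fitnessGradient <- function(slice, fraction = 0.10) {
  s <- slice@sites
  n <- nrow(s)
  if (n < 10L) stop("slice too small for fitness-gradient sampling")
  fit <- .siteFitness(slice)
  dC <- sqrt((s$x - slice@centre[1])^2 + (s$y - slice@centre[2])^2)
  dM <- apply(cbind(s$x, s$y), 1L, .distToPoints, pts = slice@contourSmooth)
  ns <- max(1L, round(fraction * n))
  central <- mean(fit[order(dC)[seq_len(ns)]])
  marginal <- mean(fit[order(dM)[seq_len(ns)]])
  random <- mean(fit[sample.int(n, ns)])
  list(central = central, marginal = marginal, random = random,
       ratioC2M = central / marginal)
}
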