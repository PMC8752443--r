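## 2D tumour slices: extraction, Moore contour tracing, per-point contour
## smoothing, circularity, and spatial homogenisation.

## Moore boundary following on 8-connectivity. M: logical matrix (x rows,
## y cols). Returns a matrix of (x, y) contour points in tracing order;
## points can repeat where the structure is one voxel wide.
.traceContour <- function(M) {
  nx <- nrow(M); ny <- ncol(M)
  occAt <- function(x, y) x >= 1 && x <= nx && y >= 1 && y <= ny && M[x, y]
  ## start: first occupied site scanning y then x, so (x-1, y) is empty
  start <- NULL
  for (y in seq_len(ny)) {
    xs <- which(M[, y])
    if (length(xs)) { start <- c(xs[1], y); break }
  }
  if (is.null(start)) stop("empty slice")
  ## clockwise Moore neighbourhood beginning west
  dirs <- cbind(x = c(-1, -1, 0, 1, 1, 1, 0, -1),
                y = c(0, 1, 1, 1, 0, -1, -1, -1))
  pts <- list(start)
  cur <- start
  back <- start + c(-1, 0) # backtrack: empty by the scan order
  limit <- 4L * (sum(M) + 1L)
  firstMove <- NULL
  repeat {
    rel <- back - cur
    bi <- which(dirs[, 1] == rel[1] & dirs[, 2] == rel[2])
    qnext <- NULL
    for (k in seq_len(8L)) { # clockwise from the cell after the backtrack
      j <- ((bi - 1L + k) %% 8L) + 1L
      q <- cur + dirs[j, ]
      if (occAt(q[1], q[2])) {
        qnext <- unname(q)
        newBack <- unname(cur + dirs[((j - 2L) %% 8L) + 1L, ])
        break
      }
    }
    if (is.null(qnext)) return(matrix(start, 1L)) # isolated voxel
    atStart <- all(cur == start)
    if (atStart && !is.null(firstMove) && all(qnext == firstMove)) break
    if (atStart && is.null(firstMove)) firstMove <- qnext
    pts[[length(pts) + 1L]] <- qnext
    back <- newBack
    cur <- qnext
    if (length(pts) > limit) break
  }
  ## the final point closes onto the start; drop the duplicate if present
  if (length(pts) > 1L && all(pts[[length(pts)]] == start))
    pts[[length(pts)]] <- NULL
  do.call(rbind, pts)
}

## smoothed contour: per contour voxel, mean (x, y) position of the voxel
## and its adjacent tumour voxels along the traced contour (cyclic window
## of three); removes the lattice staircase without pulling the boundary
## inward, so a digital disc keeps perimeter ~ 2 pi r. Same point count as
## the input.
.smoothContour <- function(contour, M) {
  n <- nrow(contour)
  if (n < 3L) return(contour)
  prv <- contour[c(n, seq_len(n - 1L)), , drop = FALSE]
  nxt <- contour[c(seq_len(n)[-1L], 1L), , drop = FALSE]
  (prv + contour + nxt) / 3
}

#' Construct a tumour slice from a site table
#'
#' Computes the slice centre (centroid of occupied sites) and traces and
#' smooths the tumour contour. Used by [extractSlice()] and directly by
#' crafted fixtures.
#'
#' @param sites data.frame with columns \code{x}, \code{y},
#'   \code{clone_id}, \code{birth_step}.
#' @param dims lattice extent c(Lx, Ly).
#' @param clones clone registry data.frame.
#' @param genotypes logical clones x events matrix.
#' @param panel a [DriverPanel-class].
#' @param advantage an [AdvantageModel-class].
#' @param z0 slice plane label.
#' @return A [TumourSlice-class].
#' @export
tumourSlice <- function(sites, dims, clones, genotypes, panel, advantage,
                        z0 = 0L) {
  if (nrow(sites) == 0L) stop("empty slice")
  M <- matrix(FALSE, dims[1], dims[2])
  M[cbind(sites$x, sites$y)] <- TRUE
  contour <- .traceContour(M)
  colnames(contour) <- c("x", "y")
  smooth <- .smoothContour(contour, M)
  colnames(smooth) <- c("x", "y")
  new("TumourSlice", z0 = as.integer(z0), sites = sites,
      dims = as.integer(dims), centre = c(mean(sites$x), mean(sites$y)),
      contour = contour, contourSmooth = smooth, clones = clones,
      genotypes = genotypes, panel = panel, advantage = advantage)
}

#' Extract the 2D tumour slice at a plane
#'
#' All tumour voxels within the plane z = z0 (default: the lattice centre
#' plane through the founder voxel).
#'
#' @param state a [TumourState-class].
#' @param z slice plane; defaults to the founder plane z0.
#' @return A [TumourSlice-class].
#' @export
extractSlice <- function(state, z = NULL) {
  L <- state@config@L
  if (is.null(z)) z <- latticeCentre(L)
  occ2 <- state@occ[, , z]
  idx <- which(occ2 != 0L)
  if (!length(idx)) stop("plane z = ", z, " does not intersect the tumour")
  co <- arrayInd(idx, dim(occ2))
  sites <- data.frame(x = co[, 1], y = co[, 2], clone_id = occ2[idx],
                      birth_step = state@birth[, , z][idx])
  tumourSlice(sites, dim(occ2), state@clones, state@genotypes,
              state@config@panel, state@config@advantage, z0 = z)
}

#' Extract a slice from a snapshot
#'
#' @param snapshot a [Snapshot-class].
#' @param z slice plane; defaults to the founder plane of the snapshot's
#'   lattice.
#' @return A [TumourSlice-class].
#' @export
snapshotSlice <- function(snapshot, z = NULL) {
  cfg <- .configFromList(snapshot@config)
  if (is.null(z)) z <- latticeCentre(cfg@L)
  v <- snapshot@voxels
  v <- v[v$z == z, , drop = FALSE]
  if (nrow(v) == 0L) stop("plane z = ", z, " does not intersect the tumour")
  sites <- data.frame(x = v$x, y = v$y, clone_id = v$clone_id,
                      birth_step = v$birth_step)
  G <- .genotypesFromRegistry(snapshot@clones, nEvents(cfg@panel))
  tumourSlice(sites, c(cfg@L, cfg@L), snapshot@clones, G, cfg@panel,
              cfg@advantage, z0 = z)
}

#' Slice area in mm^2
#' @param slice a [TumourSlice-class].
#' @return Occupied-site count (1 site = 1 mm^2).
#' @export
sliceArea <- function(slice) nrow(slice@sites)

#' Perimeter of the smoothed tumour contour in mm
#' @param slice a [TumourSlice-class].
#' @return Closed polyline length of the smoothed contour.
#' @export
slicePerimeter <- function(slice) {
  P <- slice@contourSmooth
  if (nrow(P) < 2L) return(0)
  Q <- rbind(P, P[1L, , drop = FALSE])
  sum(sqrt(rowSums(diff(Q)^2)))
}

#' Contour circularity of a tumour slice
#'
#' The isoperimetric ratio 4 pi Area / Perimeter^2, computed with the
#' occupied-site count as Area (mm^2) and the smoothed-contour polyline
#' length as Perimeter (mm). Equals 1 for a perfect circle and decreases
#' towards 0 for elongated or lobed shapes. (Note: the quantity is the
#' standard dimensionless isoperimetric ratio with the squared perimeter in
#' the denominator; an unsquared perimeter would leave the measure
#' dimensional.)
#'
#' @param slice a [TumourSlice-class].
#' @return Circularity in (0, 1 + epsilon].
#' @export
circularity <- function(slice) {
  if (nrow(slice@contour) < 3L)
    stop("degenerate contour: fewer than 3 points")
  4 * pi * sliceArea(slice) / slicePerimeter(slice)^2
}

#' Spatially homogenise a slice
#'
#' Permutes clone labels uniformly at random across the occupied sites.
#' The label multiset (and hence any clonal composition) is preserved;
#' the geometry, contour and centre are untouched. Used as the null
#' control that destroys spatial clustering of subclones.
#'
#' @param slice a [TumourSlice-class].
#' @param seed optional RNG seed for reproducibility.
#' @return A [TumourSlice-class] with permuted labels.
#' @export
homogenise <- function(slice, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(nrow(slice@sites))
  slice@sites$clone_id <- slice@sites$clone_id[perm]
  slice@sites$birth_step <- slice@sites$birth_step[perm]
  slice
}
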