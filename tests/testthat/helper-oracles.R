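# Independent oracles and crafted-state helpers shared across test files.

# Brute-force depth field: exterior empty region found by flood fill from
# the lattice boundary (6-connectivity), then a direct minimisation of the
# Euclidean distance from every site to the exterior sites. Independent of
# the distance-transform implementation in the package.
bruteDepthField <- function(occ) {
  dims <- dim(occ)
  ext <- array(FALSE, dims)
  co <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                              z = seq_len(dims[3])))
  onBoundary <- co[, 1] %in% c(1, dims[1]) | co[, 2] %in% c(1, dims[2]) |
    co[, 3] %in% c(1, dims[3])
  queue <- which(onBoundary & occ[co] == 0)
  ext[co[queue, , drop = FALSE]] <- TRUE
  steps <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  while (length(queue)) {
    nxt <- integer()
    for (i in queue) {
      p <- co[i, ]
      for (k in 1:6) {
        q <- p + steps[k, ]
        if (any(q < 1) || any(q > dims)) next
        if (occ[q[1], q[2], q[3]] == 0 && !ext[q[1], q[2], q[3]]) {
          ext[q[1], q[2], q[3]] <- TRUE
          nxt <- c(nxt, (q[1] + dims[1] * (q[2] - 1) +
                           dims[1] * dims[2] * (q[3] - 1)))
        }
      }
    }
    queue <- nxt
  }
  extPts <- co[which(ext), , drop = FALSE]
  out <- array(Inf, dims)
  if (nrow(extPts) == 0) return(out)
  for (i in seq_len(nrow(co))) {
    p <- co[i, ]
    out[i] <- sqrt(min((extPts[, 1] - p[1])^2 + (extPts[, 2] - p[2])^2 +
                         (extPts[, 3] - p[3])^2))
  }
  out
}

# A state whose occupancy is set from a coordinate matrix, each voxel given
# a clone label; the registry is fabricated so that every label maps to a
# clone with the founder genotype unless extraEvents supplies event names
# per clone id.
makeLabelledState <- function(L, positions, labels = 1L,
                              extraEvents = list(), seed = 1L) {
  cfg <- simulationConfig(L = as.integer(L),
                          stopSize = min(1e6, as.numeric(L)^3),
                          seed = as.integer(seed))
  st <- newTumourState(cfg)
  labels <- rep_len(as.integer(labels), nrow(positions))
  K <- max(labels)
  panel <- cfg@panel
  fg <- founderGenotype(panel)
  G <- matrix(rep(fg@presence, K), nrow = K, byrow = TRUE)
  newEv <- rep(paste(which(fg@presence), collapse = ";"), K)
  for (id in names(extraEvents)) {
    i <- as.integer(id)
    ids <- match(extraEvents[[id]], panel@events$name)
    G[i, ids] <- TRUE
    newEv[i] <- paste(ids, collapse = ";")
  }
  occ <- array(0L, dim = c(L, L, L))
  birth <- array(0L, dim = c(L, L, L))
  occ[positions] <- labels
  st@occ <- occ
  st@birth <- birth
  st@founder <- array(0L, dim = c(L, L, L))
  st@clones <- data.frame(
    clone_id = seq_len(K),
    parent_id = c(0L, rep(1L, K - 1L)),
    birth_step = c(0L, seq_len(max(0L, K - 1L))),
    origin_x = positions[match(seq_len(K), labels), 1],
    origin_y = positions[match(seq_len(K), labels), 2],
    origin_z = positions[match(seq_len(K), labels), 3],
    founder_alive = FALSE,
    new_events = ifelse(seq_len(K) == 1L,
                        paste(which(fg@presence), collapse = ";"), newEv),
    stringsAsFactors = FALSE)
  st@genotypes <- G
  st@growthProb <- cloneGrowthProbs(G, cfg@advantage, panel)
  st@alleles <- data.frame(allele_id = 1L, event_id = match("VHL", panel@events$name),
                           clone_id = 1L)
  st@nextAllele <- 2L
  st
}

# A crafted 2D slice: disc of the given radius with per-site labels
# assigned by labelFun(x, y, centre) (default: all parental).
makeDiscSlice <- function(R = 20, L = 2 * R + 20, labelFun = NULL,
                          extraEvents = list(), advantage = saturatedModel(s = 1)) {
  c0 <- ceiling(L / 2)
  g <- expand.grid(x = seq_len(L), y = seq_len(L))
  keep <- (g$x - c0)^2 + (g$y - c0)^2 <= R^2
  sites <- data.frame(x = g$x[keep], y = g$y[keep])
  labs <- if (is.null(labelFun)) rep(1L, nrow(sites))
          else labelFun(sites$x, sites$y, c(c0, c0))
  sites$clone_id <- as.integer(labs)
  sites$birth_step <- sites$clone_id
  K <- max(sites$clone_id)
  panel <- defaultPanel()
  fg <- founderGenotype(panel)
  G <- matrix(rep(fg@presence, K), nrow = K, byrow = TRUE)
  for (id in names(extraEvents))
    G[as.integer(id), match(extraEvents[[id]], panel@events$name)] <- TRUE
  clones <- data.frame(clone_id = seq_len(K), parent_id = c(0L, rep(1L, K - 1L)),
                       birth_step = seq_len(K) - 1L,
                       origin_x = c0, origin_y = c0, origin_z = c0,
                       founder_alive = FALSE,
                       new_events = "", stringsAsFactors = FALSE)
  tumourSlice(sites, c(L, L), clones, G, panel, advantage, z0 = c0)
}

# Inverse-CDF sample from the power law P(D <= d) = d^k on (0, 1]
plantedPowerLaw <- function(n, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  runif(n)^(1 / k)
}
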