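test_that("initialisation places one founder voxel at the lattice centre", {
  cfg <- simulationConfig(L = 21L, stopSize = 100, seed = 5L)
  st <- newTumourState(cfg)
  expect_identical(nVoxels(st), 1L)
  c0 <- latticeCentre(21L)
  expect_identical(st@occ[c0, c0, c0], 1L)
  fg <- founderGenotype(cfg@panel)
  expect_identical(st@genotypes[1, ], fg@presence)
  # same seed, same RNG state
  st2 <- newTumourState(cfg)
  expect_identical(st@rngState, st2@rngState)
})

test_that("death phase removes voxels at the configured rate", {
  # cube of 20^3 = 8000 voxels
  g <- as.matrix(expand.grid(x = 3:22, y = 3:22, z = 3:22))
  st <- makeLabelledState(25L, g)

  st@config@pDeath <- 0
  expect_length(deathPhase(st)$removed, 0L)

  st@config@pDeath <- 1
  res <- deathPhase(st)
  expect_identical(length(res$removed), 8000L)
  expect_identical(nVoxels(res$state), 0L)

  st@config@pDeath <- 0.05
  n <- length(deathPhase(st)$removed)
  ci <- qbinom(c(0.005, 0.995), 8000, 0.05) # 99% binomial interval
  expect_gte(n, ci[1])
  expect_lte(n, ci[2])
})

test_that("surface eligibility requires an empty 26-neighbour", {
  st <- fixtureLattice("cube3")
  expect_identical(nrow(eligibleParents(st, "surface")), 26L)
  expect_identical(nrow(eligibleParents(st, "volume")), 27L)
  c0 <- latticeCentre(9L)
  centreIdx <- c0 + 9L * (c0 - 1L) + 81L * (c0 - 1L)
  expect_false(centreIdx %in% eligibleParents(st, "surface")$index)

  single <- newTumourState(simulationConfig(L = 9L, stopSize = 10, seed = 1L))
  expect_identical(nrow(eligibleParents(single, "surface")), 1L)
  expect_identical(nrow(eligibleParents(single, "volume")), 1L)
})

test_that("surface placement picks the unique empty neighbour and is uniform", {
  # cube3 with one corner removed: the centre gains exactly one empty
  # 26-neighbour (that corner)
  st <- fixtureLattice("cube3")
  c0 <- latticeCentre(9L)
  st@occ[c0 + 1L, c0 + 1L, c0 + 1L] <- 0L
  res <- placeChildSurface(st, c(c0, c0, c0))
  co <- arrayInd(res$child, dim(st@occ))
  expect_identical(as.integer(co), c(c0 + 1L, c0 + 1L, c0 + 1L))

  # fully enclosed parent signals an error
  st2 <- fixtureLattice("cube3")
  expect_error(placeChildSurface(st2, c(c0, c0, c0)), "no empty neighbour")

  # an isolated parent has 26 empty neighbours, each chosen ~uniformly
  counts <- integer(26)
  for (i in 1:1300) {
    sti <- newTumourState(simulationConfig(L = 9L, stopSize = 10,
                                           seed = as.integer(i)))
    res <- placeChildSurface(sti, c(c0, c0, c0))
    off <- arrayInd(res$child, dim(sti@occ)) - c0 # components in {-1,0,1}
    slot <- (off[1] + 1) + 3 * (off[2] + 1) + 9 * (off[3] + 1) + 1
    slot <- slot - (slot > 14) # skip the (0,0,0) cell
    counts[slot] <- counts[slot] + 1L
  }
  expect_identical(sum(counts), 1300L)
  expect_gt(chisq.test(counts)$p.value, 0.001)
})

test_that("volume placement pushes the displaced ray outward in order", {
  # 7^3 solid cube with unique labels; parent at the centre is enclosed,
  # so the child insertion must shift a whole ray one step outward
  L <- 15L
  g <- as.matrix(expand.grid(x = 5:11, y = 5:11, z = 5:11))
  st <- makeLabelledState(L, g, labels = seq_len(nrow(g)))
  c0 <- 8L
  before <- st@occ
  res <- placeChildVolume(st, c(c0, c0, c0))
  after <- res$state@occ
  expect_identical(sum(after != 0L), sum(before != 0L) + 1L)
  childCo <- as.integer(arrayInd(res$child, dim(after)))
  dir <- childCo - c0
  expect_true(all(abs(dir) <= 1) && any(dir != 0))
  # walk along the push ray: every pre-push occupant moved one step outward
  k <- 1L
  repeat {
    fromPos <- c0 + k * dir
    toPos <- c0 + (k + 1L) * dir
    fromLab <- before[fromPos[1], fromPos[2], fromPos[3]]
    if (fromLab == 0L) break
    expect_identical(after[toPos[1], toPos[2], toPos[3]], fromLab)
    k <- k + 1L
  }
  # child sits adjacent to the parent, which keeps its label
  expect_identical(after[childCo[1], childCo[2], childCo[3]],
                   before[c0, c0, c0])
  expect_identical(after[c0, c0, c0], before[c0, c0, c0])

  # a parent with empty sampled neighbours places the child with no push
  single <- makeLabelledState(9L, matrix(c(5L, 5L, 5L), 1))
  res2 <- placeChildVolume(single, c(5L, 5L, 5L))
  expect_identical(nVoxels(res2$state), 2L)

  # a push that would exit the lattice aborts with a boundary error
  full <- makeLabelledState(5L, as.matrix(expand.grid(1:5, 1:5, 1:5)))
  expect_error(placeChildVolume(full, c(3L, 3L, 3L)), "boundary|lattice")
})

test_that("depth field equals the brute-force exterior distance", {
  set.seed(7)
  for (rep in 1:3) {
    L <- sample(8:14, 1)
    occ <- array(0L, dim = c(L, L, L))
    # random blob with internal holes
    c0 <- ceiling(L / 2)
    g <- as.matrix(expand.grid(seq_len(L), seq_len(L), seq_len(L)))
    r2 <- rowSums((g - c0)^2)
    keep <- r2 <= (c0 - 2)^2 & runif(nrow(g)) > 0.1
    occ[g[keep, , drop = FALSE]] <- 1L
    st <- makeLabelledState(L, g[keep, , drop = FALSE])
    expect_equal(depthField(st), bruteDepthField(st@occ), tolerance = 1e-12)
  }
  # interior holes are not tumour surface
  L <- 13L
  g <- as.matrix(expand.grid(3:11, 3:11, 3:11))
  st <- makeLabelledState(L, g)
  c0 <- 7L
  st@occ[c0, c0, c0] <- 0L # single hole at the centre of a 9^3 cube
  dep <- depthField(st)
  expect_equal(dep, bruteDepthField(st@occ), tolerance = 1e-12)
  expect_gt(dep[c0, c0, c0], 3) # the hole is deep, not surface
  # a voxel adjacent to the hole is still measured to the exterior
  expect_gt(dep[c0 + 1L, c0, c0], 2)
})

test_that("driver phase respects harboured events and founds new clones", {
  st <- newTumourState(simulationConfig(L = 9L, stopSize = 10, seed = 2L,
                                        pDriver = 1))
  c0 <- latticeCentre(9L)
  res <- placeChildSurface(st, c(c0, c0, c0))
  st2 <- res$state
  daughters <- data.frame(site = res$child, parent_clone = 1L)
  drv <- driverPhase(st2, daughters)
  expect_length(drv$newClones, 1L)
  newId <- drv$newClones
  gained <- setdiff(which(drv$state@genotypes[newId, ]),
                    which(drv$state@genotypes[1L, ]))
  panel <- st@config@panel
  vhlId <- match("VHL", panel@events$name)
  p3Id <- match("3p loss", panel@events$name)
  # VHL and 3p loss are inherited, never re-acquired
  expect_false(vhlId %in% gained)
  expect_false(p3Id %in% gained)
  # with pDriver = 1 every other gene mutation is acquired
  geneIds <- which(panel@events$event_class == "gene_mutation")
  expect_true(all(setdiff(geneIds, vhlId) %in% gained))

  # pDriver = 0: no acquisitions, no clones
  st0 <- st2
  st0@config@pDriver <- 0
  expect_length(driverPhase(st0, daughters)$newClones, 0L)

  # two daughters acquiring the same gene found distinct clones with
  # distinct allele ids (parallel events)
  res2 <- placeChildSurface(st2, c(c0, c0, c0))
  st3 <- res2$state
  dd <- data.frame(site = c(res$child, res2$child), parent_clone = c(1L, 1L))
  drv2 <- driverPhase(st3, dd)
  expect_length(drv2$newClones, 2L)
  al <- drv2$state@alleles
  pbrm1 <- match("PBRM1", panel@events$name)
  hits <- al[al$event_id == pbrm1 & al$clone_id %in% drv2$newClones, ]
  expect_identical(nrow(hits), 2L)
  expect_identical(length(unique(hits$allele_id)), 2L)
})

test_that("necrosis only removes voxels deeper than the threshold", {
  st <- fixtureLattice("sphere20") # ball radius 20, max depth ~20
  st@config@necrosisEnabled <- TRUE
  st@config@pNecrosis <- 1
  dep <- depthField(st)
  res <- necrosisPhase(st)
  expect_gt(length(res$removed), 0L)
  expect_true(all(dep[res$removed] > 15))
  # everything deeper than 15 mm is removed at pNecrosis = 1
  deep <- which(st@occ != 0L & dep > 15)
  expect_setequal(res$removed, deep)
  # voxels at most 15 mm deep are never touched
  left <- which(res$state@occ != 0L)
  expect_true(all(dep[left] <= 15))

  # expected necrotic fraction at pNecrosis = 0.5 matches the geometric
  # volume fraction deeper than 15 mm times 0.5 (binomial 99% interval)
  st@config@pNecrosis <- 0.5
  n <- length(necrosisPhase(st)$removed)
  ci <- qbinom(c(0.005, 0.995), length(deep), 0.5)
  expect_gte(n, ci[1])
  expect_lte(n, ci[2])

  st@config@necrosisEnabled <- FALSE
  expect_length(necrosisPhase(st)$removed, 0L)
})

test_that("a step with all rates zero only advances the counter", {
  cfg <- simulationConfig(L = 11L, stopSize = 100, seed = 3L, pDeath = 0,
                          pDriver = 0,
                          advantage = saturatedModel(s = 0, pInit = 0))
  st <- newTumourState(cfg)
  st2 <- simStep(st)
  expect_identical(st2@occ, st@occ)
  expect_identical(st2@clones, st@clones)
  expect_identical(st2@step, st@step + 1L)
})

test_that("simulation runs are deterministic and honour the stop size", {
  cfg <- simulationConfig(L = 30L, stopSize = 500, seed = 11L,
                          pDriver = 6e-4, snapshotEvery = 5L)
  r1 <- runUntilEstablished(cfg)
  r2 <- runUntilEstablished(cfg)
  expect_identical(length(r1$snapshots), length(r2$snapshots))
  for (i in seq_along(r1$snapshots)) {
    expect_identical(r1$snapshots[[i]]@voxels, r2$snapshots[[i]]@voxels)
    expect_identical(r1$snapshots[[i]]@clones, r2$snapshots[[i]]@clones)
    expect_identical(r1$snapshots[[i]]@rngState, r2$snapshots[[i]]@rngState)
  }
  expect_gte(nVoxels(r1$state), 500)
  # occupancy count and log agree (conservation)
  expect_identical(nVoxels(r1$state), tail(r1$state@log$n_voxels, 1))

  # stopSize = 1 terminates immediately after initialisation
  r0 <- runSimulation(simulationConfig(L = 9L, stopSize = 1, seed = 1L))
  expect_identical(r0$state@step, 0L)
  expect_identical(nVoxels(r0$state), 1L)
})

test_that("replay resumes bit-identically and rejects duplicate seeds", {
  cfg <- simulationConfig(L = 30L, stopSize = 400, seed = 21L,
                          pDriver = 6e-4, snapshotEvery = 10L)
  base <- runUntilEstablished(cfg)
  mid <- base$snapshots[[2]] # an intermediate state
  expect_lt(mid@step, base$state@step)

  # continuing the stored RNG stream reproduces the uninterrupted run
  cont <- replaySimulation(mid, seeds = NULL,
                           stopSize = base$state@config@stopSize)[[1]]
  expect_identical(takeSnapshot(cont$state)@voxels,
                   takeSnapshot(base$state)@voxels)
  expect_identical(takeSnapshot(cont$state)@clones,
                   takeSnapshot(base$state)@clones)

  # distinct new seeds give (generally) diverging outcomes
  reps <- replaySimulation(mid, seeds = c(101L, 202L, 303L),
                           stopSize = base$state@config@stopSize)
  v1 <- takeSnapshot(reps[[1]]$state)@voxels
  v2 <- takeSnapshot(reps[[2]]$state)@voxels
  expect_false(identical(v1, v2))

  # a snapshot already at the stopping size is returned unchanged
  fin <- takeSnapshot(base$state)
  same <- replaySimulation(fin, seeds = c(9L))[[1]]
  expect_identical(takeSnapshot(same$state)@voxels, fin@voxels)

  expect_error(replaySimulation(mid, seeds = c(1L, 1L)), "distinct")
})

test_that("volume growth is exponential while surface growth is radial", {
  # reduced single-seed check; the full 10-seed version runs in the
  # acceptance suite
  cfg <- simulationConfig(L = 40L, stopSize = 4000, seed = 8L, pDriver = 0,
                          growthMode = "volume")
  lg <- runUntilEstablished(cfg)$state@log
  lg <- lg[lg$n_voxels >= 100, ]
  fit <- lm(log(n_voxels) ~ step, data = lg)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_equal(exp(unname(coef(fit)[2])), (1 - 0.05) * (1 + 0.25),
               tolerance = 0.02)

  cfgS <- simulationConfig(L = 40L, stopSize = 4000, seed = 8L, pDriver = 0,
                           growthMode = "surface")
  lgS <- runUntilEstablished(cfgS)$state@log
  lgS <- lgS[lgS$n_voxels >= 100, ]
  fitS <- lm(I(n_voxels^(1 / 3)) ~ step, data = lgS)
  expect_gt(summary(fitS)$r.squared, 0.98)
})
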