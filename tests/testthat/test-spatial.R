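test_that("slice extraction recovers disc geometry", {
  sl <- extractSlice(fixtureLattice("disc20"))
  expect_equal(sliceArea(sl), sum(outer((-40:40)^2, (-40:40)^2, "+") <= 400))
  # contour points all lie ~20 mm from the centroid
  dd <- sqrt((sl@contour[, 1] - sl@centre[1])^2 +
             (sl@contour[, 2] - sl@centre[2])^2)
  expect_true(all(abs(dd - 20) <= 1.5))
  # smoothed perimeter within 5% of the true circumference
  expect_equal(slicePerimeter(sl), 2 * pi * 20, tolerance = 0.05)
  expect_identical(nrow(sl@contour), nrow(sl@contourSmooth))
  # every raw contour point is occupied and has an empty 8-neighbour
  M <- matrix(FALSE, sl@dims[1], sl@dims[2])
  M[cbind(sl@sites$x, sl@sites$y)] <- TRUE
  for (i in seq_len(nrow(sl@contour))) {
    p <- sl@contour[i, ]
    expect_true(M[p[1], p[2]])
    nb <- expand.grid(x = p[1] + (-1:1), y = p[2] + (-1:1))
    expect_true(any(!M[cbind(nb$x, nb$y)]))
  }
  # ... and the traced set is sandwiched by the exposure oracles: it
  # covers every pixel with an empty 4-neighbour (the walk cannot skip
  # them) and never strays beyond pixels with an empty 8-neighbour
  exposed4 <- which(vapply(seq_len(nrow(sl@sites)), function(i) {
    x <- sl@sites$x[i]; y <- sl@sites$y[i]
    !all(M[cbind(x + c(-1, 1, 0, 0), y + c(0, 0, -1, 1))])
  }, logical(1)))
  b4 <- paste(sl@sites$x[exposed4], sl@sites$y[exposed4])
  cset <- unique(paste(sl@contour[, 1], sl@contour[, 2]))
  expect_true(all(b4 %in% cset))
})

test_that("contour tracing agrees with an independent image-analysis tracer", {
  sl <- extractSlice(fixtureLattice("disc20"))
  M <- matrix(0, sl@dims[1], sl@dims[2])
  M[cbind(sl@sites$x, sl@sites$y)] <- 1
  oc <- EBImage::ocontour(M)[[1]] + 1L # 0-based to 1-based
  expect_setequal(paste(oc[, 1], oc[, 2]),
                  unique(paste(sl@contour[, 1], sl@contour[, 2])))
})

test_that("degenerate slices are handled", {
  st <- newTumourState(simulationConfig(L = 9L, stopSize = 5, seed = 1L))
  sl <- extractSlice(st)
  expect_identical(sliceArea(sl), 1L)
  expect_identical(nrow(sl@contour), 1L)
  expect_error(circularity(sl), "degenerate")
  expect_error(extractSlice(st, z = 1L), "does not intersect")
})

test_that("circularity separates discs, bars and lobed shapes", {
  disc <- extractSlice(fixtureLattice("disc20"))
  expect_equal(circularity(disc), 1, tolerance = 0.05)
  # 1xN bars tend to zero circularity as N grows
  bar <- function(n) {
    sites <- data.frame(x = seq_len(n) + 2L, y = 10L, clone_id = 1L,
                        birth_step = 0L)
    tumourSlice(sites, c(n + 4L, 20L), disc@clones, disc@genotypes,
                disc@panel, disc@advantage)
  }
  c20 <- circularity(bar(20))
  c60 <- circularity(bar(60))
  expect_lt(c60, c20)
  expect_lt(c60, 0.25)
  # a budding lobe lowers circularity below the disc's
  lobed <- extractSlice(fixtureLattice("twolobe"))
  expect_lt(circularity(lobed), circularity(disc))
})

test_that("biopsy sampling uses the stated grid and radius", {
  # a slice covering the full 200 mm plane yields all 100 candidates
  g <- expand.grid(x = 1:200, y = 1:200)
  full <- data.frame(x = g$x, y = g$y, clone_id = 1L, birth_step = 0L)
  disc <- makeDiscSlice(R = 5, L = 24) # donor for registry slots
  slFull <- tumourSlice(full, c(200L, 200L), disc@clones, disc@genotypes,
                        disc@panel, disc@advantage)
  bx <- sampleBiopsies(slFull)
  expect_identical(length(bx), 100L)
  # members lie within 5 mm of their centre
  for (b in bx[c(1, 50, 100)])
    expect_true(all((b$sites$x - b$centre[1])^2 +
                    (b$sites$y - b$centre[2])^2 <= 25))

  # disc of radius 30: only centres within 35 mm of the disc centre can
  # collect voxels, and all centres within 25 mm must
  sl30 <- makeDiscSlice(R = 30, L = 200)
  bx30 <- sampleBiopsies(sl30)
  ctr <- sl30@centre
  dc <- vapply(bx30, function(b) sqrt(sum((b$centre - ctr)^2)), numeric(1))
  expect_true(all(dc <= 35 + 1e-9))
  grid <- expand.grid(x = seq(10, 200, 20), y = seq(10, 200, 20))
  inner <- sqrt((grid$x - ctr[1])^2 + (grid$y - ctr[2])^2) <= 25
  expect_gte(length(bx30), sum(inner))
})

test_that("microdiversity windows count distinct clones", {
  mono <- makeDiscSlice(R = 10)
  mp <- microdiversityMap(mono)
  expect_true(all(mp$n_clones == 1L))
  # all windows contain at least one occupied site
  expect_true(all(mp$n_sites >= 1L))

  # crafted 3x3 patch with 5 distinct labels qualifies as a hotspot
  sites <- expand.grid(x = 10:12, y = 10:12)
  sites$clone_id <- c(1L, 2L, 3L, 4L, 5L, 1L, 2L, 3L, 4L)
  sites$birth_step <- 0L
  donor <- makeDiscSlice(R = 6, labelFun = function(x, y, c0) 1L)
  K <- 5L
  G <- donor@genotypes[rep(1L, K), , drop = FALSE]
  clones <- data.frame(clone_id = 1:K, parent_id = c(0L, rep(1L, K - 1L)),
                       birth_step = 0:(K - 1L), origin_x = 11L,
                       origin_y = 11L, origin_z = 1L, founder_alive = FALSE,
                       new_events = "", stringsAsFactors = FALSE)
  sl <- tumourSlice(sites, c(21L, 21L), clones, G, donor@panel,
                    donor@advantage)
  mp2 <- microdiversityMap(sl)
  centreWin <- mp2[mp2$cx == 11 & mp2$cy == 11, ]
  expect_identical(centreWin$n_clones, 5)
  hs <- hotspotsAndDistances(mp2, sl, minClones = 5)
  expect_gte(nrow(hs), 1L)
  expect_true(all(hs$d >= 0 & hs$d <= 1))
})

test_that("hotspot distances interpolate centre to margin", {
  sl <- makeDiscSlice(R = 20)
  ctr <- sl@centre
  fakeMap <- data.frame(cx = c(ctr[1], ctr[1] + 10, ctr[1] + 20),
                        cy = rep(ctr[2], 3), n_clones = 5L, n_sites = 9L)
  hs <- hotspotsAndDistances(fakeMap, sl, minClones = 5)
  expect_equal(hs$d[1], 0)
  expect_equal(hs$d[2], 0.5, tolerance = 0.05)
  expect_equal(hs$d[3], 1, tolerance = 0.05)
  expect_true(all(hs$d1 + hs$d2 > 0))
})

test_that("power-law fitting recovers planted exponents", {
  for (k in c(1, 2, 3)) {
    d <- plantedPowerLaw(400, k, seed = 100 + k)
    fit <- fitPowerLaw(d)
    expect_equal(median(fit@kBoot), k, tolerance = 0.1)
    expect_length(fit@kBoot, 100L)
    expect_false(fit@degenerate)
    # log-log cross-check agrees loosely
    expect_equal(fitPowerLawLogLog(d), k, tolerance = 0.35)
  }
  expect_error(fitPowerLaw(c(0.5, 0.6)), "at least 10")
  expect_warning(fit <- fitPowerLaw(rep(1 - 1e-9, 50)), "degenerate")
  expect_true(fit@degenerate)
})

test_that("Q-Q pairs lie on the identity for matched exponents", {
  d <- plantedPowerLaw(1000, 2, seed = 9)
  qq <- qqAgainstPowerLaw(d, 2)
  expect_lt(max(abs(qq$theoretical - qq$empirical)), 0.05)
  # a mismatched exponent bends the curve monotonically to one side
  qqBad <- qqAgainstPowerLaw(d, 4)
  dev <- qqBad$empirical - qqBad$theoretical
  expect_gt(mean(dev < 0), 0.95)
  expect_identical(nrow(qqAgainstPowerLaw(0.4, 2)), 1L)
})

test_that("homogenisation preserves composition and flattens structure", {
  # edge-enriched label pattern: a fine mosaic of subclones in an outer
  # annulus, parental core
  lab <- function(x, y, c0) {
    r <- sqrt((x - c0[1])^2 + (y - c0[2])^2)
    ifelse(r > 14, 2L + ((x + 2L * y) %% 40L), 1L)
  }
  sl <- makeDiscSlice(R = 20, L = 60, labelFun = lab)
  before <- composition(sl)
  hom <- homogenise(sl, seed = 5)
  after <- composition(hom)
  expect_identical(before, after)
  expect_identical(sl@contour, hom@contour)

  # monoclonal slices are unchanged
  mono <- makeDiscSlice(R = 8)
  expect_identical(composition(homogenise(mono, seed = 1)),
                   composition(mono))

  # the edge enrichment of hotspot distances disappears after shuffling
  hsB <- hotspotsAndDistances(microdiversityMap(sl), sl)
  hsA <- hotspotsAndDistances(microdiversityMap(hom), hom)
  expect_gt(nrow(hsB), 10L)
  expect_gt(nrow(hsA), 10L)
  kB <- median(fitPowerLaw(hsB$d)@kBoot)
  kA <- median(fitPowerLaw(hsA$d)@kBoot)
  expect_gt(kB, 2.5)          # planted edge enrichment
  expect_lt(abs(kA - 2), 0.5) # null-like after homogenisation
})

test_that("youngest subclones report margin distances from birth positions", {
  lab <- function(x, y, c0) ifelse(x == c0[1] & y == c0[2], 2L, 1L)
  sl <- makeDiscSlice(R = 15, L = 50, labelFun = lab)
  # subclone 2 originated at the centroid of the disc
  ys <- youngestSubclones(sl, n = 100)
  expect_true(ys$flagged) # fewer than 100 subclones
  expect_identical(ys$subclones$clone_id, 2L)
  expect_equal(ys$subclones$dist_to_margin, 15, tolerance = 0.1)
  expect_equal(ys$meanDistance, 15, tolerance = 0.1)

  # a clone born on the contour has distance ~0
  sl2 <- makeDiscSlice(R = 15, L = 50, labelFun = function(x, y, c0)
    ifelse(x == c0[1] + 15 & y == c0[2], 2L, 1L))
  sl2@clones$origin_x[2] <- sl2@z0 + 15L # centroid x + 15 = contour
  sl2@clones$origin_y[2] <- sl2@z0
  ys2 <- youngestSubclones(sl2)
  expect_lt(ys2$meanDistance, 0.8)

  # ordering: the n youngest by birth step
  lab3 <- function(x, y, c0) 1L + (x %% 5L)
  sl3 <- makeDiscSlice(R = 15, L = 50, labelFun = lab3)
  ys3 <- youngestSubclones(sl3, n = 2)
  expect_false(ys3$flagged)
  expect_identical(ys3$subclones$clone_id, c(5L, 4L))
})

test_that("fitness gradients detect fitter cores and margins", {
  uni <- makeDiscSlice(R = 15)
  fg <- fitnessGradient(uni)
  expect_identical(fg$ratioC2M, 1)
  expect_equal(fg$central, 0.25)

  # fitter ring at the margin
  ring <- makeDiscSlice(R = 15, labelFun = function(x, y, c0)
    ifelse((x - c0[1])^2 + (y - c0[2])^2 > 11^2, 2L, 1L),
    extraEvents = list("2" = "7q gain"))
  fgR <- fitnessGradient(ring)
  expect_lt(fgR$ratioC2M, 1)

  # fitter core
  core <- makeDiscSlice(R = 15, labelFun = function(x, y, c0)
    ifelse((x - c0[1])^2 + (y - c0[2])^2 < 6^2, 2L, 1L),
    extraEvents = list("2" = "7q gain"))
  fgC <- fitnessGradient(core)
  expect_gt(fgC$ratioC2M, 1)

  expect_error(fitnessGradient(makeDiscSlice(R = 1)), "too small")
})
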