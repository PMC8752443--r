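# circle-margin region table crafted around planted normalised distances
craftTable <- function(d, R = 30, group = "g", events = NULL,
                       tumour = "T001") {
  ang <- seq(0, 2 * pi, length.out = length(d) + 1L)[-1]
  rg <- data.frame(tumour_id = tumour,
                   region_id = sprintf("%s_R%03d", tumour, seq_along(d)),
                   x_mm = R + d * R * cos(ang), y_mm = R + d * R * sin(ang),
                   n_clones = 2L, n_subclones = 1L,
                   events = if (is.null(events)) "" else events,
                   group = group, stringsAsFactors = FALSE)
  theta <- seq(0, 2 * pi, length.out = 181)[-181]
  structure(list(regions = rg,
                 margins = setNames(list(cbind(R + R * cos(theta),
                                               R + R * sin(theta))),
                                    tumour)),
            class = "RegionTable")
}

test_that("region tables load, validate and round-trip", {
  rt <- generateSyntheticRegionTable(list(n_tumours = 3,
                                          regions_per_tumour = 20,
                                          pattern = "uniform"), seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  fm <- withr::local_tempfile(fileext = ".csv")
  writeRegionTable(rt, f, fm)
  rt2 <- loadRegionTable(f, fm)
  expect_equal(rt2$regions$x_mm, rt$regions$x_mm)
  expect_identical(rt2$regions$n_clones, as.integer(rt$regions$n_clones))
  expect_identical(names(rt2$margins), names(rt$margins))

  bad <- rt$regions
  bad$n_clones[3] <- 0L
  fb <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, fb, row.names = FALSE)
  expect_error(loadRegionTable(fb), "clone count")

  # no margins supplied: convex hull computed per tumour on demand
  rt3 <- loadRegionTable(f)
  expect_length(rt3$margins, 0L)
  dd <- regionDistances(rt3)
  expect_true(all(dd$d >= 0 & dd$d <= 1))
})

test_that("hotspot proxy thresholds regions by subclone count", {
  rt <- craftTable(runif(30))
  rt$regions$n_subclones <- rep(c(0L, 1L, 3L), each = 10)
  rt$regions$n_clones <- rt$regions$n_subclones + 1L
  expect_identical(nrow(hotspotProxy(rt, 1)), 20L)
  expect_identical(nrow(hotspotProxy(rt, 2)), 10L)
  expect_identical(nrow(hotspotProxy(rt, 3)), 10L)
  mono <- craftTable(runif(10))
  mono$regions$n_subclones <- 0L
  expect_identical(nrow(hotspotProxy(mono)), 0L)
})

test_that("region distances interpolate centre to margin", {
  rt <- craftTable(c(0, 0.5, 1))
  dd <- regionDistances(rt)
  expect_equal(dd$d[1], 0, tolerance = 1e-6)
  expect_equal(dd$d[2], 0.5, tolerance = 0.01)
  expect_equal(dd$d[3], 1, tolerance = 0.01)

  degen <- craftTable(c(0.2, 0.4))
  degen$margins <- list()
  expect_error(regionDistances(degen), "degenerate margin")
})

test_that("group exponent comparison separates planted laws", {
  dA <- plantedPowerLaw(400, 2, seed = 11)
  dB <- plantedPowerLaw(400, 3, seed = 12)
  rtA <- craftTable(dA, group = "A", tumour = "T001")
  rtB <- craftTable(dB, group = "B", tumour = "T002")
  rt <- structure(list(regions = rbind(rtA$regions, rtB$regions),
                       margins = c(rtA$margins, rtB$margins)),
                  class = "RegionTable")
  set.seed(1)
  res <- compareGroupExponents(rt)
  expect_equal(median(res$fits$A@kBoot), 2, tolerance = 0.15)
  expect_equal(median(res$fits$B@kBoot), 3, tolerance = 0.2)
  expect_lt(res$tests$p_value, 0.001)

  # identical groups: no significant difference
  rtsame <- structure(list(regions = rbind(rtA$regions,
                                           within(rtA$regions, {
                                             group <- "B"
                                             tumour_id <- "T002"
                                           })),
                           margins = c(rtA$margins,
                                       setNames(rtA$margins, "T002"))),
                      class = "RegionTable")
  set.seed(7)
  resSame <- compareGroupExponents(rtsame)
  expect_gt(resSame$tests$p_value, 0.05)

  # too-small groups are rejected
  small <- craftTable(runif(5), group = "A")
  small2 <- craftTable(runif(40), group = "B", tumour = "T002")
  rtSmall <- structure(list(regions = rbind(small$regions, small2$regions),
                            margins = c(small$margins, small2$margins)),
                       class = "RegionTable")
  expect_error(compareGroupExponents(rtSmall), "insufficient")
})

test_that("single-region event distances flag deep events", {
  # three regions: event E1 on the margin, E2 at 12 mm depth, E3 spanning
  # all three regions
  rt <- craftTable(c(1, (30 - 12) / (30 - 12 + 12), 0.5),
                   events = c("E1;E3", "E2;E3", "E3"))
  out <- singleRegionEventDistances(rt)
  e1 <- out[out$event == "E1", ]
  expect_identical(e1$n_regions, 1L)
  expect_lt(e1$dist_to_margin, 0.5)
  expect_false(e1$beyond_reference)
  e2 <- out[out$event == "E2", ]
  expect_equal(e2$dist_to_margin, 12, tolerance = 0.1)
  expect_true(e2$beyond_reference)
  e3 <- out[out$event == "E3", ]
  expect_identical(e3$n_regions, 3L)
  expect_true(is.na(e3$dist_to_margin))
  expect_identical(attr(out, "reference_mm"), 10)
})

test_that("synthetic tables recover planted spatial patterns", {
  rtU <- generateSyntheticRegionTable(list(n_tumours = 1,
                                           regions_per_tumour = 400,
                                           pattern = "uniform",
                                           hotspot_fraction = 1), seed = 5)
  dU <- regionDistances(rtU, hotspotProxy(rtU))$d
  expect_equal(median(fitPowerLaw(dU)@kBoot), 2, tolerance = 0.2)

  rtE <- generateSyntheticRegionTable(list(n_tumours = 1,
                                           regions_per_tumour = 400,
                                           pattern = "edge_enriched", k = 4,
                                           hotspot_fraction = 1), seed = 6)
  dE <- regionDistances(rtE, hotspotProxy(rtE))$d
  expect_equal(median(fitPowerLaw(dE)@kBoot), 4, tolerance = 0.3)

  # planted single-region event at 12 mm depth round-trips
  rtP <- generateSyntheticRegionTable(list(
    n_tumours = 1, regions_per_tumour = 30, pattern = "uniform",
    planted_events = data.frame(tumour_id = "T001", event = "PBRM1_a",
                                span = 1L, depth_mm = 12)), seed = 7)
  out <- singleRegionEventDistances(rtP)
  hit <- out[out$event == "PBRM1_a", ]
  expect_identical(hit$n_regions, 1L)
  expect_equal(hit$dist_to_margin, 12, tolerance = 0.2)

  # edge-enriched exponent exceeds the uniform one in >= 18/20 replicates
  wins <- 0L
  for (i in 1:20) {
    ru <- generateSyntheticRegionTable(list(n_tumours = 1,
                                            regions_per_tumour = 400,
                                            pattern = "uniform",
                                            hotspot_fraction = 1),
                                       seed = 1000 + i)
    re <- generateSyntheticRegionTable(list(n_tumours = 1,
                                            regions_per_tumour = 400,
                                            pattern = "edge_enriched",
                                            k = 4, hotspot_fraction = 1),
                                       seed = 2000 + i)
    ku <- fitPowerLaw(regionDistances(ru, hotspotProxy(ru))$d,
                      nBoot = 20)@k
    ke <- fitPowerLaw(regionDistances(re, hotspotProxy(re))$d,
                      nBoot = 20)@k
    wins <- wins + (ke > ku)
  }
  expect_gte(wins, 18L)
})
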