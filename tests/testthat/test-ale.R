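test_that("selectNearestExperiments ranks by nearest-focus distance", {
  geom <- makeGeometry(c(16L, 16L, 16L), 4)
  ex <- data.frame(experiment_id = c("e1", "e2", "e3"),
                   n_subjects = 20L, fwhm_mm = 10)
  fo <- data.frame(experiment_id = c("e1", "e2", "e2", "e3"),
                   x_mm = c(0, 5, 30, 10), y_mm = 0, z_mm = 0)
  db <- new("FociDatabase", experiments = ex, foci = fo)

  sel <- selectNearestExperiments(db, c(0, 0, 0), k = 2)
  expect_equal(sel$experimentIds, c("e1", "e2"))
  expect_equal(sel$maxDistance, 5)

  selAll <- selectNearestExperiments(db, c(0, 0, 0), k = 3)
  expect_equal(selAll$maxDistance, 10)

  ## a focus exactly at the seed is always selected, at distance zero
  expect_true("e1" %in% selectNearestExperiments(db, c(0, 0, 0),
                                                 k = 1)$experimentIds)
  expect_equal(selectNearestExperiments(db, c(0, 0, 0), k = 1)$maxDistance,
               0)

  expect_error(selectNearestExperiments(db, c(0, 0, 0), k = 4), "exceeds")
})

test_that("modeledActivation is a truncated max-of-Gaussians kernel map", {
  geom <- makeGeometry(c(16L, 16L, 16L), 4)
  fwhm <- 12
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  pMax <- min(1, 64 * (2 * pi * sigma^2)^(-1.5))
  focus <- c(2, 2, -2)   # a voxel centre on this grid (centres at +-2, +-6, ...)

  ma <- modeledActivation(rbind(focus), geom, fwhm)
  mm <- voxelCenters(geom)
  atFocus <- which(colSums((t(mm) - focus)^2) == 0)
  expect_equal(ma[atFocus], pMax)
  ## closed-form value at a neighbour 4 mm away
  nb <- which(colSums((t(mm) - c(6, 2, -2))^2) == 0)
  expect_equal(ma[nb], pMax * exp(-16 / (2 * sigma^2)), tolerance = 1e-12)

  ## coincident foci are no more evidence than one (max rule)
  ma2 <- modeledActivation(rbind(focus, focus), geom, fwhm)
  expect_identical(ma, ma2)

  ## far-away voxels carry (truncated) zero
  far <- which.max(colSums((t(mm) - focus)^2))
  expect_lt(ma[far], 1e-12)

  ## out-of-mask focus is clamped with a warning
  expect_warning(mac <- modeledActivation(rbind(c(90, 0, 0)), geom, fwhm),
                 "clamped")
  expect_equal(max(mac), pMax)
})

test_that("aleUnion composes modeled activation probabilistically", {
  d <- c(4L, 4L, 4L)
  m1 <- array(0.5, d); m2 <- array(0.5, d)
  expect_equal(aleUnion(list(m1, m2)), array(0.75, d))
  expect_equal(aleUnion(list(array(0, d), array(0, d))), array(0, d))
  expect_equal(aleUnion(list(m1)), m1)
  expect_error(aleUnion(list(m1, array(0.1, c(3L, 3L, 3L)))), "differ")

  ## bounds, monotonicity and experiment-order invariance
  set.seed(41)
  ms <- lapply(1:5, function(i) array(runif(64, 0, 0.3), d))
  ale <- aleUnion(ms)
  expect_true(all(ale >= Reduce(pmax, ms) - 1e-12))
  expect_true(all(ale <= Reduce(`+`, ms) + 1e-12))
  expect_true(all(aleUnion(ms[c(3, 1, 5, 2, 4)]) - ale < 1e-12))
  expect_true(all(aleUnion(ms[1:4]) <= ale + 1e-12))
})

test_that("the two-point null is recovered exactly", {
  ## single experiment whose MA is pMax on a fraction f of the mask
  d <- c(8L, 8L, 8L)
  geom <- makeGeometry(d, 4)
  f <- 16 / 512
  ma <- array(0, d); ma[seq_len(512 * f)] <- 0.2
  sig <- aleVoxelSignificance(list(ma), geom, "analytic_histogram")
  expect_equal(aleP(sig$result)[1], f)          # observed pMax
  expect_equal(aleP(sig$result)[512], 1)        # observed zero
  expect_lte(aleZ(sig$result)[512], 0)
})

test_that("analytic and Monte-Carlo nulls agree", {
  geom <- makeGeometry(c(16L, 16L, 16L), 4)
  db <- nullFociDatabase(10, geom, fwhm = 12, seed = 3)
  ma <- agefc:::.maVolumes(db, geom)
  an <- aleVoxelSignificance(ma, geom, "analytic_histogram")
  mc <- aleVoxelSignificance(ma, geom, "monte_carlo", nNull = 1e5,
                             seed = 4)
  expect_lt(max(abs(aleP(an$result) - aleP(mc$result))), 0.005)
  expect_error(aleVoxelSignificance(ma, geom, "monte_carlo", nNull = 50),
               "nNull")
})

test_that("26-connectivity components are labelled correctly", {
  d <- c(5L, 5L, 5L)
  mask <- array(FALSE, d)
  mask[1, 1, 1] <- TRUE
  mask[2, 2, 2] <- TRUE    # corner-adjacent: same component under 26-conn
  mask[5, 5, 5] <- TRUE    # isolated
  lab <- array(agefc:::cpp_label_components(as.vector(mask), d), d)
  expect_equal(lab[1, 1, 1], lab[2, 2, 2])
  expect_true(lab[5, 5, 5] != lab[1, 1, 1])
  expect_equal(sort(unique(as.vector(lab))), c(0L, 1L, 2L))
})

test_that("clusterFwe recovers planted convergence zones", {
  setup <- plantedZoneSetup(100, seed = 51, backgroundRate = 0)
  res <- clusterFwe(setup$db, setup$geometry, nPerm = 500, seed = 52)
  tab <- clusterTable(res$clusterSet)
  sig <- tab[tab$significant, , drop = FALSE]
  expect_gte(nrow(sig), 1L)
  for (z in 1:2) {
    dists <- sqrt((sig$peak_x - setup$zones[z, 1])^2 +
                    (sig$peak_y - setup$zones[z, 2])^2 +
                    (sig$peak_z - setup$zones[z, 3])^2)
    expect_lte(min(dists), 2 * 4)   # within 2 voxels of the planted zone
  }
})

test_that("an empty supra-threshold map yields an empty ClusterSet", {
  geom <- makeGeometry(c(16L, 16L, 16L), 4)
  ## two diffuse experiments cannot clear a stringent forming threshold
  db <- nullFociDatabase(2, geom, fociPerExperiment = 1, fwhm = 12,
                         seed = 61)
  res <- clusterFwe(db, geom, formingP = 1e-9, nPerm = 100,
                    nullMethod = "analytic_histogram", seed = 62)
  expect_equal(nrow(clusterTable(res$clusterSet)), 0L)
  expect_true(all(clusterLabels(res$clusterSet) == 0L))
})

test_that("minimumStatisticConjunction intersects thresholded maps", {
  d <- c(6L, 6L, 6L)
  geom <- makeGeometry(d, 4)
  m1 <- array(FALSE, d); m1[2:3, 2:3, 2:3] <- TRUE
  m2 <- array(FALSE, d); m2[5:6, 5:6, 5:6] <- TRUE

  same <- minimumStatisticConjunction(list(m1, m1), geom)
  expect_identical(same$mask, m1)
  expect_equal(nrow(same$components), 1L)

  disj <- minimumStatisticConjunction(list(m1, m2), geom)
  expect_false(any(disj$mask))
  expect_equal(nrow(disj$components), 0L)

  expect_error(minimumStatisticConjunction(list(m1), geom), "two maps")
})

test_that("seed MACMs plus conjunction isolate the planted task-general zones", {
  setup <- plantedZoneSetup(300, seed = 71, backgroundRate = 1)
  ms <- lapply(1:6, function(s)
    macmAnalysis(setup$db, setup$homes[s, ], k = 100,
                 geometry = setup$geometry, nPerm = 300, seed = 80 + s))
  conj <- minimumStatisticConjunction(
    lapply(ms, `[[`, "clusterSet"), setup$geometry,
    statMaps = lapply(ms, function(r) aleValues(r$ale)))
  expect_equal(nrow(conj$components), 2L)
  peaks <- as.matrix(conj$components[, c("peak_x", "peak_y", "peak_z")])
  dists <- sapply(1:2, function(z)
    min(sqrt(colSums((t(peaks) - setup$zones[z, ])^2))))
  expect_true(all(dists <= 2 * 4))
})
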