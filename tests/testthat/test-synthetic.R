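test_that("generateCohort draws reproducible multi-site cohorts", {
  profiles <- data.frame(
    site = c("A", "B", "C", "D"),
    n = c(75, 151, 41, 132),
    tr_s = c(2.2, 2.2, 2.0, 2.5),
    n_volumes = c(250, 300, 256, 260)
  )
  ch <- generateCohort(399, c(18, 85), profiles, seed = 7)
  expect_equal(nrow(ch), 399)
  expect_false(anyDuplicated(ch$subject_id) > 0)
  expect_true(all(ch$age >= 18 & ch$age <= 85))
  expect_equal(length(unique(paste(ch$tr_s, ch$n_volumes))), 4L)
  expect_true(all(ch$n_volumes >= 64L))
  ## TR/volumes copied from the assigned profile
  m <- match(ch$site, profiles$site)
  expect_equal(ch$tr_s, profiles$tr_s[m])
  expect_equal(ch$n_volumes, as.integer(profiles$n_volumes[m]))
  ## determinism
  expect_identical(ch, generateCohort(399, c(18, 85), profiles, seed = 7))

  ## degenerate range
  one <- profiles[1, ]
  ch2 <- generateCohort(2, c(40, 40), one, seed = 3)
  expect_equal(ch2$age, c(40, 40))

  ## uniform-mean oracle: E[age] = (18 + 85) / 2 = 51.5
  ch3 <- generateCohort(1000, c(18, 85), profiles, seed = 1)
  expect_lt(abs(mean(ch3$age) - 51.5), 3)

  expect_error(generateCohort(10, c(18, 85), profiles[0, ], seed = 1),
               "profile")
  expect_error(generateCohort(10, c(85, 18), profiles, seed = 1),
               "ageRange")
})

test_that("couplingAtAge applies the linear-in-Z law and stays PSD", {
  rn <- paste0("R", 1:9)
  ## zero slope: inverse Fisher of the base, unchanged by age
  base <- matrix(0.2, 9, 9); diag(base) <- 0
  tru <- makeNetworkTruth(rn, baseZ = base, slopeZ = 0)
  expect_equal(couplingAtAge(tru, 25), couplingAtAge(tru, 80))
  expect_equal(couplingAtAge(tru, 25)[1, 2], tanh(0.2))

  ## zero base and slope: identity correlation
  tru0 <- makeNetworkTruth(rn, baseZ = 0, slopeZ = 0)
  expect_equal(couplingAtAge(tru0, 50), diag(9))

  ## endpoint interpolation through the reference group means is exact:
  ## base at the young-group mean age, slope to the old-group mean age
  youngAge <- 26.4; oldAge <- 76.6
  zy <- atanh(0.472); zo <- atanh(0.322)
  tru2 <- makeNetworkTruth(c("L OP4", "R OP4"), baseZ = zy,
                           slopeZ = (zo - zy) / (oldAge - youngAge),
                           referenceAge = youngAge)
  expect_equal(couplingAtAge(tru2, oldAge)[1, 2], 0.322, tolerance = 1e-8)

  ## non-symmetric truth rejected at construction
  bad <- matrix(rnorm(81), 9, 9)
  expect_error(makeNetworkTruth(rn, baseZ = bad), "symmetric")

  ## property: symmetric, unit diagonal, PSD for random strong truths
  set.seed(41)
  for (rep in 1:20) {
    z <- matrix(rnorm(81, sd = 0.8), 9, 9)
    z <- (z + t(z)) / 2; diag(z) <- 0
    tru3 <- makeNetworkTruth(rn, baseZ = z, slopeZ = 0)
    r <- couplingAtAge(tru3, 50)
    expect_equal(r, t(r))
    expect_equal(diag(r), rep(1, 9), ignore_attr = TRUE)
    expect_gte(min(eigen(r, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("simulateSubject plants recoverable signals deterministically", {
  seeds <- compressSeeds(defaultSeeds(), 0.35)
  geom <- makeGeometry(c(24L, 24L, 24L), 3)
  tru <- calibrateTruth(regionNames = seeds$name)
  quiet <- makeNoiseSpec(roiNoiseSd = 0, backgroundNoiseSd = 0,
                         driftAmplitude = 0, physioAmplitude = 0,
                         motionCoupling = 0)
  spec <- subjectSpec(age = 40, tr = 2.0, nVolumes = 300L)
  sub <- simulateSubject(spec, tru, seeds, quiet, geom, seed = 11)

  ## noiseless limit: seed-sphere mean signals carry the exact realized
  ## coupling
  d <- dim(scanData(sub$scan))
  mat <- matrix(scanData(sub$scan), prod(d[1:3]), d[4])
  means <- t(sapply(seq_len(nrow(seeds)), function(s) {
    idx <- sphereVoxels(seeds[s, ], sub$scan)
    colMeans(mat[idx, , drop = FALSE])
  }))
  expect_lt(max(abs(cor(t(means)) - sub$realized)), 1 / sqrt(300))

  ## bit-for-bit determinism
  sub2 <- simulateSubject(spec, tru, seeds, quiet, geom, seed = 11)
  expect_identical(scanData(sub$scan), scanData(sub2$scan))
  expect_identical(sub$motion, sub2$motion)

  ## physio at/above Nyquist rejected
  fast <- makeNoiseSpec(physioFrequency = 0.25)
  expect_error(simulateSubject(spec, tru, seeds, fast, geom, seed = 1),
               "Nyquist")

  ## overlapping spheres rejected
  crowd <- seeds
  crowd$x_mm[2] <- crowd$x_mm[1] + 1
  crowd$y_mm[2] <- crowd$y_mm[1]
  crowd$z_mm[2] <- crowd$z_mm[1]
  expect_error(simulateSubject(spec, tru, crowd, quiet, geom, seed = 1),
               "overlap")
})

test_that("planted spectral components appear raw and vanish after band-pass", {
  seeds <- compressSeeds(defaultSeeds(), 0.35)
  geom <- makeGeometry(c(24L, 24L, 24L), 3)
  tru <- twoRegionTruthFull <- calibrateTruth(regionNames = seeds$name)
  noise <- makeNoiseSpec(roiNoiseSd = 0.1, backgroundNoiseSd = 0.1,
                         driftAmplitude = 1, driftFrequency = 0.005,
                         physioAmplitude = 1, physioFrequency = 0.2,
                         motionCoupling = 0)
  ## TR 2.0 s, 400 frames: both planted frequencies fall on DFT bins
  spec <- subjectSpec(age = 50, tr = 2.0, nVolumes = 400L)
  sub <- simulateSubject(spec, tru, seeds, noise, geom, seed = 21)
  d <- dim(scanData(sub$scan))
  mat <- matrix(scanData(sub$scan), prod(d[1:3]), d[4])
  idx <- sphereVoxels(seeds[1, ], sub$scan)
  roi <- colMeans(mat[idx, , drop = FALSE])

  ampPhysio <- dftAmplitude(roi, 2.0, 0.2)
  neighbors <- mean(c(dftAmplitude(roi, 2.0, 0.2 - 3 / 800),
                      dftAmplitude(roi, 2.0, 0.2 + 3 / 800)))
  expect_gt(ampPhysio / neighbors, 5)
  ampDrift <- dftAmplitude(roi, 2.0, 0.005)
  expect_gt(ampDrift, 5 * dftAmplitude(roi, 2.0, 0.005 + 3 / 800))

  filtered <- bandpassFilter(roi, 2.0)
  expect_lt(dftAmplitude(filtered, 2.0, 0.2), 1e-10)
  expect_lt(dftAmplitude(filtered, 2.0, 0.005), 1e-10)
})

test_that("full-pipeline closure recovers realized coupling on noiseless data", {
  seeds <- compressSeeds(defaultSeeds(), 0.35)
  geom <- makeGeometry(c(24L, 24L, 24L), 3)
  tru <- calibrateTruth(regionNames = seeds$name)
  ## noiseless cohort: every NoiseSpec amplitude zero, including the motion
  ## random walks (all-zero motion columns are flagged constant, so the
  ## design contributes nothing and closure is exact: the latent signals
  ## live inside the pass band, so the boxcar filter leaves them untouched)
  quiet <- makeNoiseSpec(roiNoiseSd = 0, backgroundNoiseSd = 0,
                         driftAmplitude = 0, physioAmplitude = 0,
                         motionCoupling = 0, motionStepSd = 0)
  spec <- subjectSpec(age = 35, tr = 2.0, nVolumes = 300L)
  sub <- simulateSubject(spec, tru, seeds, quiet, geom, seed = 31)
  pre <- preprocessBold(sub$scan, sub$motion, includeTissue = FALSE)
  ts <- extractSeedTimeseries(pre$scan, seeds)
  r <- corMatrix(pairwiseCorrelation(ts))
  expect_lt(max(abs(r - sub$realized)), 0.05)
  expect_lt(max(abs(r - sub$realized)), 1e-6)

  ## with stochastic motion regressors present (signal still clean), the
  ## projection onto ~19 nuisance columns costs a share of the band's
  ## effective degrees of freedom and perturbs correlations; the pipeline
  ## must agree with an independent per-voxel lm() + filter oracle
  walk <- makeNoiseSpec(roiNoiseSd = 0, backgroundNoiseSd = 0,
                        driftAmplitude = 0, physioAmplitude = 0,
                        motionCoupling = 0)
  subW <- simulateSubject(spec, tru, seeds, walk, geom, seed = 32)
  preW <- preprocessBold(subW$scan, subW$motion, includeTissue = FALSE)
  rW <- corMatrix(pairwiseCorrelation(extractSeedTimeseries(preW$scan,
                                                            seeds)))
  motW <- as.matrix(subW$motion[, -1])
  desW <- buildConfoundDesign(motW, tissue = tissueMeans(subW$scan))
  keep <- !grepl("^(gm|wm|csf)", desW$columnNames)
  dW <- dim(scanData(subW$scan))
  matW <- matrix(scanData(subW$scan), prod(dW[1:3]), dW[4])
  oracleW <- t(sapply(seq_len(nrow(seeds)), function(s) {
    vox <- matW[sphereVoxels(seeds[s, ], subW$scan)[1], ]
    res <- unname(stats::lm.fit(desW$matrix[, keep], vox)$residuals)
    bandpassFilter(res, 2.0)
  }))
  expect_lt(max(abs(rW - cor(t(oracleW)))), 1e-8)

  ## with the tissue family included, the GM-mean regressor is pure seed
  ## leakage in this limit and its projection shifts correlations; the
  ## pipeline must match an independent per-voxel lm() + filter oracle
  preT <- preprocessBold(sub$scan, sub$motion, includeTissue = TRUE)
  tsT <- extractSeedTimeseries(preT$scan, seeds)
  rT <- corMatrix(pairwiseCorrelation(tsT))
  d <- dim(scanData(sub$scan))
  mat <- matrix(scanData(sub$scan), prod(d[1:3]), d[4])
  design <- buildConfoundDesign(
    as.matrix(sub$motion[, -1]), tissue = tissueMeans(sub$scan))
  oracle <- t(sapply(seq_len(nrow(seeds)), function(s) {
    vox <- mat[sphereVoxels(seeds[s, ], sub$scan)[1], ]
    res <- unname(stats::lm.fit(design$matrix, vox)$residuals)
    bandpassFilter(res, 2.0)
  }))
  expect_lt(max(abs(rT - cor(t(oracle)))), 1e-8)
})

test_that("generateFociDatabase plants convergence zones as specified", {
  geom <- makeGeometry(c(16L, 16L, 16L), 4)
  homes <- rbind(c(-18, -18, -18), c(18, -18, -18))
  zones <- rbind(c(0, 18, 0))

  ## scatter -> 0: foci exactly at the home seed and planted zones
  db0 <- generateFociDatabase(6, homes, zones, scatterSd = 1e-9,
                              backgroundRate = 0, geometry = geom,
                              seed = 2, fwhm = 12)
  fo <- fociTable(db0)
  expect_equal(nrow(fo), 12L)  # one home focus + one zone focus each
  homeFoci <- fo[seq(1, 12, by = 2), ]
  expect_equal(unname(as.matrix(homeFoci[, c("x_mm", "y_mm", "z_mm")])),
               homes[rep(1:2, 3), ], tolerance = 1e-6)
  zoneFoci <- as.matrix(fo[seq(2, 12, by = 2), c("x_mm", "y_mm", "z_mm")])
  expect_equal(unname(zoneFoci), zones[rep(1, 6), ], tolerance = 1e-6)

  ## no zones, no background: exactly one focus per experiment
  db1 <- generateFociDatabase(10, homes, NULL, scatterSd = 2,
                              backgroundRate = 0, geometry = geom,
                              seed = 3, fwhm = 12)
  expect_equal(as.integer(table(fociTable(db1)$experiment_id)),
               rep(1L, 10))

  ## isotropic scatter: mean of zone-nearest foci within 1 mm of the zone
  db2 <- generateFociDatabase(400, homes, zones, scatterSd = 3,
                              backgroundRate = 0, geometry = geom,
                              seed = 4, fwhm = 12)
  fo2 <- fociTable(db2)
  pts <- as.matrix(fo2[, c("x_mm", "y_mm", "z_mm")])
  d2zone <- colSums((t(pts) - zones[1, ])^2)
  nearest <- do.call(rbind, lapply(split(seq_len(nrow(fo2)),
                                         fo2$experiment_id),
                                   function(i) pts[i[which.min(d2zone[i])], ,
                                                   drop = FALSE]))
  expect_lt(sqrt(sum((colMeans(nearest) - zones[1, ])^2)), 1)

  expect_error(generateFociDatabase(5, homes, zones, scatterSd = 0,
                                    geometry = geom, seed = 1),
               "scatterSd")
  ## determinism
  expect_identical(fociTable(db2),
                   fociTable(generateFociDatabase(400, homes, zones,
                                                  scatterSd = 3,
                                                  backgroundRate = 0,
                                                  geometry = geom,
                                                  seed = 4, fwhm = 12)))
})

test_that("calibrateTruth reproduces the reference table generatively", {
  tru <- calibrateTruth()
  ref <- referenceAgeEffects()
  rn <- regionNames(tru)
  youngAge <- 18 + 67 * 100 / (2 * 399)
  oldAge <- 85 - 67 * 100 / (2 * 399)
  for (i in seq_len(nrow(ref))) {
    a <- match(ref$region_i[i], rn)
    b <- match(ref$region_j[i], rn)
    zy <- baseCoupling(tru)[a, b] +
      ageSlope(tru)[a, b] * (youngAge - referenceAge(tru))
    zo <- baseCoupling(tru)[a, b] +
      ageSlope(tru)[a, b] * (oldAge - referenceAge(tru))
    expect_equal(tanh(zy), ref$mean_r_young[i], tolerance = 1e-10)
    expect_equal(tanh(zo), ref$mean_r_old[i], tolerance = 1e-10)
  }
  expect_true(all(subjectSd(tru)[upper.tri(subjectSd(tru))] > 0))
})
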