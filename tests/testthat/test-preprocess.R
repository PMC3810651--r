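test_that("temporalDerivative is a backward difference with zero first row", {
  expect_equal(temporalDerivative(cbind(rep(5, 4))), cbind(rep(0, 4)))
  expect_equal(drop(temporalDerivative(c(0, 1, 3))), c(0, 1, 2))
  set.seed(1)
  steps <- rnorm(2000, 0, 0.02)
  walk <- cumsum(steps)
  d <- drop(temporalDerivative(walk))
  expect_equal(sd(d[-1]), sd(steps[-1]), tolerance = 0.05)
  expect_error(temporalDerivative(cbind(1)), "two time points")
})

test_that("tissueMeans averages each class per frame", {
  dims <- c(4L, 4L, 4L, 20L)
  tissue <- array(0L, dims[1:3])
  tissue[1:20] <- 1L; tissue[21] <- 2L; tissue[22:30] <- 3L
  gmCourse <- sin(seq_len(20))
  dat <- array(0, dims)
  mat <- matrix(0, 64, 20)
  mat[1:20, ] <- rep(gmCourse, each = 20)       # all GM voxels share it
  mat[21, ] <- cos(seq_len(20))                  # single WM voxel
  mat[22:30, ] <- rnorm(9 * 20)
  scan <- new("BoldScan", data = array(mat, dims), affine = diag(4),
              tr = 2, tissue = tissue, subjectId = "t")
  tm <- tissueMeans(scan)
  expect_equal(tm[, "gm"], gmCourse, ignore_attr = TRUE)
  expect_equal(tm[, "wm"], cos(seq_len(20)), ignore_attr = TRUE)

  tissue2 <- tissue; tissue2[tissue2 == 3L] <- 0L
  scan2 <- new("BoldScan", data = array(mat, dims), affine = diag(4),
               tr = 2, tissue = tissue2, subjectId = "t")
  expect_error(tissueMeans(scan2), "CSF")
})

test_that("tissue means inherit a planted drift in all three classes", {
  seeds <- compressSeeds(defaultSeeds(), 0.35)
  geom <- makeGeometry(c(24L, 24L, 24L), 3)
  tru <- calibrateTruth(regionNames = seeds$name)
  noise <- makeNoiseSpec(roiNoiseSd = 0.1, backgroundNoiseSd = 0.1,
                         driftAmplitude = 1, driftFrequency = 0.005)
  sub <- simulateSubject(subjectSpec(nVolumes = 400L), tru, seeds, noise,
                         geom, seed = 5)
  tm <- tissueMeans(sub$scan)
  for (cls in c("gm", "wm", "csf")) {
    amp <- dftAmplitude(tm[, cls], 2.0, 0.005)
    expect_gt(amp / dftAmplitude(tm[, cls], 2.0, 0.005 + 3 / 800), 5)
  }
})

test_that("buildConfoundDesign yields the 31-column first/second-order design", {
  set.seed(2)
  n <- 50
  motion <- matrix(rnorm(n * 6), n, 6)
  tissue <- matrix(rnorm(n * 3), n, 3)
  des <- buildConfoundDesign(motion, tissue = tissue)
  expect_equal(ncol(des$matrix), 31L)
  expect_equal(des$columnNames[1], "intercept")
  expect_equal(unname(des$matrix[, 1]), rep(1, n))

  ## square columns are squares of the centred inputs, re-centred
  c1 <- motion[, 1] - mean(motion[, 1])
  expect_equal(unname(des$matrix[, "mot1_sq"]), c1^2 - mean(c1^2))

  ## degenerate input: all-zero motion flags the whole motion family
  ## (12 first-order columns and their 12 squares); design still returned
  des0 <- buildConfoundDesign(matrix(0, n, 6), tissue = tissue)
  expect_equal(ncol(des0$matrix), 31L)
  expect_length(des0$constantColumns, 24L)
  expect_true(all(grepl("mot", des0$constantColumns)))

  expect_error(buildConfoundDesign(motion, tissue = tissue[-1, ]),
               "row counts")
})

test_that("regressConfounds leaves residuals orthogonal to the design", {
  set.seed(3)
  n <- 60
  motion <- matrix(rnorm(n * 6), n, 6)
  tissue <- matrix(rnorm(n * 3), n, 3)
  des <- buildConfoundDesign(motion, tissue = tissue)

  ## a pure multiple of a design column is annihilated
  y <- rbind(3.2 * des$matrix[, 5])
  expect_lt(max(abs(regressConfounds(y, des))), 1e-10)

  ## residual orthogonality for random data
  Y <- matrix(rnorm(20 * n), 20, n)
  R <- regressConfounds(Y, des)
  dots <- abs(R %*% des$matrix)
  expect_lt(max(dots), 1e-6 * max(abs(Y)) * n)

  ## a mean-zero series orthogonal to all columns passes through unchanged
  q <- qr.Q(qr(cbind(des$matrix, rnorm(n))))[, 32]
  expect_equal(drop(regressConfounds(rbind(q), des)), q, tolerance = 1e-10)

  ## rank-deficient designs are handled (duplicate columns)
  dup <- cbind(des$matrix, des$matrix[, 2])
  Rd <- regressConfounds(Y, dup)
  expect_lt(max(abs(Rd %*% des$matrix)), 1e-6 * max(abs(Y)) * n)

  ## unestimable: as many time points as design rank
  expect_error(regressConfounds(matrix(rnorm(10), 1), diag(10)),
               "unestimable")
})

test_that("bandpassFilter is an exact boxcar in the Fourier domain", {
  tr <- 2; n <- 256
  tt <- (0:(n - 1)) * tr
  inBand <- sin(2 * pi * 0.04 * tt)          # bin 0.04 * 512 = 20.48 -> on-bin?
  inBand <- sin(2 * pi * (20 / (n * tr)) * tt)   # exactly on bin 20
  outBand <- sin(2 * pi * (102 / (n * tr)) * tt) # ~0.199 Hz, on bin

  filt <- bandpassFilter(inBand, tr)
  expect_lt(max(abs(filt - inBand)), 1e-8)
  expect_lt(max(abs(bandpassFilter(outBand, tr))), 1e-10)

  ## DC removed
  expect_lt(abs(mean(bandpassFilter(inBand + 7, tr))), 1e-10)

  ## idempotence
  X <- matrix(rnorm(5 * n), 5, n)
  once <- bandpassFilter(X, tr)
  expect_equal(bandpassFilter(once, tr), once, tolerance = 1e-12)

  ## linearity
  Y <- matrix(rnorm(5 * n), 5, n)
  expect_equal(bandpassFilter(2 * X - 3 * Y, tr),
               2 * bandpassFilter(X, tr) - 3 * bandpassFilter(Y, tr),
               tolerance = 1e-8)

  ## Parseval: output variance = input variance * retained-bin fraction
  freqs <- pmin(0:(n - 1), n - 0:(n - 1)) / (n * tr)
  frac <- sum(freqs >= 0.01 & freqs <= 0.08 & (0:(n - 1)) != 0) / n
  set.seed(4)
  ratio <- replicate(100, {
    x <- rnorm(n)
    sum(bandpassFilter(x, tr)^2) / sum((x - mean(x))^2)
  })
  expect_equal(mean(ratio), frac, tolerance = 0.05)

  expect_error(bandpassFilter(inBand, 2.5, high = 0.3), "TR")
  expect_error(bandpassFilter(inBand, 2, low = 0.08, high = 0.01), "low")
})

test_that("preprocessBold removes planted confounds in the mandated order", {
  seeds <- compressSeeds(defaultSeeds(), 0.35)
  geom <- makeGeometry(c(24L, 24L, 24L), 3)
  tru <- calibrateTruth(regionNames = seeds$name)
  noise <- makeNoiseSpec(roiNoiseSd = 0.2, backgroundNoiseSd = 0.2,
                         motionCoupling = 1)
  sub <- simulateSubject(subjectSpec(nVolumes = 200L), tru, seeds, noise,
                         geom, seed = 9)
  pre <- preprocessBold(sub$scan, sub$motion)
  expect_equal(ncol(pre$design$matrix), 31L)
  ts <- extractSeedTimeseries(pre$scan, seeds)

  ## planted motion leakage is projected out: the extracted series are
  ## (numerically) uncorrelated with every motion regressor
  motReg <- scale(as.matrix(sub$motion[, -1]))
  cors <- abs(cor(t(ts), motReg))
  expect_lt(max(cors), 0.1)   # eigenvariate is not a design column, so not 0
  ## and the physio/drift lines are gone from the spectrum
  expect_lt(dftAmplitude(ts[1, ], 2.0, 0.15), 1e-10)
})
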