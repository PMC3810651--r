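## Shared fixtures and independent brute-force oracles.

## Small all-GM scan geometry for ROI tests.
allGmGeometry <- function(dim = c(9L, 9L, 9L), voxelSize = 3) {
  geom <- makeGeometry(dim, voxelSize)
  list(geometry = geom, tissue = array(1L, dim))
}

## One-row cohort spec.
subjectSpec <- function(age = 40, tr = 2.0, nVolumes = 300L,
                        id = "sub-test") {
  data.frame(subject_id = id, age = age, tr_s = tr,
             n_volumes = as.integer(nVolumes), stringsAsFactors = FALSE)
}

## Two-region truth with a given correlation at the reference age.
twoRegionTruth <- function(r = 0.5, slope = 0, referenceAge = 50) {
  makeNetworkTruth(c("A", "B"), baseZ = atanh(r), slopeZ = slope,
                   referenceAge = referenceAge)
}

## Brute-force sphere membership: scan every voxel, compare mm distance and
## tissue label.
bruteSphereVoxels <- function(peak, radius, geometry, tissue) {
  mm <- voxelCenters(geometry)
  keep <- integer(0)
  for (v in seq_len(nrow(mm))) {
    d <- sqrt(sum((mm[v, ] - peak)^2))
    if (d <= radius && as.integer(tissue)[v] == 1L) keep <- c(keep, v)
  }
  keep
}

## Brute-force Benjamini-Hochberg step-up: sort, scan thresholds, reject.
bruteBH <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  cutoff <- 0L
  for (i in seq_len(m)) if (sorted[i] <= i * q / m) cutoff <- i
  rejected <- logical(m)
  if (cutoff > 0L) rejected[ord[seq_len(cutoff)]] <- TRUE
  rejected
}

## Definition-level Spearman with average ranks, no cor() shortcuts.
bruteSpearman <- function(x, y) {
  avgRank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- avgRank(x)
  ry <- avgRank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

## Fourier amplitude of a series at the bin nearest frequency f.
dftAmplitude <- function(x, tr, f) {
  n <- length(x)
  bin <- round(f * n * tr)
  amp <- Mod(fft(x)) / n
  amp[bin + 1L]
}

## Planted-zone database on the meta-analysis grid: 6 well-separated home
## seeds (box corners) and 2 planted convergence zones shared by all
## experiments.
plantedZoneSetup <- function(nExperiments = 300L, seed = 5,
                             backgroundRate = 1) {
  geom <- makeGeometry(c(16L, 16L, 16L), 4)
  corners <- as.matrix(expand.grid(c(-18, 18), c(-18, 18), c(-18, 18)))
  homes <- corners[1:6, , drop = FALSE]
  zones <- corners[7:8, , drop = FALSE]
  db <- generateFociDatabase(nExperiments, homes, zones, scatterSd = 6,
                             backgroundRate = backgroundRate,
                             geometry = geom, seed = seed, fwhm = 12)
  list(geometry = geom, homes = homes, zones = zones, db = db)
}
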