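## Synthetic-data module: multi-site cohorts with a known age-coupling law,
## planted confounds, and foci databases with planted convergence zones.

## Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched. All generator determinism contracts rest on this.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      else if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Stage sub-seeds: master seed plus a documented per-stage counter offset,
## kept below 2^31. Avoids hidden coupling between stages' random streams.
.subSeed <- function(seed, stage) {
  (as.integer(seed) + 10007L * as.integer(stage)) %% 2147483629L
}

#' Noise specification constructor
#'
#' Defaults plant a slow drift at 0.005 Hz and a physiological sinusoid at
#' 0.15 Hz (below the slowest site's Nyquist of 0.2 Hz at TR 2.5 s), both of
#' amplitude 1 against band-limited region signals of s.d. ~0.6; voxel noise
#' s.d. 0.5; motion random walks with 0.02 mm/degree per-frame steps leaking
#' into seed voxels with weight 0.5.
#'
#' @param roiNoiseSd,backgroundNoiseSd,driftAmplitude,driftFrequency
#'   see [NoiseSpec-class].
#' @param physioAmplitude,physioFrequency,motionCoupling,motionStepSd
#'   see [NoiseSpec-class].
#' @return a [NoiseSpec-class].
#' @export
makeNoiseSpec <- function(roiNoiseSd = 0.5, backgroundNoiseSd = 0.5,
                          driftAmplitude = 1, driftFrequency = 0.005,
                          physioAmplitude = 1, physioFrequency = 0.15,
                          motionCoupling = 0.5, motionStepSd = 0.02) {
  new("NoiseSpec", roiNoiseSd = roiNoiseSd,
      backgroundNoiseSd = backgroundNoiseSd,
      driftAmplitude = driftAmplitude, driftFrequency = driftFrequency,
      physioAmplitude = physioAmplitude, physioFrequency = physioFrequency,
      motionCoupling = motionCoupling, motionStepSd = motionStepSd)
}

#' Network ground-truth constructor
#'
#' @param regionNames ordered region labels.
#' @param baseZ symmetric Fisher-Z matrix at the reference age, or a single
#'   number applied to every off-diagonal entry.
#' @param slopeZ symmetric Fisher-Z-per-year matrix, or a single number.
#' @param referenceAge years (default 51.5, the midpoint of 18-85).
#' @param subjectSd between-subject s.d. of subject-level Fisher-Z offsets;
#'   symmetric matrix or single number (default 0: no inter-subject
#'   variability).
#' @return a [NetworkTruth-class].
#' @export
makeNetworkTruth <- function(regionNames, baseZ = 0, slopeZ = 0,
                             referenceAge = 51.5, subjectSd = 0) {
  n <- length(regionNames)
  expand <- function(x) {
    if (length(x) == 1L) {
      m <- matrix(x, n, n); diag(m) <- 0; m
    } else as.matrix(x)
  }
  new("NetworkTruth", regionNames = regionNames, baseZ = expand(baseZ),
      slopeZ = expand(slopeZ), referenceAge = referenceAge,
      subjectSd = expand(subjectSd))
}

#' Generate a multi-site cohort table
#'
#' Ages are drawn uniformly over \code{ageRange} (uniform rather than
#' site-matched: it maximises power for age-slope recovery while the site
#' profiles carry the TR/duration heterogeneity). Sites are assigned by the
#' profile weights; TR and volume count are copied from the assigned profile.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param ageRange numeric(2), inclusive age interval in years.
#' @param siteProfiles data.frame with columns \code{site}, \code{tr_s},
#'   \code{n_volumes} and a weight column \code{n} (or \code{weight});
#'   default [defaultSiteProfiles()].
#' @param seed RNG seed; fixed seed gives a bit-identical cohort.
#' @param femaleFraction probability of \code{sex == "female"}
#'   (default 0.46, the reference cohort's fraction).
#' @return data.frame with columns \code{subject_id}, \code{age}, \code{sex},
#'   \code{site}, \code{tr_s}, \code{n_volumes}.
#' @examples
#' head(generateCohort(10, seed = 1))
#' @export
generateCohort <- function(nSubjects, ageRange = c(18, 85),
                           siteProfiles = defaultSiteProfiles(),
                           seed = NULL, femaleFraction = 0.46) {
  if (is.null(siteProfiles) || nrow(siteProfiles) == 0L)
    stop("siteProfiles must contain at least one profile")
  if (length(ageRange) != 2L || ageRange[1] > ageRange[2])
    stop("ageRange must be an interval with ageRange[1] <= ageRange[2]")
  stopifnot(nSubjects >= 2L)
  w <- if ("weight" %in% names(siteProfiles)) siteProfiles$weight
       else siteProfiles$n
  if (is.null(w) || any(w <= 0))
    stop("site profiles need positive weights ('n' or 'weight' column)")
  .withSeed(seed, {
    age <- runif(nSubjects, ageRange[1], ageRange[2])
    siteIdx <- sample.int(nrow(siteProfiles), nSubjects, replace = TRUE,
                          prob = w / sum(w))
    sex <- ifelse(runif(nSubjects) < femaleFraction, "female", "male")
    data.frame(
      subject_id = sprintf("sub-%04d", seq_len(nSubjects)),
      age = age, sex = sex,
      site = siteProfiles$site[siteIdx],
      tr_s = siteProfiles$tr_s[siteIdx],
      n_volumes = as.integer(siteProfiles$n_volumes[siteIdx]),
      stringsAsFactors = FALSE
    )
  })
}

## Nearest positive-semidefinite correlation matrix: clip eigenvalues at a
## small floor, rescale to unit diagonal, iterate until the minimum
## eigenvalue clears -1e-10. Simplest projection preserving symmetry and the
## unit diagonal.
.nearPSDCorr <- function(r, floor = 1e-8, maxIter = 50L) {
  for (iter in seq_len(maxIter)) {
    e <- eigen(r, symmetric = TRUE)
    if (min(e$values) >= -1e-10 && max(abs(diag(r) - 1)) < 1e-12) return(r)
    vals <- pmax(e$values, floor)
    r <- e$vectors %*% (vals * t(e$vectors))
    d <- sqrt(diag(r))
    r <- r / tcrossprod(d)
    r <- (r + t(r)) / 2
    diag(r) <- 1
  }
  r
}

#' Population correlation matrix at a given age
#'
#' Applies the linear-in-Fisher-Z coupling law
#' \code{z_ij(age) = baseZ_ij + slopeZ_ij (age - referenceAge)}, maps back to
#' correlations with the inverse Fisher transform, and repairs the result to
#' the nearest positive-semidefinite correlation matrix (eigenvalue clipping
#' plus diagonal rescaling) if necessary.
#'
#' @param truth a [NetworkTruth-class].
#' @param age years.
#' @return symmetric unit-diagonal PSD correlation matrix.
#' @examples
#' tr <- makeNetworkTruth(c("A", "B"), baseZ = atanh(0.5))
#' couplingAtAge(tr, 40)[1, 2]  # 0.5
#' @export
couplingAtAge <- function(truth, age) {
  stopifnot(is(truth, "NetworkTruth"), length(age) == 1L, is.finite(age))
  z <- baseCoupling(truth) + ageSlope(truth) * (age - referenceAge(truth))
  r <- tanh(z)
  diag(r) <- 1
  r <- .nearPSDCorr(r)
  if (min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("PSD repair failed")
  r
}

## Subject-level coupling: population law plus (optionally) a subject-
## specific Fisher-Z offset with s.d. subjectSd, re-projected to PSD.
.subjectCoupling <- function(truth, age) {
  z <- baseCoupling(truth) + ageSlope(truth) * (age - referenceAge(truth))
  sdm <- subjectSd(truth)
  if (any(sdm > 0)) {
    n <- nrow(z)
    eps <- .symFromVec(rnorm(n * (n - 1) / 2, 0, .upperVec(sdm)), n)
    z <- z + eps
  }
  r <- tanh(z)
  diag(r) <- 1
  .nearPSDCorr(r)
}

## Band-limited multivariate-normal region signals: white draws from Sigma,
## then the package's own boxcar band-pass. Rows = regions, cols = frames.
.latentSignals <- function(nVolumes, tr, sigma, low = 0.01, high = 0.08) {
  n <- nrow(sigma)
  white <- matrix(rnorm(nVolumes * n), nVolumes, n) %*% chol(sigma)
  bandpassFilter(t(white), tr, low = low, high = high)
}

## Concentric synthetic anatomy: WM core, GM shell out to the radius that
## contains every seed sphere, thin CSF rind, background beyond; seed spheres
## stamped GM afterwards so extraction always finds gray matter.
.makeTissue <- function(geometry, seeds) {
  mm <- voxelCenters(geometry)
  rad <- sqrt(rowSums(mm^2))
  voxel <- max(sqrt(colSums(geometry@affine[1:3, 1:3]^2)))
  seedNorm <- sqrt(seeds$x_mm^2 + seeds$y_mm^2 + seeds$z_mm^2)
  brainR <- max(seedNorm + seeds$radius_mm) + 2 * voxel
  wmR <- 0.3 * brainR
  csfR <- brainR + 2 * voxel
  lab <- integer(nrow(mm))
  lab[rad < csfR] <- 3L
  lab[rad < brainR] <- 1L
  lab[rad < wmR] <- 2L
  tissue <- array(lab, geometry@dim)
  for (s in seq_len(nrow(seeds))) {
    d2 <- (mm[, 1] - seeds$x_mm[s])^2 + (mm[, 2] - seeds$y_mm[s])^2 +
      (mm[, 3] - seeds$z_mm[s])^2
    tissue[d2 <= seeds$radius_mm[s]^2] <- 1L
  }
  tissue
}

#' Simulate one subject's BOLD scan
#'
#' Nine latent region signals are drawn from a multivariate normal with the
#' subject's age-dependent coupling and band-limited to the 0.01-0.08 Hz
#' analysis band (resting-state BOLD fluctuations of interest are slow; this
#' also makes the noiseless pipeline round-trip exact). Every voxel inside a
#' seed sphere carries its region's signal plus independent noise, the
#' planted motion-regressor leakage, drift and physiological sinusoids;
#' other brain voxels carry drift, physio and noise only; background voxels
#' are zero. The returned realized coupling is the empirical correlation
#' matrix of the latent signals actually used.
#'
#' @param spec one cohort row (data.frame with \code{subject_id}, \code{age},
#'   \code{tr_s}, \code{n_volumes}).
#' @param truth a [NetworkTruth-class].
#' @param seeds seed data.frame (already in grid coordinates, e.g. via
#'   [compressSeeds()]).
#' @param noise a [NoiseSpec-class].
#' @param geometry a [VolumeGeometry-class]; tissue labels are generated by
#'   the packaged concentric anatomy unless \code{tissue} is supplied.
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @param tissue optional 3D integer label array.
#' @return list with \code{scan} ([BoldScan-class]), \code{motion}
#'   (data.frame \code{t, tx, ty, tz, rx, ry, rz}), and \code{realized}
#'   (the latent correlation matrix).
#' @export
simulateSubject <- function(spec, truth, seeds, noise = makeNoiseSpec(),
                            geometry = makeGeometry(), seed = NULL,
                            tissue = NULL) {
  stopifnot(is(truth, "NetworkTruth"), is(noise, "NoiseSpec"),
            nrow(spec) == 1L)
  tr <- spec$tr_s
  nT <- spec$n_volumes
  if (noise@physioFrequency >= 1 / (2 * tr))
    stop(sprintf("physio frequency %.3g Hz is at or above Nyquist %.3g Hz",
                 noise@physioFrequency, 1 / (2 * tr)))
  if (is.null(tissue)) tissue <- .makeTissue(geometry, seeds)
  d <- geometry@dim
  nVox <- prod(d)

  ## seed sphere voxel sets (GM by construction); overlap is a fault
  sph <- lapply(seq_len(nrow(seeds)), function(s)
    sphereVoxels(seeds[s, ], geometry, tissue))
  allIdx <- unlist(sph)
  if (anyDuplicated(allIdx))
    stop("seed spheres overlap; adjust the grid or compression scale")

  .withSeed(seed, {
    sigma <- .subjectCoupling(truth, spec$age)
    latent <- .latentSignals(nT, tr, sigma)
    realized <- cor(t(latent))
    dimnames(realized) <- list(regionNames(truth), regionNames(truth))

    motion <- matrix(0, nT, 6)
    for (j in 1:6) motion[, j] <- cumsum(rnorm(nT, 0, noise@motionStepSd))
    colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    sds <- apply(motion, 2, sd)
    if (all(sds > 0)) {
      motReg <- rowMeans(scale(motion))
      if (sd(motReg) > 0) motReg <- motReg / sd(motReg)
    } else motReg <- numeric(nT)   # degenerate (zero-step) motion

    tt <- (seq_len(nT) - 1) * tr
    drift <- noise@driftAmplitude *
      sin(2 * pi * noise@driftFrequency * tt + runif(1, 0, 2 * pi))
    physio <- noise@physioAmplitude *
      sin(2 * pi * noise@physioFrequency * tt + runif(1, 0, 2 * pi))
    shared <- drift + physio

    dataMat <- matrix(0, nVox, nT)
    brain <- which(tissue > 0L)
    nb <- length(brain)
    dataMat[brain, ] <- rep(shared, each = nb) +
      rnorm(nb * nT, 0, noise@backgroundNoiseSd)
    for (s in seq_along(sph)) {
      idx <- sph[[s]]
      ns <- length(idx)
      dataMat[idx, ] <- dataMat[idx, , drop = FALSE] +
        rep(latent[s, ], each = ns) +
        rnorm(ns * nT, 0, max(noise@roiNoiseSd - noise@backgroundNoiseSd, 0)) +
        noise@motionCoupling * rep(motReg, each = ns)
    }

    scan <- new("BoldScan", data = array(dataMat, c(d, nT)),
                affine = geometry@affine, tr = tr, tissue = tissue,
                subjectId = spec$subject_id)
    list(scan = scan,
         motion = data.frame(t = tt, motion),
         realized = realized)
  })
}

#' Simulate a cohort at the seed-timeseries level
#'
#' Fast path that skips the voxel stage: for each subject the latent
#' band-limited region signals are generated exactly as in
#' [simulateSubject()] and correlated directly. Used for group-level
#' calibration and null studies where voxel plumbing is irrelevant.
#'
#' @param cohort a cohort data.frame from [generateCohort()].
#' @param truth a [NetworkTruth-class].
#' @param seed RNG seed.
#' @return list with \code{z} (n_subjects x 36 Fisher-Z matrix in
#'   [connectionIndex()] order), \code{ages}, and \code{connections}.
#' @export
simulateSeedCohort <- function(cohort, truth, seed = NULL) {
  rn <- regionNames(truth)
  ci <- connectionIndex(rn)
  .withSeed(seed, {
    z <- matrix(NA_real_, nrow(cohort), nrow(ci),
                dimnames = list(cohort$subject_id, ci$connection))
    for (i in seq_len(nrow(cohort))) {
      sigma <- .subjectCoupling(truth, cohort$age[i])
      latent <- .latentSignals(cohort$n_volumes[i], cohort$tr_s[i], sigma)
      r <- cor(t(latent))
      z[i, ] <- atanh(.upperVec(r))
    }
    list(z = z, ages = cohort$age, connections = ci)
  })
}

## Fisher-Z sampling s.d. of a correlation estimated from series band-limited
## to [low, high]: the estimator only has ~2B real degrees of freedom, where
## B is the number of retained positive-frequency bins.
.zEstimationSd <- function(nVolumes, tr, low = 0.01, high = 0.08) {
  freqs <- seq_len(floor(nVolumes / 2)) / (nVolumes * tr)
  b <- sum(freqs >= low & freqs <= high)
  if (b < 2L) stop("band retains fewer than 2 frequency bins")
  1 / sqrt(2 * b - 3)
}

#' Calibrate generative truth to a reference age-effect table
#'
#' Places the linear-in-Z coupling law exactly through the reference group
#' means: with ages uniform on \code{ageRange}, the expected mean ages of the
#' k youngest and k oldest of n subjects are
#' \code{lo + w k/(2n)} and \code{hi - w k/(2n)} (w = range width); the base
#' and slope are chosen so the population mean Fisher-Z at those ages equals
#' \code{atanh(mean_r_young)} and \code{atanh(mean_r_old)}. Linearity of the
#' law makes this endpoint calibration exact in expectation. The
#' between-subject s.d. is then set per connection so the population
#' correlation between subject Fisher-Z and age matches the reference
#' \code{rho_s}: \code{sigma_total = |slope| sd(age) sqrt(1/rho^2 - 1)},
#' minus (in quadrature) the estimation noise implied by the scan length.
#' Connections absent from the reference table get \code{baseOtherZ}, zero
#' slope, and the median calibrated between-subject s.d.
#'
#' @param reference data.frame like [referenceAgeEffects()].
#' @param regionNames region labels (default the packaged seed order).
#' @param n,k cohort size and extreme-group size (defaults 399, 100).
#' @param ageRange age interval (default 18-85).
#' @param nVolumes,tr scan length and repetition time used to size the
#'   estimation-noise component (defaults 260 volumes at TR 2.5 s).
#' @param baseOtherZ population Fisher-Z for connections not in the
#'   reference table (default 0).
#' @return a [NetworkTruth-class] with calibrated \code{subjectSd}.
#' @export
calibrateTruth <- function(reference = referenceAgeEffects(),
                           regionNames = defaultSeeds()$name,
                           n = 399L, k = 100L, ageRange = c(18, 85),
                           nVolumes = 260L, tr = 2.5, baseOtherZ = 0) {
  nr <- length(regionNames)
  w <- diff(ageRange)
  youngMean <- ageRange[1] + w * k / (2 * n)
  oldMean <- ageRange[2] - w * k / (2 * n)
  refAge <- mean(ageRange)
  sdAge <- w / sqrt(12)
  sigmaEst <- .zEstimationSd(nVolumes, tr)

  baseZ <- matrix(baseOtherZ, nr, nr)
  slopeZ <- matrix(0, nr, nr)
  sdZ <- matrix(NA_real_, nr, nr)
  diag(baseZ) <- 0

  calibrated <- numeric(0)
  for (rI in seq_len(nrow(reference))) {
    i <- match(reference$region_i[rI], regionNames)
    j <- match(reference$region_j[rI], regionNames)
    if (is.na(i) || is.na(j))
      stop("reference table names a region outside regionNames")
    zy <- atanh(reference$mean_r_young[rI])
    zo <- atanh(reference$mean_r_old[rI])
    slope <- (zo - zy) / (oldMean - youngMean)
    base <- zy + slope * (refAge - youngMean)
    rho <- reference$rho_s[rI]
    sigmaTot <- abs(slope) * sdAge * sqrt(1 / rho^2 - 1)
    sigmaB <- sqrt(max(sigmaTot^2 - sigmaEst^2, 0))
    baseZ[i, j] <- baseZ[j, i] <- base
    slopeZ[i, j] <- slopeZ[j, i] <- slope
    sdZ[i, j] <- sdZ[j, i] <- sigmaB
    calibrated <- c(calibrated, sigmaB)
  }
  sdZ[is.na(sdZ)] <- stats::median(calibrated)
  diag(sdZ) <- 0
  makeNetworkTruth(regionNames, baseZ = baseZ, slopeZ = slopeZ,
                   referenceAge = refAge, subjectSd = sdZ)
}

#' Default ALE kernel width as a function of sample size
#'
#' Between-subject spatial uncertainty shrinks with the number of subjects an
#' experiment scanned; the packaged model is
#' \code{fwhm(n) = sqrt(a + b/n)} mm with defaults a = 74, b = 260, an
#' approximation giving ~10 mm at n = 10 and ~8.9 mm at n = 50 (the
#' magnitudes empirical models in the field report). Tests and analyses can
#' always pin the kernel width per experiment instead.
#'
#' @param n number of subjects (positive).
#' @param a,b model constants (mm^2).
#' @return kernel FWHM in mm.
#' @export
fwhmOfN <- function(n, a = 74, b = 260) {
  stopifnot(all(n > 0))
  sqrt(a + b / n)
}

## Clip mm coordinates into the geometry's voxel-centre bounding box.
.clampToGrid <- function(geometry, mm) {
  mm <- rbind(mm)
  lo <- .voxelToMm(geometry, c(0, 0, 0))
  hi <- .voxelToMm(geometry, geometry@dim - 1)
  for (a in 1:3) mm[, a] <- pmin(pmax(mm[, a], min(lo[a], hi[a])),
                                 max(lo[a], hi[a]))
  mm
}

#' Generate a foci database with planted convergence zones
#'
#' Every experiment has a "home" seed (assigned round-robin over
#' \code{seedCoords}) near which it reports one focus (isotropic Gaussian
#' scatter, s.d. \code{scatterSd}), one focus scattered around each planted
#' zone, and Poisson(\code{backgroundRate}) background foci uniform over the
#' mask. The planted zones are therefore convergence zones shared by all
#' experiments, emulating task-general co-activation with known truth.
#'
#' @param nExperiments number of experiments.
#' @param seedCoords matrix/data.frame of home-seed mm coordinates
#'   (columns x, y, z).
#' @param plantedZones matrix of planted-zone mm coordinates (possibly
#'   0 rows).
#' @param scatterSd isotropic scatter s.d. in mm (> 0).
#' @param backgroundRate expected uniform background foci per experiment.
#' @param geometry analysis-mask [VolumeGeometry-class].
#' @param seed RNG seed.
#' @param fwhm kernel FWHM in mm: one value for all experiments, or NULL to
#'   use [fwhmOfN()] of the drawn sample size.
#' @param nSubjectsRange inclusive integer range from which each
#'   experiment's sample size is drawn.
#' @return a [FociDatabase-class]; scattered foci are clipped to the mask's
#'   bounding box so every focus lies in-analysis.
#' @export
generateFociDatabase <- function(nExperiments, seedCoords,
                                 plantedZones = NULL, scatterSd = 6,
                                 backgroundRate = 0,
                                 geometry = makeGeometry(c(16, 16, 16), 4),
                                 seed = NULL, fwhm = NULL,
                                 nSubjectsRange = c(10L, 30L)) {
  if (scatterSd <= 0) stop("scatterSd must be positive")
  stopifnot(nExperiments >= 1L)
  seedCoords <- rbind(as.matrix(seedCoords))
  if (!is.null(plantedZones) && length(plantedZones))
    plantedZones <- rbind(as.matrix(plantedZones))
  else plantedZones <- matrix(0, 0, 3)
  maskIdx <- which(geometry@mask)
  mmAll <- voxelCenters(geometry)

  .withSeed(seed, {
    home <- rep_len(seq_len(nrow(seedCoords)), nExperiments)
    ns <- sample(nSubjectsRange[1]:nSubjectsRange[2], nExperiments,
                 replace = TRUE)
    fw <- if (is.null(fwhm)) fwhmOfN(ns) else rep_len(fwhm, nExperiments)
    ids <- sprintf("exp-%05d", seq_len(nExperiments))
    fociList <- vector("list", nExperiments)
    for (e in seq_len(nExperiments)) {
      pts <- rbind(seedCoords[home[e], ], plantedZones)
      pts <- pts + matrix(rnorm(length(pts), 0, scatterSd), nrow(pts), 3)
      nBg <- rpois(1, backgroundRate)
      if (nBg > 0) {
        vox <- maskIdx[sample.int(length(maskIdx), nBg, replace = TRUE)]
        pts <- rbind(pts, mmAll[vox, , drop = FALSE])
      }
      pts <- .clampToGrid(geometry, pts)
      fociList[[e]] <- data.frame(experiment_id = ids[e], x_mm = pts[, 1],
                                  y_mm = pts[, 2], z_mm = pts[, 3])
    }
    new("FociDatabase",
        experiments = data.frame(experiment_id = ids, n_subjects = ns,
                                 fwhm_mm = fw, stringsAsFactors = FALSE),
        foci = do.call(rbind, fociList))
  })
}

#' Generate a null foci database (no spatial convergence)
#'
#' Every focus is an independently chosen in-mask voxel centre; experiments
#' report 1-3 (configurable) such foci. This is the no-convergence reference
#' condition for family-wise-error calibration of the cluster-level
#' inference.
#'
#' @param nExperiments number of experiments.
#' @param geometry analysis-mask [VolumeGeometry-class].
#' @param fociPerExperiment integer vector of candidate focus counts, drawn
#'   uniformly per experiment.
#' @param fwhm kernel FWHM in mm for all experiments.
#' @param seed RNG seed.
#' @param nSubjectsRange inclusive sample-size range.
#' @return a [FociDatabase-class].
#' @export
nullFociDatabase <- function(nExperiments,
                             geometry = makeGeometry(c(16, 16, 16), 4),
                             fociPerExperiment = 1:3, fwhm = 12,
                             seed = NULL, nSubjectsRange = c(10L, 30L)) {
  maskIdx <- which(geometry@mask)
  mmAll <- voxelCenters(geometry)
  .withSeed(seed, {
    ids <- sprintf("exp-%05d", seq_len(nExperiments))
    ns <- sample(nSubjectsRange[1]:nSubjectsRange[2], nExperiments,
                 replace = TRUE)
    nf <- if (length(fociPerExperiment) == 1L)
      rep(fociPerExperiment, nExperiments)
    else sample(fociPerExperiment, nExperiments, replace = TRUE)
    vox <- maskIdx[sample.int(length(maskIdx), sum(nf), replace = TRUE)]
    pts <- mmAll[vox, , drop = FALSE]
    new("FociDatabase",
        experiments = data.frame(experiment_id = ids, n_subjects = ns,
                                 fwhm_mm = fwhm, stringsAsFactors = FALSE),
        foci = data.frame(experiment_id = rep(ids, nf), x_mm = pts[, 1],
                          y_mm = pts[, 2], z_mm = pts[, 3]))
  })
}
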