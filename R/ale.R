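## Meta-analytic connectivity modeling: experiment selection, ALE maps,
## random-spatial-association null, cluster-level FWE, conjunction.

.sigmaFromFwhm <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

## Peak MA value: Gaussian probability mass per voxel at the focus,
## capped at 1.
.peakMA <- function(sigma, voxelVolume) {
  min(1, voxelVolume * (2 * pi * sigma^2)^(-1.5))
}

## Kernels are truncated where the Gaussian falls below this fraction of its
## peak; the same rule applies to observed maps, null histograms and
## permutation maps, keeping the voxel-p calibration internally consistent.
.KERNEL_REL_TRUNC <- 1e-4

## Precomputed kernel cube over integer voxel offsets (for permutation maps,
## where relocated foci sit on voxel centres).
.kernelCube <- function(fwhm, voxelSize) {
  sigma <- .sigmaFromFwhm(fwhm)
  pMax <- .peakMA(sigma, voxelSize^3)
  maxD <- sigma * sqrt(-2 * log(.KERNEL_REL_TRUNC))
  hw <- as.integer(ceiling(maxD / voxelSize))
  off <- (-hw):hw
  d2 <- outer(outer(off^2, off^2, "+"), off^2, "+") * voxelSize^2
  g <- exp(-d2 / (2 * sigma^2))
  g[g < .KERNEL_REL_TRUNC] <- 0
  list(values = pMax * g, halfwidth = hw)
}

#' Select the k experiments reporting activation closest to a seed
#'
#' An experiment's distance to the seed is the minimum Euclidean mm distance
#' over its foci; the k smallest distances are selected, with ties at rank k
#' broken by experiment id. The distance of the k-th experiment is the
#' "maximum distance" associated with the seed.
#'
#' @param db a [FociDatabase-class].
#' @param peak seed mm coordinates (length 3). (Named `peak`, not
#'   `seed*`: RNG `seed` arguments passed through `...` elsewhere must not
#'   partially match it.)
#' @param k number of experiments (default 100).
#' @return list with \code{db} (the selected sub-database),
#'   \code{experimentIds}, \code{maxDistance} (mm), and \code{distances}
#'   (data.frame over the full database).
#' @export
selectNearestExperiments <- function(db, peak, k = 100L) {
  ex <- experimentTable(db)
  if (k > nrow(ex))
    stop(sprintf("k = %d exceeds the database size %d", k, nrow(ex)))
  fo <- fociTable(db)
  d <- sqrt((fo$x_mm - peak[1])^2 + (fo$y_mm - peak[2])^2 +
              (fo$z_mm - peak[3])^2)
  minD <- tapply(d, factor(fo$experiment_id, levels = ex$experiment_id),
                 min)
  ord <- order(minD, ex$experiment_id)
  sel <- ord[seq_len(k)]
  ids <- ex$experiment_id[sel]
  list(db = subsetFociDatabase(db, ids), experimentIds = ids,
       maxDistance = unname(minD[sel[k]]),
       distances = data.frame(experiment_id = ex$experiment_id,
                              distance_mm = as.numeric(minD),
                              stringsAsFactors = FALSE))
}

#' Subset a foci database by experiment id
#'
#' @param db a [FociDatabase-class].
#' @param ids experiment ids to keep.
#' @return a [FociDatabase-class].
#' @export
subsetFociDatabase <- function(db, ids) {
  ex <- experimentTable(db)
  fo <- fociTable(db)
  new("FociDatabase",
      experiments = ex[ex$experiment_id %in% ids, , drop = FALSE],
      foci = fo[fo$experiment_id %in% ids, , drop = FALSE])
}

#' Modeled-activation map of one experiment
#'
#' Per voxel, the maximum over the experiment's foci of an isotropic 3D
#' Gaussian \code{pMax exp(-d^2 / (2 sigma^2))} with
#' \code{sigma = fwhm / (2 sqrt(2 log 2))} and peak \code{pMax} equal to the
#' Gaussian probability mass of one voxel at the focus (capped at 1). The
#' maximum (not the sum) implements the non-additive within-experiment rule:
#' two coincident foci are no more evidence than one. Foci outside the mask
#' are clamped to the nearest in-mask voxel centre with a warning.
#'
#' @param foci matrix/data.frame of mm coordinates (columns x, y, z).
#' @param geometry the analysis [VolumeGeometry-class].
#' @param fwhm kernel width in mm.
#' @return 3D MA array, zero outside the mask.
#' @export
modeledActivation <- function(foci, geometry, fwhm) {
  stopifnot(fwhm > 0)
  foci <- rbind(as.matrix(foci))[, 1:3, drop = FALSE]
  sigma <- .sigmaFromFwhm(fwhm)
  voxelVol <- abs(det(geometry@affine[1:3, 1:3]))
  pMax <- .peakMA(sigma, voxelVol)
  mm <- voxelCenters(geometry)
  maskVec <- as.vector(geometry@mask)
  ma <- numeric(nrow(mm))
  for (f in seq_len(nrow(foci))) {
    pt <- foci[f, ]
    v <- .mmToVoxel(geometry, pt)
    vr <- pmin(pmax(round(v), 0), geometry@dim - 1)
    if (any(v < -0.5) || any(v > geometry@dim - 0.5) ||
        !maskVec[.linearIndex(geometry@dim, vr)]) {
      inIdx <- which(maskVec)
      d2in <- colSums((t(mm[inIdx, , drop = FALSE]) - pt)^2)
      pt <- mm[inIdx[which.min(d2in)], ]
      warning(sprintf("focus (%.1f, %.1f, %.1f) outside mask; clamped",
                      foci[f, 1], foci[f, 2], foci[f, 3]))
    }
    d2 <- (mm[, 1] - pt[1])^2 + (mm[, 2] - pt[2])^2 + (mm[, 3] - pt[3])^2
    g <- exp(-d2 / (2 * sigma^2))
    g[g < .KERNEL_REL_TRUNC] <- 0
    ma <- pmax(ma, pMax * g)
  }
  ma[!maskVec] <- 0
  array(ma, geometry@dim)
}

## MA maps for every experiment of a database.
.maVolumes <- function(db, geometry) {
  ex <- experimentTable(db)
  fo <- fociTable(db)
  lapply(seq_len(nrow(ex)), function(e) {
    sub <- fo[fo$experiment_id == ex$experiment_id[e], , drop = FALSE]
    modeledActivation(cbind(sub$x_mm, sub$y_mm, sub$z_mm), geometry,
                      ex$fwhm_mm[e])
  })
}

#' Union of modeled-activation maps into an ALE map
#'
#' \code{ale = 1 - prod_e (1 - MA_e)} voxelwise.
#'
#' @param maVolumes list of MA arrays with identical dimensions.
#' @return 3D ALE array.
#' @export
aleUnion <- function(maVolumes) {
  dims <- dim(maVolumes[[1]])
  for (m in maVolumes)
    if (!identical(dim(m), dims)) stop("MA volume geometries differ")
  prodC <- Reduce(function(acc, m) acc * (1 - m), maVolumes,
                  array(1, dims))
  1 - prodC
}

#' Voxelwise ALE significance under the random-spatial-association null
#'
#' The null ALE value at a voxel is the union of one uniformly random
#' in-mask MA value per experiment. \code{analytic_histogram} discretises
#' each experiment's in-mask MA values into fixed-width bins and convolves
#' the complement products exactly (bins with mass below 1e-16 are pruned);
#' \code{monte_carlo} draws \code{nNull} random unions. Voxel p is
#' \code{P(null ALE >= observed)}; z is the standard-normal quantile of
#' 1 - p, with p clamped to the resolution of the null so z stays finite.
#'
#' @param maVolumes list of MA arrays (one per experiment).
#' @param geometry the analysis [VolumeGeometry-class].
#' @param method \code{"analytic_histogram"} (default) or
#'   \code{"monte_carlo"}.
#' @param nNull Monte-Carlo draw count (>= 100).
#' @param binWidth histogram bin width (default 1e-5).
#' @param seed RNG seed for the Monte-Carlo method.
#' @return list with \code{result} (an [AleResult-class]) and \code{null}
#'   (the null representation, usable with [aleCritical()]).
#' @export
aleVoxelSignificance <- function(maVolumes, geometry,
                                 method = c("analytic_histogram",
                                            "monte_carlo"),
                                 nNull = 1e5, binWidth = 1e-5,
                                 seed = NULL) {
  method <- match.arg(method)
  maskVec <- as.vector(geometry@mask)
  if (!any(maskVec)) stop("empty analysis mask")
  ale <- aleUnion(maVolumes)
  maskedMA <- lapply(maVolumes, function(m) as.vector(m)[maskVec])

  if (method == "analytic_histogram") {
    nb <- as.integer(ceiling(1 / binWidth)) + 1L
    H <- numeric(nb)
    H[1] <- 1
    for (vals in maskedMA) {
      bins <- pmin(as.integer(round(vals / binWidth)), nb - 1L)
      tab <- tabulate(bins + 1L, nbins = nb)
      nz <- which(tab > 0L)
      Hn <- cpp_combine_hist(H, tab[nz] / length(vals),
                             (nz - 1) * binWidth, binWidth)
      Hn[Hn < 1e-16] <- 0
      H <- Hn / sum(Hn)
    }
    tailMass <- rev(cumsum(rev(H)))
    null <- list(method = method, hist = H, tail = tailMass,
                 binWidth = binWidth)
    obsBins <- pmin(as.integer(round(as.vector(ale) / binWidth)), nb - 1L)
    p <- tailMass[obsBins + 1L]
    pFloor <- max(min(tailMass[tailMass > 0]), 1e-12)
  } else {
    if (nNull < 100) stop("monte_carlo needs nNull >= 100")
    nMask <- sum(maskVec)
    draws <- .withSeed(seed, {
      acc <- rep(1, nNull)
      for (vals in maskedMA)
        acc <- acc * (1 - vals[sample.int(nMask, nNull, replace = TRUE)])
      1 - acc
    })
    ## share the analytic method's bin lattice so both methods estimate the
    ## same discretised tail probability
    nb <- as.integer(ceiling(1 / binWidth)) + 1L
    nullBins <- pmin(as.integer(round(draws / binWidth)), nb - 1L)
    tailMass <- rev(cumsum(rev(tabulate(nullBins + 1L, nbins = nb)))) / nNull
    null <- list(method = method, values = sort(nullBins * binWidth),
                 tail = tailMass, binWidth = binWidth, nNull = nNull)
    obsBins <- pmin(as.integer(round(as.vector(ale) / binWidth)), nb - 1L)
    p <- tailMass[obsBins + 1L]
    pFloor <- 1 / nNull
  }
  p[!maskVec] <- 1
  pc <- pmin(pmax(p, pFloor), 1 - 1e-16)
  z <- qnorm(1 - pc)
  res <- new("AleResult", ale = ale, z = array(z, geometry@dim),
             p = array(p, geometry@dim), geometry = geometry)
  list(result = res, null = null)
}

#' Critical ALE value for a voxel-level p threshold
#'
#' The smallest ALE value c such that \code{P(null ALE > c)} does not exceed
#' \code{p}; used to threshold both the observed map and each permutation
#' map with strict \code{ale > c}.
#'
#' @param null a null representation from [aleVoxelSignificance()].
#' @param p voxel-level threshold (e.g. 0.001).
#' @return critical ALE value.
#' @export
aleCritical <- function(null, p) {
  if (null$method == "analytic_histogram") {
    b <- which(c(null$tail[-1], 0) < p)[1]
    (b - 1) * null$binWidth
  } else {
    m <- floor(p * null$nNull)
    if (m < 1) max(null$values)
    else null$values[null$nNull - m]
  }
}

## Observed clusters of a thresholded ALE map.
.observedClusters <- function(aleRes, cAle, formingP, clusterAlpha) {
  geom <- geometryOf(aleRes)
  supra <- aleValues(aleRes) > cAle & geom@mask
  labels <- array(cpp_label_components(as.vector(supra), geom@dim),
                  geom@dim)
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  zv <- aleZ(aleRes)
  av <- aleValues(aleRes)
  rows <- lapply(ids, function(id) {
    vox <- which(labels == id)
    ## peak by ALE value: z saturates at the null's resolution inside
    ## strong clusters, ALE does not
    peakVox <- vox[which.max(av[vox])]
    ijk <- arrayInd(peakVox, geom@dim) - 1L
    mm <- .voxelToMm(geom, ijk)
    data.frame(cluster_id = id, size_voxels = length(vox),
               peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
               peak_z_value = zv[peakVox])
  })
  clusters <- if (length(rows)) do.call(rbind, rows)
  else data.frame(cluster_id = integer(), size_voxels = integer(),
                  peak_x = numeric(), peak_y = numeric(),
                  peak_z = numeric(), peak_z_value = numeric())
  list(clusters = clusters, labels = labels)
}

#' Cluster-level family-wise-error inference on an ALE analysis
#'
#' Computes the ALE map of a database, derives the voxel-forming threshold
#' from the random-spatial-association null at \code{formingP}, extracts
#' 26-connected supra-threshold clusters, and calibrates cluster extent
#' against a permutation null in which every experiment's foci are relocated
#' to uniformly random in-mask voxel centres and the thresholded map is
#' recomputed. A cluster's FWE p is the fraction of permutations whose
#' maximum cluster size reaches its size; clusters with
#' \code{fwe_p < clusterAlpha} are retained as significant. An observed map
#' with no supra-threshold voxels yields an empty cluster set (not an
#' error).
#'
#' @param db a [FociDatabase-class].
#' @param geometry the analysis [VolumeGeometry-class].
#' @param formingP voxel-level cluster-forming threshold (default 0.001).
#' @param clusterAlpha cluster-level FWE level (default 0.05).
#' @param nPerm number of foci-relocation permutations (>= 100,
#'   default 500).
#' @param nullMethod,nNull,binWidth null options passed to
#'   [aleVoxelSignificance()].
#' @param seed RNG seed covering the null and the permutations.
#' @return list with \code{clusterSet} (a [ClusterSet-class]), \code{ale}
#'   (an [AleResult-class]), \code{aleThreshold}, and \code{nullMaxSizes}.
#' @export
clusterFwe <- function(db, geometry, formingP = 0.001,
                       clusterAlpha = 0.05, nPerm = 500L,
                       nullMethod = "monte_carlo", nNull = 5e4,
                       binWidth = 1e-5, seed = NULL) {
  if (nPerm < 100L) stop("nPerm must be at least 100")
  ex <- experimentTable(db)
  fo <- fociTable(db)
  ma <- .maVolumes(db, geometry)
  voxelSize <- abs(det(geometry@affine[1:3, 1:3]))^(1 / 3)

  .withSeed(seed, {
    sig <- aleVoxelSignificance(ma, geometry, method = nullMethod,
                                nNull = nNull, binWidth = binWidth,
                                seed = NULL)
    cAle <- aleCritical(sig$null, formingP)
    obs <- .observedClusters(sig$result, cAle, formingP, clusterAlpha)

    fwhms <- unique(ex$fwhm_mm)
    cubes <- lapply(fwhms, .kernelCube, voxelSize = voxelSize)
    kernelIdx <- match(ex$fwhm_mm, fwhms) - 1L
    nFoci <- as.integer(table(factor(fo$experiment_id,
                                     levels = ex$experiment_id)))
    maskVox <- which(as.vector(geometry@mask)) - 1L
    maxSizes <- cpp_perm_max_cluster(
      as.integer(nPerm), nFoci, kernelIdx,
      lapply(cubes, `[[`, "values"),
      vapply(cubes, `[[`, integer(1), "halfwidth"),
      maskVox, geometry@dim, cAle
    )

    clusters <- obs$clusters
    clusters$fwe_p <- vapply(clusters$size_voxels,
                             function(s) mean(maxSizes >= s), numeric(1))
    clusters$significant <- clusters$fwe_p < clusterAlpha
    cs <- new("ClusterSet", clusters = clusters, labels = obs$labels,
              formingP = formingP, clusterAlpha = clusterAlpha,
              geometry = geometry)
    list(clusterSet = cs, ale = sig$result, aleThreshold = cAle,
         nullMaxSizes = maxSizes)
  })
}

#' Significance mask of a cluster set
#'
#' @param clusterSet a [ClusterSet-class].
#' @return logical array: voxels in FWE-surviving clusters.
#' @export
significanceMask <- function(clusterSet) {
  tab <- clusterTable(clusterSet)
  sigIds <- tab$cluster_id[tab$significant]
  array(clusterLabels(clusterSet) %in% sigIds, geometryOf(clusterSet)@dim)
}

#' Minimum-statistic conjunction of thresholded maps
#'
#' Voxelwise logical intersection of FWE-surviving masks -- equivalent to
#' thresholding the minimum statistic at the common threshold -- returning
#' the 26-connected components of the conjunction with peak coordinates
#' (the voxel maximising the minimum statistic across maps when statistic
#' maps -- e.g. the ALE values, which unlike capped z do not saturate -- are
#' given, otherwise the component voxel nearest its centroid).
#'
#' @param maps list (length >= 2) of [ClusterSet-class] objects or logical
#'   arrays on a common geometry.
#' @param geometry required when \code{maps} are bare arrays.
#' @param statMaps optional list of statistic arrays matching \code{maps}
#'   (ALE or z volumes).
#' @return list with \code{mask} (logical array) and \code{components}
#'   (data.frame: \code{component_id}, \code{size_voxels}, \code{peak_x},
#'   \code{peak_y}, \code{peak_z}).
#' @export
minimumStatisticConjunction <- function(maps, geometry = NULL,
                                        statMaps = NULL) {
  if (length(maps) < 2L)
    stop("a conjunction requires at least two maps")
  masks <- lapply(maps, function(m) {
    if (is(m, "ClusterSet")) significanceMask(m) else m
  })
  if (is.null(geometry)) {
    cs <- Filter(function(m) is(m, "ClusterSet"), maps)
    if (!length(cs)) stop("supply the geometry for bare mask arrays")
    geometry <- geometryOf(cs[[1]])
  }
  dims <- geometry@dim
  for (m in masks)
    if (!identical(dim(m), dims)) stop("map geometries differ")
  conj <- Reduce(`&`, masks)
  labels <- array(cpp_label_components(as.vector(conj), dims), dims)
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  minStat <- if (!is.null(statMaps)) Reduce(pmin, statMaps) else NULL
  rows <- lapply(ids, function(id) {
    vox <- which(labels == id)
    ijk <- arrayInd(vox, dims) - 1L
    peakVox <- if (!is.null(minStat)) vox[which.max(minStat[vox])]
    else {
      ctr <- colMeans(ijk)
      vox[which.min(colSums((t(ijk) - ctr)^2))]
    }
    mm <- .voxelToMm(geometry, arrayInd(peakVox, dims) - 1L)
    data.frame(component_id = id, size_voxels = length(vox),
               peak_x = mm[1], peak_y = mm[2], peak_z = mm[3])
  })
  comps <- if (length(rows)) do.call(rbind, rows)
  else data.frame(component_id = integer(), size_voxels = integer(),
                  peak_x = numeric(), peak_y = numeric(),
                  peak_z = numeric())
  list(mask = conj, components = comps)
}

#' Seed co-activation analysis (MACM) for one seed
#'
#' Selects the \code{k} experiments nearest the seed and runs the full ALE
#' cluster-level inference on them.
#'
#' @param db a [FociDatabase-class].
#' @param peak seed mm coordinates.
#' @param k number of nearest experiments (default 100).
#' @param geometry analysis [VolumeGeometry-class].
#' @param ... passed to [clusterFwe()].
#' @return list with \code{selection} (from [selectNearestExperiments()])
#'   and the [clusterFwe()] fields.
#' @export
macmAnalysis <- function(db, peak, k = 100L,
                         geometry = makeGeometry(c(16, 16, 16), 4), ...) {
  sel <- selectNearestExperiments(db, peak, k)
  res <- clusterFwe(sel$db, geometry, ...)
  c(list(selection = sel), res)
}
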