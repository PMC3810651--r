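## Seed ROI definition (5-mm gray-matter spheres) and first-eigenvariate
## time-course extraction.

#' Gray-matter voxels within a seed sphere
#'
#' Membership rule: a voxel belongs to the seed if its centre lies within
#' \code{radius_mm} (inclusive) of the peak in mm, and its tissue label is
#' gray matter.
#'
#' @param seed one seed row (\code{x_mm}, \code{y_mm}, \code{z_mm},
#'   \code{radius_mm}, \code{name}).
#' @param geometry a [VolumeGeometry-class] (or a [BoldScan-class], whose
#'   geometry and tissue are used).
#' @param tissue 3D integer label array (1 = GM); required when
#'   \code{geometry} is a bare geometry.
#' @return integer vector of 1-based linear voxel indices.
#' @export
sphereVoxels <- function(seed, geometry, tissue = NULL) {
  if (is(geometry, "BoldScan")) {
    tissue <- tissueLabels(geometry)
    geometry <- scanGeometry(geometry)
  }
  if (is.null(tissue)) stop("tissue labels are required")
  peak <- c(seed$x_mm, seed$y_mm, seed$z_mm)
  v <- .mmToVoxel(geometry, peak)
  if (any(v < -0.5) || any(v > geometry@dim - 0.5))
    stop(sprintf("seed '%s' peak maps outside the volume", seed$name))
  mm <- voxelCenters(geometry)
  d2 <- (mm[, 1] - peak[1])^2 + (mm[, 2] - peak[2])^2 +
    (mm[, 3] - peak[3])^2
  idx <- which(d2 <= seed$radius_mm^2 & as.integer(tissue) == 1L)
  if (length(idx) == 0L)
    stop(sprintf("seed '%s' contains no gray-matter voxels", seed$name))
  idx
}

#' First eigenvariate of an ROI
#'
#' Dominant rank-1 temporal summary: each voxel series is mean-centred, the
#' first right singular vector of the voxels x time matrix is scaled by its
#' singular value over the square root of the voxel count, and the sign is
#' fixed so the mean spatial loading is non-negative (ties broken by the
#' first nonzero loading). Any fixed scaling is correlation-invariant
#' downstream; the sign convention is not cosmetic, because correlations are
#' sign-sensitive.
#'
#' @param roiSeries n_voxels x n_volumes numeric matrix.
#' @return numeric vector of length n_volumes.
#' @export
firstEigenvariate <- function(roiSeries) {
  roiSeries <- rbind(roiSeries)
  centered <- roiSeries - rowMeans(roiSeries)
  if (max(abs(centered)) == 0)
    stop("degenerate ROI: all voxel series are constant")
  sv <- svd(centered, nu = 1, nv = 1)
  loadings <- sv$u[, 1]
  s <- mean(loadings)
  if (s == 0) s <- loadings[which(loadings != 0)[1]]
  sign <- if (s >= 0) 1 else -1
  sign * sv$v[, 1] * sv$d[1] / sqrt(nrow(roiSeries))
}

#' Extract all seed eigenvariate time courses from a scan
#'
#' @param scan a (preprocessed) [BoldScan-class].
#' @param seeds seed data.frame in grid coordinates.
#' @return n_seeds x n_volumes matrix with seed names as row names and a
#'   \code{subjectId} attribute; row order follows the seed table.
#' @export
extractSeedTimeseries <- function(scan, seeds) {
  d <- dim(scanData(scan))
  mat <- matrix(scanData(scan), prod(d[1:3]), d[4])
  out <- matrix(NA_real_, nrow(seeds), d[4],
                dimnames = list(seeds$name, NULL))
  for (s in seq_len(nrow(seeds))) {
    idx <- sphereVoxels(seeds[s, ], scan)
    out[s, ] <- firstEigenvariate(mat[idx, , drop = FALSE])
  }
  structure(out, subjectId = subjectId(scan))
}
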