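## S4 containers for the pipeline's central objects.

#' VolumeGeometry: a 3D sampling grid with a voxel-to-mm affine and mask
#'
#' The affine maps zero-based voxel indices \code{(i,j,k,1)} to mm
#' coordinates; voxel centres are \code{affine \%*\% c(i,j,k,1)}. The mask
#' marks in-analysis voxels (for meta-analysis grids, the whole box by
#' default).
#'
#' @slot dim integer(3), grid extent in voxels.
#' @slot affine 4x4 numeric voxel-to-mm map (invertible).
#' @slot mask logical array with dimension \code{dim}.
#' @seealso [makeGeometry()]
#' @export
setClass("VolumeGeometry", representation(
  dim = "integer", affine = "matrix", mask = "array"
))

setValidity("VolumeGeometry", function(object) {
  msg <- character()
  if (length(object@dim) != 3L || any(object@dim < 1L))
    msg <- c(msg, "dim must be three positive integers")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be 4x4")
  else if (abs(det(object@affine)) < 1e-12)
    msg <- c(msg, "affine must be invertible")
  if (!is.logical(object@mask) || !identical(dim(object@mask), object@dim))
    msg <- c(msg, "mask must be a logical array of dimension 'dim'")
  if (length(msg)) msg else TRUE
})

#' BoldScan: one subject's 4D BOLD volume with geometry and tissue labels
#'
#' @slot data 4D numeric array (x, y, z, t).
#' @slot affine 4x4 voxel-to-mm map (zero-based voxel indices).
#' @slot tr repetition time in seconds.
#' @slot tissue 3D integer array aligned with \code{data}
#'   (0 = background, 1 = GM, 2 = WM, 3 = CSF).
#' @slot subjectId subject identifier.
#' @export
setClass("BoldScan", representation(
  data = "array", affine = "matrix", tr = "numeric",
  tissue = "array", subjectId = "character"
))

setValidity("BoldScan", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "data must be a 4D array")
  if (!all(dim(object@affine) == c(4L, 4L)) ||
      abs(det(object@affine)) < 1e-12)
    msg <- c(msg, "affine must be an invertible 4x4 matrix")
  if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
    msg <- c(msg, "tr must be a single positive number")
  if (length(dim(object@tissue)) != 3L ||
      !identical(dim(object@tissue), dim(object@data)[1:3]))
    msg <- c(msg, "tissue must match the spatial dimensions of data")
  if (length(msg)) msg else TRUE
})

#' NetworkTruth: generative ground truth for region coupling vs age
#'
#' Population coupling is linear in Fisher-Z:
#' \code{z_ij(age) = baseZ_ij + slopeZ_ij * (age - referenceAge)}; the
#' correlation matrix at an age is the inverse Fisher transform, repaired to
#' the nearest positive-semidefinite correlation matrix if needed.
#'
#' @slot regionNames ordered region labels.
#' @slot baseZ symmetric matrix of population Fisher-Z at the reference age
#'   (diagonal 0 by convention).
#' @slot slopeZ symmetric matrix of Fisher-Z change per year (diagonal 0).
#' @slot referenceAge years.
#' @slot subjectSd symmetric matrix of between-subject s.d. of the
#'   subject-level Fisher-Z offsets (diagonal 0); 0 disables inter-subject
#'   variability.
#' @seealso [couplingAtAge()], [calibrateTruth()]
#' @export
setClass("NetworkTruth", representation(
  regionNames = "character", baseZ = "matrix", slopeZ = "matrix",
  referenceAge = "numeric", subjectSd = "matrix"
))

.checkSymZero <- function(m, n, what) {
  msg <- character()
  if (!is.numeric(m) || !all(dim(m) == c(n, n)))
    msg <- c(msg, sprintf("%s must be %dx%d numeric", what, n, n))
  else {
    if (max(abs(m - t(m))) > 1e-8)
      msg <- c(msg, sprintf("%s must be symmetric", what))
    if (max(abs(diag(m))) > 1e-12)
      msg <- c(msg, sprintf("diagonal of %s must be 0", what))
  }
  msg
}

setValidity("NetworkTruth", function(object) {
  n <- length(object@regionNames)
  msg <- character()
  if (n < 2L) msg <- c(msg, "need at least two regions")
  if (anyDuplicated(object@regionNames))
    msg <- c(msg, "region names must be unique")
  msg <- c(msg, .checkSymZero(object@baseZ, n, "baseZ"))
  msg <- c(msg, .checkSymZero(object@slopeZ, n, "slopeZ"))
  msg <- c(msg, .checkSymZero(object@subjectSd, n, "subjectSd"))
  if (length(object@subjectSd) && any(object@subjectSd < 0))
    msg <- c(msg, "subjectSd must be non-negative")
  if (length(object@referenceAge) != 1L || !is.finite(object@referenceAge))
    msg <- c(msg, "referenceAge must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' NoiseSpec: confound and noise structure planted into synthetic scans
#'
#' The planted components mirror the nuisance sources the preprocessing
#' stage is designed to remove: slow scanner drift (below the analysis band),
#' a cardiac/respiratory-like sinusoid (above the band), voxel noise and
#' leakage of a motion regressor into voxel signals.
#'
#' @slot roiNoiseSd independent noise s.d. added to seed-sphere voxels.
#' @slot backgroundNoiseSd noise s.d. for non-seed brain voxels.
#' @slot driftAmplitude,driftFrequency slow drift sinusoid; frequency in Hz,
#'   must lie below 0.01 Hz.
#' @slot physioAmplitude,physioFrequency physiological sinusoid; frequency in
#'   Hz, must lie above 0.08 Hz and below Nyquist for the site's TR.
#' @slot motionCoupling scale of the planted motion-regressor leakage into
#'   seed-sphere voxel signals.
#' @slot motionStepSd per-frame step s.d. (mm or degrees) of the six
#'   motion random walks.
#' @export
setClass("NoiseSpec", representation(
  roiNoiseSd = "numeric", backgroundNoiseSd = "numeric",
  driftAmplitude = "numeric", driftFrequency = "numeric",
  physioAmplitude = "numeric", physioFrequency = "numeric",
  motionCoupling = "numeric", motionStepSd = "numeric"
))

setValidity("NoiseSpec", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  for (s in slotNames(object))
    if (!one(slot(object, s)) || slot(object, s) < 0)
      msg <- c(msg, sprintf("%s must be a single non-negative number", s))
  if (length(msg) == 0L) {
    if (object@driftFrequency >= 0.01)
      msg <- c(msg, "driftFrequency must be below 0.01 Hz")
    if (object@physioFrequency <= 0.08)
      msg <- c(msg, "physioFrequency must be above 0.08 Hz")
  }
  if (length(msg)) msg else TRUE
})

#' FociDatabase: a coordinate meta-analysis database
#'
#' @slot experiments data.frame with columns \code{experiment_id},
#'   \code{n_subjects}, \code{fwhm_mm}.
#' @slot foci data.frame with columns \code{experiment_id}, \code{x_mm},
#'   \code{y_mm}, \code{z_mm}; every experiment has at least one focus.
#' @export
setClass("FociDatabase", representation(
  experiments = "data.frame", foci = "data.frame"
))

setValidity("FociDatabase", function(object) {
  msg <- character()
  ecols <- c("experiment_id", "n_subjects", "fwhm_mm")
  fcols <- c("experiment_id", "x_mm", "y_mm", "z_mm")
  if (!all(ecols %in% names(object@experiments)))
    msg <- c(msg, "experiments needs columns experiment_id, n_subjects, fwhm_mm")
  if (!all(fcols %in% names(object@foci)))
    msg <- c(msg, "foci needs columns experiment_id, x_mm, y_mm, z_mm")
  if (length(msg) == 0L) {
    if (anyDuplicated(object@experiments$experiment_id))
      msg <- c(msg, "experiment ids must be unique")
    if (any(object@experiments$n_subjects <= 0))
      msg <- c(msg, "n_subjects must be positive")
    if (any(object@experiments$fwhm_mm <= 0))
      msg <- c(msg, "fwhm_mm must be positive")
    if (!all(object@experiments$experiment_id %in% object@foci$experiment_id))
      msg <- c(msg, "every experiment must report at least one focus")
    if (!all(object@foci$experiment_id %in% object@experiments$experiment_id))
      msg <- c(msg, "foci reference unknown experiments")
  }
  if (length(msg)) msg else TRUE
})

#' ConnectivityResult: one subject's seed-network correlation matrices
#'
#' @slot subjectId subject identifier.
#' @slot r symmetric Pearson correlation matrix, unit diagonal.
#' @slot z Fisher-Z transform of \code{r} off-diagonal (diagonal 0 by
#'   convention; it carries no information).
#' @slot regionNames seed labels in canonical order.
#' @export
setClass("ConnectivityResult", representation(
  subjectId = "character", r = "matrix", z = "matrix",
  regionNames = "character"
))

setValidity("ConnectivityResult", function(object) {
  n <- length(object@regionNames)
  msg <- character()
  if (!all(dim(object@r) == c(n, n)) || !all(dim(object@z) == c(n, n)))
    msg <- c(msg, "r and z must be square over the regions")
  else {
    if (max(abs(object@r - t(object@r))) > 1e-10)
      msg <- c(msg, "r must be symmetric")
    if (max(abs(diag(object@r) - 1)) > 1e-10)
      msg <- c(msg, "diag(r) must be 1")
    off <- object@r[upper.tri(object@r)]
    if (any(abs(off) >= 1))
      msg <- c(msg, "off-diagonal correlations must lie in (-1, 1)")
    else if (max(abs(object@z[upper.tri(object@z)] - atanh(off))) > 1e-8)
      msg <- c(msg, "z must equal atanh(r) off-diagonal")
  }
  if (length(msg)) msg else TRUE
})

#' AleResult: voxelwise ALE statistic with significance fields
#'
#' @slot ale 3D array of ALE values in [0, 1] (1 - prod(1 - MA) over
#'   experiments), 0 outside the mask.
#' @slot z 3D array of standard-normal quantiles of 1 - p (capped at the
#'   null's resolution).
#' @slot p 3D array of voxelwise p-values under the
#'   random-spatial-association null (1 outside the mask).
#' @slot geometry the meta-analysis [VolumeGeometry-class].
#' @export
setClass("AleResult", representation(
  ale = "array", z = "array", p = "array", geometry = "VolumeGeometry"
))

setValidity("AleResult", function(object) {
  msg <- character()
  d <- object@geometry@dim
  for (s in c("ale", "z", "p"))
    if (!identical(dim(slot(object, s)), d))
      msg <- c(msg, sprintf("%s must match the geometry dimensions", s))
  if (length(msg) == 0L) {
    if (min(object@ale) < 0 || max(object@ale) > 1)
      msg <- c(msg, "ale values must lie in [0, 1]")
    if (any(!is.finite(object@z[object@geometry@mask])))
      msg <- c(msg, "z must be finite on the mask")
  }
  if (length(msg)) msg else TRUE
})

#' ClusterSet: FWE-assessed clusters of a thresholded statistic map
#'
#' @slot clusters data.frame with one row per 26-connected supra-threshold
#'   cluster: \code{cluster_id}, \code{size_voxels}, \code{peak_x},
#'   \code{peak_y}, \code{peak_z} (mm), \code{peak_z_value}, \code{fwe_p},
#'   \code{significant}.
#' @slot labels 3D integer array of cluster labels (0 = sub-threshold).
#' @slot formingP voxel-level cluster-forming p threshold.
#' @slot clusterAlpha cluster-level FWE alpha.
#' @slot geometry the [VolumeGeometry-class] of the map.
#' @export
setClass("ClusterSet", representation(
  clusters = "data.frame", labels = "array", formingP = "numeric",
  clusterAlpha = "numeric", geometry = "VolumeGeometry"
))

setValidity("ClusterSet", function(object) {
  msg <- character()
  if (!identical(dim(object@labels), object@geometry@dim))
    msg <- c(msg, "labels must match the geometry dimensions")
  if (nrow(object@clusters) && any(object@clusters$size_voxels <= 0))
    msg <- c(msg, "cluster sizes must be positive")
  if (length(msg)) msg else TRUE
})
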