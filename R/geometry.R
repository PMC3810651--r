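#' Construct a volume geometry
#'
#' Builds an RAS+ grid of \code{dim} voxels at \code{voxelSize} mm isotropic
#' spacing, centred on the mm origin (the central voxel index maps to 0 mm on
#' every axis). The default 32x32x32 grid at 3 mm spans +-46.5 mm, a
#' desk-scale stand-in for a whole-brain field of view that keeps mm geometry
#' meaningful.
#'
#' @param dim integer(3) grid extent in voxels.
#' @param voxelSize voxel edge length in mm (scalar, isotropic).
#' @param mask optional logical array (default: all voxels in-analysis).
#' @return a [VolumeGeometry-class].
#' @examples
#' g <- makeGeometry(c(16, 16, 16), 4)
#' range(voxelCenters(g))
#' @export
makeGeometry <- function(dim = c(32L, 32L, 32L), voxelSize = 3,
                         mask = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L), voxelSize > 0)
  aff <- diag(c(rep(voxelSize, 3), 1))
  aff[1:3, 4] <- -voxelSize * (dim - 1) / 2
  if (is.null(mask)) mask <- array(TRUE, dim)
  new("VolumeGeometry", dim = dim, affine = aff, mask = mask)
}

## mm -> fractional zero-based voxel indices
.mmToVoxel <- function(geometry, mm) {
  mm <- rbind(mm)
  v <- cbind(mm, 1) %*% t(solve(geometry@affine))
  v[, 1:3, drop = FALSE]
}

## zero-based voxel indices -> mm centres
.voxelToMm <- function(geometry, ijk) {
  ijk <- rbind(ijk)
  mm <- cbind(ijk, 1) %*% t(geometry@affine)
  mm[, 1:3, drop = FALSE]
}

.linearIndex <- function(dim, ijk) {
  ## zero-based ijk matrix -> 1-based linear index
  as.integer(1 + ijk[, 1] + dim[1] * (ijk[, 2] + dim[2] * ijk[, 3]))
}

#' Geometry of a BOLD scan
#'
#' @param scan a [BoldScan-class].
#' @param mask optional logical array; defaults to all brain
#'   (tissue label > 0).
#' @return a [VolumeGeometry-class] sharing the scan's affine.
#' @export
scanGeometry <- function(scan, mask = NULL) {
  if (is.null(mask)) mask <- tissueLabels(scan) > 0L
  new("VolumeGeometry", dim = dim(scanData(scan))[1:3],
      affine = scanAffine(scan), mask = mask)
}
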