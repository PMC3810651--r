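## Accessor generics and show methods. Slots are never accessed directly by
## user code; these are the supported surface.

#' Accessor generics
#'
#' Generic accessors for the package's S4 containers; see the class pages
#' ([BoldScan-class], [NetworkTruth-class], [ConnectivityResult-class],
#' [FociDatabase-class], [AleResult-class], [ClusterSet-class],
#' [VolumeGeometry-class]) for the methods.
#'
#' @param x an object of one of the package's S4 classes.
#' @return the accessed component; see the class documentation.
#' @name accessors
#' @aliases regionNames baseCoupling ageSlope referenceAge subjectSd
#'   scanData scanAffine scanTR tissueLabels subjectId corMatrix zMatrix
#'   experimentTable fociTable aleValues aleZ aleP geometryOf clusterTable
#'   clusterLabels gridMask voxelCenters
NULL

#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))
#' @export
setGeneric("baseCoupling", function(x) standardGeneric("baseCoupling"))
#' @export
setGeneric("ageSlope", function(x) standardGeneric("ageSlope"))
#' @export
setGeneric("referenceAge", function(x) standardGeneric("referenceAge"))
#' @export
setGeneric("subjectSd", function(x) standardGeneric("subjectSd"))
#' @export
setGeneric("scanData", function(x) standardGeneric("scanData"))
#' @export
setGeneric("scanAffine", function(x) standardGeneric("scanAffine"))
#' @export
setGeneric("scanTR", function(x) standardGeneric("scanTR"))
#' @export
setGeneric("tissueLabels", function(x) standardGeneric("tissueLabels"))
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @export
setGeneric("corMatrix", function(x) standardGeneric("corMatrix"))
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))
#' @export
setGeneric("experimentTable", function(x) standardGeneric("experimentTable"))
#' @export
setGeneric("fociTable", function(x) standardGeneric("fociTable"))
#' @export
setGeneric("aleValues", function(x) standardGeneric("aleValues"))
#' @export
setGeneric("aleZ", function(x) standardGeneric("aleZ"))
#' @export
setGeneric("aleP", function(x) standardGeneric("aleP"))
#' @export
setGeneric("geometryOf", function(x) standardGeneric("geometryOf"))
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @export
setGeneric("gridMask", function(x) standardGeneric("gridMask"))
#' @export
setGeneric("voxelCenters", function(x) standardGeneric("voxelCenters"))

#' @describeIn NetworkTruth region labels in canonical order
#' @param x an object of the documented class
#' @export
setMethod("regionNames", "NetworkTruth", function(x) x@regionNames)
#' @describeIn NetworkTruth population Fisher-Z matrix at the reference age
#' @export
setMethod("baseCoupling", "NetworkTruth", function(x) x@baseZ)
#' @describeIn NetworkTruth Fisher-Z change per year
#' @export
setMethod("ageSlope", "NetworkTruth", function(x) x@slopeZ)
#' @describeIn NetworkTruth reference age in years
#' @export
setMethod("referenceAge", "NetworkTruth", function(x) x@referenceAge)
#' @describeIn NetworkTruth between-subject Fisher-Z s.d. matrix
#' @export
setMethod("subjectSd", "NetworkTruth", function(x) x@subjectSd)

#' @describeIn BoldScan the 4D intensity array
#' @param x an object of the documented class
#' @export
setMethod("scanData", "BoldScan", function(x) x@data)
#' @describeIn BoldScan the 4x4 voxel-to-mm affine
#' @export
setMethod("scanAffine", "BoldScan", function(x) x@affine)
#' @describeIn BoldScan repetition time in seconds
#' @export
setMethod("scanTR", "BoldScan", function(x) x@tr)
#' @describeIn BoldScan the 3D tissue-label array
#' @export
setMethod("tissueLabels", "BoldScan", function(x) x@tissue)
#' @describeIn BoldScan subject identifier
#' @export
setMethod("subjectId", "BoldScan", function(x) x@subjectId)

#' @describeIn ConnectivityResult subject identifier
#' @param x an object of the documented class
#' @export
setMethod("subjectId", "ConnectivityResult", function(x) x@subjectId)
#' @describeIn ConnectivityResult Pearson correlation matrix
#' @export
setMethod("corMatrix", "ConnectivityResult", function(x) x@r)
#' @describeIn ConnectivityResult Fisher-Z matrix (diagonal 0)
#' @export
setMethod("zMatrix", "ConnectivityResult", function(x) x@z)
#' @describeIn ConnectivityResult seed labels
#' @export
setMethod("regionNames", "ConnectivityResult", function(x) x@regionNames)

#' @describeIn FociDatabase one row per experiment
#' @param x an object of the documented class
#' @export
setMethod("experimentTable", "FociDatabase", function(x) x@experiments)
#' @describeIn FociDatabase one row per reported focus
#' @export
setMethod("fociTable", "FociDatabase", function(x) x@foci)

#' @describeIn AleResult the ALE statistic array
#' @param x an object of the documented class
#' @export
setMethod("aleValues", "AleResult", function(x) x@ale)
#' @describeIn AleResult the Z-score array
#' @export
setMethod("aleZ", "AleResult", function(x) x@z)
#' @describeIn AleResult the voxel p-value array
#' @export
setMethod("aleP", "AleResult", function(x) x@p)
#' @describeIn AleResult the meta-analysis geometry
#' @export
setMethod("geometryOf", "AleResult", function(x) x@geometry)

#' @describeIn ClusterSet per-cluster statistics
#' @param x an object of the documented class
#' @export
setMethod("clusterTable", "ClusterSet", function(x) x@clusters)
#' @describeIn ClusterSet 3D integer label array
#' @export
setMethod("clusterLabels", "ClusterSet", function(x) x@labels)
#' @describeIn ClusterSet the map geometry
#' @export
setMethod("geometryOf", "ClusterSet", function(x) x@geometry)

#' @describeIn VolumeGeometry the in-analysis mask
#' @param x an object of the documented class
#' @export
setMethod("gridMask", "VolumeGeometry", function(x) x@mask)
#' @describeIn VolumeGeometry the voxel-to-mm affine
#' @export
setMethod("scanAffine", "VolumeGeometry", function(x) x@affine)

#' @describeIn VolumeGeometry grid extent in voxels
#' @export
setMethod("dim", "VolumeGeometry", function(x) x@dim)

#' @describeIn VolumeGeometry n_voxels x 3 matrix of voxel-centre mm
#'   coordinates in array order
#' @export
setMethod("voxelCenters", "VolumeGeometry", function(x) {
  d <- x@dim
  idx <- as.matrix(expand.grid(i = 0:(d[1] - 1L), j = 0:(d[2] - 1L),
                               k = 0:(d[3] - 1L)))
  mm <- cbind(idx, 1) %*% t(x@affine)
  mm[, 1:3, drop = FALSE]
})

setMethod("show", "VolumeGeometry", function(object) {
  vs <- sqrt(colSums(object@affine[1:3, 1:3]^2))
  cat(sprintf("VolumeGeometry: %s voxels, voxel size %s mm, %d in mask\n",
              paste(object@dim, collapse = "x"),
              paste(signif(vs, 3), collapse = "x"),
              sum(object@mask)))
})

setMethod("show", "BoldScan", function(object) {
  d <- dim(object@data)
  cat(sprintf("BoldScan '%s': %dx%dx%d voxels, %d volumes, TR %.3g s\n",
              object@subjectId, d[1], d[2], d[3], d[4], object@tr))
  tl <- tabulate(object@tissue + 1L, nbins = 4L)
  cat(sprintf("  tissue: %d GM, %d WM, %d CSF, %d background\n",
              tl[2], tl[3], tl[4], tl[1]))
})

setMethod("show", "NetworkTruth", function(object) {
  cat(sprintf("NetworkTruth: %d regions, reference age %.1f y\n",
              length(object@regionNames), object@referenceAge))
  cat(sprintf("  |baseZ| up to %.3f, |slopeZ| up to %.2g /y\n",
              max(abs(object@baseZ)), max(abs(object@slopeZ))))
})

setMethod("show", "NoiseSpec", function(object) {
  cat(sprintf(paste0("NoiseSpec: roi sd %.3g, background sd %.3g, drift ",
                     "%.3g @ %.3g Hz,\n  physio %.3g @ %.3g Hz, motion ",
                     "coupling %.3g, motion step sd %.3g\n"),
              object@roiNoiseSd, object@backgroundNoiseSd,
              object@driftAmplitude, object@driftFrequency,
              object@physioAmplitude, object@physioFrequency,
              object@motionCoupling, object@motionStepSd))
})

setMethod("show", "FociDatabase", function(object) {
  cat(sprintf("FociDatabase: %d experiments, %d foci\n",
              nrow(object@experiments), nrow(object@foci)))
})

setMethod("show", "ConnectivityResult", function(object) {
  n <- length(object@regionNames)
  cat(sprintf("ConnectivityResult '%s': %d regions, %d connections\n",
              object@subjectId, n, n * (n - 1L) / 2L))
})

setMethod("show", "AleResult", function(object) {
  m <- object@geometry@mask
  cat(sprintf("AleResult: max ALE %.4g, min voxel p %.3g on %d mask voxels\n",
              max(object@ale), min(object@p[m]), sum(m)))
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet: %d clusters (%d FWE-significant at alpha %.3g)\n",
              nrow(object@clusters), sum(object@clusters$significant),
              object@clusterAlpha))
})
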