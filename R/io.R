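## NIfTI-1 and TSV interchange.

#' Write a BOLD scan as NIfTI-1
#'
#' Writes the 4D intensities and the 3D tissue-label volume as NIfTI-1 with
#' the scan's affine in the sform (code 2) and the TR in the temporal
#' pixdim.
#'
#' @param scan a [BoldScan-class].
#' @param boldPath output path for the 4D volume (.nii / .nii.gz).
#' @param tissuePath optional output path for the tissue labels.
#' @return invisibly, \code{boldPath}.
#' @export
writeBoldScan <- function(scan, boldPath, tissuePath = NULL) {
  aff <- structure(scanAffine(scan), code = 2L)
  vs <- sqrt(colSums(scanAffine(scan)[1:3, 1:3]^2))
  img <- RNifti::asNifti(scanData(scan),
                         reference = list(pixdim = c(-1, vs, scanTR(scan),
                                                     0, 0, 0)),
                         datatype = "float")
  img <- RNifti::`sform<-`(img, aff)
  RNifti::writeNifti(img, boldPath)
  if (!is.null(tissuePath)) {
    timg <- RNifti::asNifti(array(as.integer(tissueLabels(scan)),
                                  dim(tissueLabels(scan))),
                            datatype = "int16")
    timg <- RNifti::`sform<-`(timg, aff)
    RNifti::writeNifti(timg, tissuePath)
  }
  invisible(boldPath)
}

#' Read a BOLD scan from NIfTI-1
#'
#' @param boldPath 4D NIfTI path.
#' @param tissuePath tissue-label NIfTI path.
#' @param tr repetition time in seconds; if NULL, taken from the temporal
#'   pixdim of the file.
#' @param subjectId subject identifier (default: file name).
#' @return a [BoldScan-class].
#' @export
readBoldScan <- function(boldPath, tissuePath, tr = NULL,
                         subjectId = NULL) {
  img <- RNifti::readNifti(boldPath)
  timg <- RNifti::readNifti(tissuePath)
  if (is.null(tr)) {
    pd <- RNifti::pixdim(img)
    if (length(pd) < 4 || pd[4] <= 0)
      stop("TR not recoverable from the file; pass tr")
    tr <- pd[4]
  }
  if (is.null(subjectId))
    subjectId <- sub("\\.nii(\\.gz)?$", "", basename(boldPath))
  new("BoldScan", data = array(as.numeric(img), dim(img)),
      affine = structure(unclass(RNifti::xform(img)),
                         imagedim = NULL, code = NULL),
      tr = as.numeric(tr),
      tissue = array(as.integer(timg), dim(timg)),
      subjectId = subjectId)
}

#' Write a 3D statistic volume as NIfTI-1
#'
#' @param values 3D numeric/logical array.
#' @param geometry the [VolumeGeometry-class] of the array.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeVolume <- function(values, geometry, path) {
  img <- RNifti::asNifti(array(as.numeric(values), geometry@dim),
                         datatype = "float")
  img <- RNifti::`sform<-`(img, structure(geometry@affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write and read tab-separated tables
#'
#' Thin wrappers fixing the package's TSV conventions (tab separator, no
#' quoting, no row names).
#'
#' @param x data.frame.
#' @param path file path.
#' @return \code{readTsv} returns a data.frame; \code{writeTsv} returns
#'   \code{path} invisibly.
#' @export
writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Read a foci database from TSV
#'
#' Expects columns \code{experiment_id}, \code{n_subjects}, \code{x_mm},
#' \code{y_mm}, \code{z_mm} and optionally \code{fwhm_mm} (defaulting to
#' [fwhmOfN()] of the sample size).
#'
#' @param path TSV path.
#' @return a [FociDatabase-class].
#' @export
readFociDatabase <- function(path) {
  tab <- readTsv(path)
  ex <- unique(tab[, c("experiment_id", "n_subjects"),
                   drop = FALSE])
  ex$fwhm_mm <- if ("fwhm_mm" %in% names(tab))
    tab$fwhm_mm[match(ex$experiment_id, tab$experiment_id)]
  else fwhmOfN(ex$n_subjects)
  rownames(ex) <- NULL
  new("FociDatabase", experiments = ex,
      foci = tab[, c("experiment_id", "x_mm", "y_mm", "z_mm")])
}

#' Write a foci database to TSV
#'
#' @param db a [FociDatabase-class].
#' @param path TSV path.
#' @return invisibly, \code{path}.
#' @export
writeFociDatabase <- function(db, path) {
  ex <- experimentTable(db)
  fo <- fociTable(db)
  m <- match(fo$experiment_id, ex$experiment_id)
  writeTsv(data.frame(experiment_id = fo$experiment_id,
                      n_subjects = ex$n_subjects[m],
                      x_mm = fo$x_mm, y_mm = fo$y_mm, z_mm = fo$z_mm,
                      fwhm_mm = ex$fwhm_mm[m]), path)
}
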