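## Nuisance regression (31-column first/second-order confound design) and
## boxcar band-pass filtering, applied in that order.

#' Temporal derivative of regressor columns
#'
#' Backward difference with the first row set to 0, the convention used for
#' realignment-parameter derivatives.
#'
#' @param series n_volumes x k numeric matrix (vectors are treated as one
#'   column).
#' @return matrix of the same shape.
#' @examples
#' temporalDerivative(cbind(c(0, 1, 3)))  # 0, 1, 2
#' @export
temporalDerivative <- function(series) {
  series <- as.matrix(series)
  if (nrow(series) < 2L)
    stop("need at least two time points for a temporal derivative")
  rbind(matrix(0, 1L, ncol(series)), diff(series))
}

#' Per-frame tissue-mean signals
#'
#' Averages the scan across voxels of each tissue class (GM, WM, CSF) per
#' time point, from the raw (pre-regression) scan: tissue means are listed
#' jointly with the motion terms among the nuisance variables, so all are
#' extracted from the same unprocessed data.
#'
#' @param scan a [BoldScan-class].
#' @return n_volumes x 3 matrix with columns \code{gm}, \code{wm},
#'   \code{csf}.
#' @export
tissueMeans <- function(scan) {
  d <- dim(scanData(scan))
  mat <- matrix(scanData(scan), prod(d[1:3]), d[4])
  lab <- as.integer(tissueLabels(scan))
  out <- matrix(NA_real_, d[4], 3, dimnames = list(NULL,
                c("gm", "wm", "csf")))
  for (cls in 1:3) {
    idx <- which(lab == cls)
    if (length(idx) == 0L)
      stop(sprintf("tissue class '%s' has no voxels",
                   c("GM", "WM", "CSF")[cls]))
    out[, cls] <- colMeans(mat[idx, , drop = FALSE])
  }
  out
}

#' Build the 31-column nuisance design
#'
#' First-order terms are the fifteen inputs (six motion parameters, their
#' six temporal derivatives, three tissue means), each mean-centred.
#' Second-order terms are the elementwise squares of the centred first-order
#' terms, then mean-centred (centring before squaring decorrelates the
#' square from the mean). An intercept completes the 31 columns. Column
#' order: \code{intercept}, 15 first-order, 15 matching \code{*_sq}.
#'
#' @param motion n x 6 motion-parameter matrix.
#' @param motionDeriv n x 6 derivative matrix (default
#'   \code{temporalDerivative(motion)}).
#' @param tissue n x 3 tissue-mean matrix.
#' @return list with \code{matrix} (n x 31), \code{columnNames}, and
#'   \code{constantColumns} (names of non-intercept columns that were
#'   constant in the input and are flagged rather than dropped).
#' @export
buildConfoundDesign <- function(motion, motionDeriv = NULL, tissue) {
  motion <- as.matrix(motion)
  if (is.null(motionDeriv)) motionDeriv <- temporalDerivative(motion)
  motionDeriv <- as.matrix(motionDeriv)
  tissue <- as.matrix(tissue)
  n <- nrow(motion)
  if (nrow(motionDeriv) != n || nrow(tissue) != n)
    stop("motion, motionDeriv and tissue must have equal row counts")
  stopifnot(ncol(motion) == 6L, ncol(motionDeriv) == 6L, ncol(tissue) == 3L)

  first <- cbind(motion, motionDeriv, tissue)
  baseNames <- c(paste0("mot", 1:6), paste0("dmot", 1:6),
                 c("gm", "wm", "csf"))
  firstC <- scale(first, center = TRUE, scale = FALSE)
  second <- firstC^2
  secondC <- scale(second, center = TRUE, scale = FALSE)
  X <- cbind(1, firstC, secondC)
  cn <- c("intercept", baseNames, paste0(baseNames, "_sq"))
  colnames(X) <- cn
  constant <- cn[-1][apply(X[, -1, drop = FALSE], 2,
                           function(col) all(abs(col) < 1e-12))]
  list(matrix = X, columnNames = cn, constantColumns = constant)
}

#' Remove nuisance variance by least squares
#'
#' Projects each series onto the orthogonal complement of the design's
#' column space. Rank-deficient designs (e.g. flagged constant columns) are
#' handled by pivoted QR; the residuals of the projection are unique even
#' when the coefficients are not.
#'
#' @param series voxels x n_volumes numeric matrix (rows are series).
#' @param design a design list from [buildConfoundDesign()] or a bare
#'   numeric matrix with n_volumes rows.
#' @return residual matrix of the same shape; every residual row is
#'   orthogonal to every design column.
#' @export
regressConfounds <- function(series, design) {
  X <- if (is.list(design)) design$matrix else as.matrix(design)
  series <- as.matrix(series)
  if (ncol(series) != nrow(X))
    stop("design rows must equal the number of time points")
  qrX <- qr(X)
  if (nrow(X) <= qrX$rank)
    stop("model is unestimable: n_volumes must exceed the design rank")
  t(qr.resid(qrX, t(series)))
}

#' Ideal (boxcar) band-pass filter
#'
#' Discrete-Fourier-domain boxcar: bins whose frequency lies in
#' \code{[low, high]} (inclusive) are retained, all others -- including the
#' DC bin -- are zeroed, and the series is inverse-transformed. The filter
#' is exactly idempotent and annihilates on-bin out-of-band sinusoids to
#' numerical precision; off-bin leakage is a property of the finite window
#' and is accepted.
#'
#' @param series voxels x n_volumes matrix (rows are series) or a vector.
#' @param tr repetition time in seconds.
#' @param low,high band edges in Hz (defaults 0.01 and 0.08).
#' @return filtered matrix of the same shape; rows have (numerically) zero
#'   mean.
#' @export
bandpassFilter <- function(series, tr, low = 0.01, high = 0.08) {
  vec <- is.null(dim(series))
  series <- rbind(series)
  if (vec) series <- matrix(series, 1L)
  n <- ncol(series)
  nyquist <- 1 / (2 * tr)
  if (low < 0 || low >= high)
    stop("need 0 <= low < high")
  if (high > nyquist)
    stop(sprintf("high edge %.4g Hz exceeds Nyquist %.4g Hz at TR %.4g s",
                 high, nyquist, tr))
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) / (n * tr)
  keep <- freq >= low & freq <= high & k != 0L
  X <- mvfft(t(series))
  X[!keep, ] <- 0
  out <- t(Re(mvfft(X, inverse = TRUE)) / n)
  if (vec) drop(out) else out
}

#' Preprocess a BOLD scan
#'
#' The full per-subject nuisance pipeline in the mandated order: build the
#' 31-column confound design from the motion table, its temporal derivatives
#' and the raw-scan tissue means; regress it from every brain voxel; then
#' band-pass filter the residuals.
#'
#' @param scan a [BoldScan-class].
#' @param motion data.frame/matrix with the six motion parameters (a
#'   \code{t} column, if present, is dropped).
#' @param low,high band edges in Hz.
#' @param includeTissue include the tissue-mean regressor family
#'   (default TRUE, the full 31-column design). Gray-matter-mean regression
#'   projects out whatever signal component is shared with the GM average
#'   and can induce or attenuate anti-correlations; setting FALSE restricts
#'   the design to the motion family (19 columns) for sensitivity analyses
#'   of that choice.
#' @return list with \code{scan} (the preprocessed [BoldScan-class]) and
#'   \code{design} (the confound design used).
#' @export
preprocessBold <- function(scan, motion, low = 0.01, high = 0.08,
                           includeTissue = TRUE) {
  mot <- as.matrix(motion[, setdiff(colnames(motion), "t"), drop = FALSE])
  design <- buildConfoundDesign(mot, tissue = tissueMeans(scan))
  if (!includeTissue) {
    keep <- !grepl("^(gm|wm|csf)", design$columnNames)
    design$matrix <- design$matrix[, keep, drop = FALSE]
    design$columnNames <- design$columnNames[keep]
    design$constantColumns <- intersect(design$constantColumns,
                                        design$columnNames)
  }
  d <- dim(scanData(scan))
  mat <- matrix(scanData(scan), prod(d[1:3]), d[4])
  brain <- which(as.integer(tissueLabels(scan)) > 0L)
  clean <- matrix(0, nrow(mat), ncol(mat))
  res <- regressConfounds(mat[brain, , drop = FALSE], design)
  clean[brain, ] <- bandpassFilter(res, scanTR(scan), low, high)
  out <- new("BoldScan", data = array(clean, d), affine = scanAffine(scan),
             tr = scanTR(scan), tissue = tissueLabels(scan),
             subjectId = subjectId(scan))
  list(scan = out, design = design)
}
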