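## Per-subject pairwise seed correlation and the Fisher-Z transform.

#' Fisher-Z transform
#'
#' \code{z = atanh(r)}, the variance-stabilising transform of a correlation
#' coefficient.
#'
#' @param r correlation value(s), strictly inside (-1, 1).
#' @return Fisher-Z value(s).
#' @examples
#' fisherZ(0.5)  # 0.5 * log(3)
#' @export
fisherZ <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("fisherZ is defined for |r| < 1")
  atanh(r)
}

#' Inverse Fisher-Z transform
#'
#' @param z Fisher-Z value(s).
#' @return correlation value(s), \code{tanh(z)}.
#' @export
fisherZinv <- function(z) tanh(z)

#' Pairwise seed-network correlation for one subject
#'
#' Pearson product-moment correlation between every pair of seed time
#' courses, with the Fisher-Z matrix computed off-diagonal. Correlations
#' numerically at +-1 off the diagonal indicate an extraction or simulation
#' fault and are rejected rather than clipped.
#'
#' @param ts n_seeds x n_volumes matrix as from [extractSeedTimeseries()]
#'   (row names are seed labels).
#' @param subjectId subject identifier; defaults to the matrix's
#'   \code{subjectId} attribute.
#' @return a [ConnectivityResult-class].
#' @export
pairwiseCorrelation <- function(ts, subjectId = NULL) {
  if (is.null(subjectId))
    subjectId <- attr(ts, "subjectId") %||% "subject"
  if (ncol(ts) < 3L) stop("need at least three time points")
  sds <- apply(ts, 1, sd)
  if (any(sds == 0))
    stop(sprintf("seed '%s' has a zero-variance time course",
                 rownames(ts)[which(sds == 0)[1]]))
  r <- cor(t(ts))
  off <- r[upper.tri(r)]
  if (any(abs(off) >= 1 - 1e-12))
    stop("degenerate correlation at +-1 between distinct seeds")
  z <- atanh(r)
  diag(z) <- 0
  rn <- rownames(ts) %||% paste0("region", seq_len(nrow(ts)))
  dimnames(r) <- dimnames(z) <- list(rn, rn)
  new("ConnectivityResult", subjectId = as.character(subjectId),
      r = r, z = z, regionNames = rn)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Long-format connectivity table for a list of subjects
#'
#' @param results list of [ConnectivityResult-class] objects.
#' @return data.frame with columns \code{subject_id}, \code{region_i},
#'   \code{region_j}, \code{r}, \code{z}, in [connectionIndex()] order
#'   within subject.
#' @export
connectivityLong <- function(results) {
  do.call(rbind, lapply(results, function(res) {
    ci <- connectionIndex(regionNames(res))
    data.frame(subject_id = subjectId(res),
               region_i = ci$region_i, region_j = ci$region_j,
               r = .upperVec(corMatrix(res)), z = .upperVec(zMatrix(res)),
               stringsAsFactors = FALSE)
  }))
}

#' Stack subject Fisher-Z matrices into a group matrix
#'
#' @param results list of [ConnectivityResult-class] objects sharing a
#'   region set.
#' @return n_subjects x n_connections matrix in [connectionIndex()] order,
#'   with subject ids as row names.
#' @export
groupZMatrix <- function(results) {
  rn <- regionNames(results[[1]])
  ci <- connectionIndex(rn)
  z <- t(vapply(results, function(res) {
    stopifnot(identical(regionNames(res), rn))
    .upperVec(zMatrix(res))
  }, numeric(nrow(ci))))
  rownames(z) <- vapply(results, subjectId, character(1))
  colnames(z) <- ci$connection
  z
}
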