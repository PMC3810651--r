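## Group inference: FC existence, age association, extreme-group contrast,
## change-pattern classification.

#' One-sample t-test per connection
#'
#' Tests whether the group-mean Fisher-Z of each connection differs from
#' zero: \code{t = mean / (sd / sqrt(n))}, two-tailed p on n - 1 degrees of
#' freedom.
#'
#' @param z n_subjects x n_connections Fisher-Z matrix.
#' @return data.frame with \code{mean_z}, \code{t}, \code{p} per connection.
#' @export
oneSampleFcTest <- function(z) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (n < 3L) stop("need at least three subjects")
  sds <- apply(z, 2, sd)
  if (any(sds == 0))
    stop("zero standard deviation in a connection; t undefined")
  m <- colMeans(z)
  tstat <- m / (sds / sqrt(n))
  data.frame(connection = colnames(z) %||% seq_len(ncol(z)),
             mean_z = m, t = tstat,
             p = 2 * pt(-abs(tstat), df = n - 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate step-up
#'
#' Adjusted p-values and rejection flags at level \code{q}: the largest i
#' with \code{p_(i) <= i q / m} and everything below it is rejected
#' (equivalently, adjusted p \code{<= q}).
#'
#' @param p vector of p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return list with \code{adjusted} (monotone in p) and \code{rejected}
#'   (logical).
#' @examples
#' fdrBH(c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205))$rejected
#' @export
fdrBH <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  adjusted <- p.adjust(p, method = "BH")
  list(adjusted = adjusted, rejected = adjusted <= q)
}

#' Spearman rank correlation of connectivity with age
#'
#' Spearman rho on average ranks (ties shared) per connection, with the
#' two-tailed p from the t approximation
#' \code{t = rho sqrt((n-2)/(1-rho^2))} on n - 2 degrees of freedom
#' (adequate at the cohort sizes this analysis targets); \code{rho = +-1}
#' is reported with p = 0.
#'
#' @param z n_subjects x n_connections Fisher-Z matrix.
#' @param ages numeric vector of ages.
#' @return data.frame with \code{rho_s} and \code{p} per connection.
#' @export
ageRankCorrelation <- function(z, ages) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (n < 4L) stop("need at least four subjects")
  if (length(ages) != n) stop("ages must match the subject count")
  if (sd(ages) == 0) stop("ages are constant; rank correlation undefined")
  rho <- drop(cor(ages, z, method = "spearman"))
  p <- numeric(length(rho))
  exact1 <- abs(rho) >= 1 - 1e-12
  p[exact1] <- 0
  tstat <- rho[!exact1] * sqrt((n - 2) / (1 - rho[!exact1]^2))
  p[!exact1] <- 2 * pt(-abs(tstat), df = n - 2)
  data.frame(connection = colnames(z) %||% seq_len(ncol(z)),
             rho_s = rho, p = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Extreme-group (youngest vs oldest) comparison
#'
#' Selects the k youngest and k oldest subjects (age ties broken by subject
#' id for deterministic membership), reports group means on the correlation
#' scale (inverse Fisher transform of the group-mean Z), and contrasts the
#' groups with Welch's unequal-variance two-sample t-test on the Fisher-Z
#' values.
#'
#' @param z n_subjects x n_connections Fisher-Z matrix.
#' @param ages numeric vector of ages.
#' @param k group size (default 100); requires \code{2k <= n}.
#' @param subjectIds tie-break ordering; defaults to the matrix row names
#'   or row position.
#' @return list with \code{stats} (data.frame: \code{mean_r_young},
#'   \code{mean_r_old}, \code{t}, \code{p}), \code{young}, \code{old}
#'   (row indices).
#' @export
extremeGroupCompare <- function(z, ages, k = 100L, subjectIds = NULL) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (2L * k > n)
    stop(sprintf("2k = %d exceeds the cohort size %d", 2L * k, n))
  if (is.null(subjectIds)) subjectIds <- rownames(z) %||% seq_len(n)
  ord <- order(ages, subjectIds)
  young <- ord[seq_len(k)]
  old <- ord[seq.int(n - k + 1L, n)]
  zy <- z[young, , drop = FALSE]
  zo <- z[old, , drop = FALSE]
  welch <- lapply(seq_len(ncol(z)), function(j) {
    if (sd(zy[, j]) == 0 && sd(zo[, j]) == 0) {
      if (mean(zy[, j]) == mean(zo[, j]))
        return(list(statistic = 0, p.value = 1))
      stop("degenerate zero-variance groups with unequal means")
    }
    t.test(zo[, j], zy[, j], var.equal = FALSE)
  })
  stats <- data.frame(
    connection = colnames(z) %||% seq_len(ncol(z)),
    mean_r_young = tanh(colMeans(zy)),
    mean_r_old = tanh(colMeans(zo)),
    t = vapply(welch, function(w) unname(w$statistic), numeric(1)),
    p = vapply(welch, function(w) w$p.value, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(stats = stats, young = young, old = old)
}

#' Classify the pattern of an age-related connectivity change
#'
#' Deterministic mapping for connections with a significant age association.
#' "Indistinguishable from zero" for a group means its one-sample test on
#' Fisher-Z does not reject at alpha = 0.05 (uncorrected, within group).
#' Categories: \code{inversion} (both groups significant, opposite signs);
#' \code{loss_of_anticorrelation} (significant negative FC in the young
#' moving toward zero); \code{loss_of_positive} (significant positive FC in
#' the young shrinking); \code{gain} (coupling magnitude growing in the
#' direction of its sign, including emergence from absent FC); \code{none}
#' otherwise.
#'
#' @param meanRYoung,meanROld group mean correlations.
#' @param sigYoung,sigOld logical: group mean Z significantly nonzero.
#' @param direction sign of the age association (rho_s).
#' @param sigAge logical: the connection passed the FDR-corrected age test.
#'   Calling the classifier on a non-significant connection is a contract
#'   error.
#' @return character vector of categories.
#' @export
classifyChange <- function(meanRYoung, meanROld, sigYoung, sigOld,
                           direction, sigAge = TRUE) {
  if (!all(sigAge))
    stop("classifyChange is defined only for connections with sig_age")
  n <- length(meanRYoung)
  out <- character(n)
  for (i in seq_len(n)) {
    sy <- sign(meanRYoung[i])
    so <- sign(meanROld[i])
    out[i] <-
      if (sigYoung[i] && sigOld[i] && sy != so) "inversion"
      else if (sigYoung[i] && sy < 0 && direction[i] > 0)
        "loss_of_anticorrelation"
      else if (sigYoung[i] && sy > 0 && direction[i] < 0)
        "loss_of_positive"
      else if ((sy < 0 && direction[i] < 0) || (sy > 0 && direction[i] > 0)
               || (!sigYoung[i] && sigOld[i])) "gain"
      else "none"
  }
  out
}

#' Full per-connection group statistics table
#'
#' The complete group analysis over a cohort's Fisher-Z matrix: FC existence
#' (one-sample t, FDR), age association (Spearman vs age, FDR -- corrected
#' within each family separately, mirroring two separate analyses),
#' extreme-group means and Welch contrast, and the change-pattern category
#' for age-significant connections.
#'
#' @param z n_subjects x n_connections Fisher-Z matrix
#'   (from [groupZMatrix()] or [simulateSeedCohort()]).
#' @param ages numeric vector of ages.
#' @param q FDR level for both families (default 0.05).
#' @param k extreme-group size (default 100).
#' @param groupAlpha within-group alpha for the "absent FC" criterion
#'   (default 0.05, uncorrected).
#' @return data.frame with one row per connection: \code{connection},
#'   \code{mean_z}, \code{t_fc}, \code{p_fc}, \code{q_fc}, \code{sig_fc},
#'   \code{rho_s}, \code{p_age}, \code{q_age}, \code{sig_age},
#'   \code{mean_r_young}, \code{mean_r_old}, \code{t_extreme},
#'   \code{p_extreme}, \code{sig_young}, \code{sig_old},
#'   \code{change_category} (NA unless \code{sig_age}).
#' @export
connectionStats <- function(z, ages, q = 0.05, k = 100L,
                            groupAlpha = 0.05) {
  fc <- oneSampleFcTest(z)
  fcAdj <- fdrBH(fc$p, q)
  ageTest <- ageRankCorrelation(z, ages)
  ageAdj <- fdrBH(ageTest$p, q)
  ext <- extremeGroupCompare(z, ages, k = k)
  youngT <- oneSampleFcTest(z[ext$young, , drop = FALSE])
  oldT <- oneSampleFcTest(z[ext$old, , drop = FALSE])

  out <- data.frame(
    connection = fc$connection,
    mean_z = fc$mean_z, t_fc = fc$t, p_fc = fc$p,
    q_fc = fcAdj$adjusted, sig_fc = fcAdj$rejected,
    rho_s = ageTest$rho_s, p_age = ageTest$p,
    q_age = ageAdj$adjusted, sig_age = ageAdj$rejected,
    mean_r_young = ext$stats$mean_r_young,
    mean_r_old = ext$stats$mean_r_old,
    t_extreme = ext$stats$t, p_extreme = ext$stats$p,
    sig_young = youngT$p < groupAlpha, sig_old = oldT$p < groupAlpha,
    change_category = NA_character_,
    row.names = NULL, stringsAsFactors = FALSE
  )
  sig <- which(out$sig_age)
  if (length(sig))
    out$change_category[sig] <- classifyChange(
      out$mean_r_young[sig], out$mean_r_old[sig],
      out$sig_young[sig], out$sig_old[sig], sign(out$rho_s[sig])
    )
  out
}
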