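#' Packaged seed-region table
#'
#' Returns the nine-seed network: six fMRI-derived seeds (bilateral superior
#' parietal area 7A, parietal-opercular area OP4, dorsal premotor cortex)
#' at their MNI peak coordinates, plus the task-general rostral supplementary
#' motor area (SMAr) and bilateral anterior insula (AIC) defined by
#' meta-analytic co-activation. Radius defaults to 5 mm. The
#' \code{max_distance_mm} column records, for the fMRI seeds, the distance of
#' the 100th-nearest experiment in the reference co-activation database
#' (NA for the task-general seeds, which are conjunction-derived).
#'
#' @param system optional filter: one of \code{"visual-attention"},
#'   \code{"sensorimotor"}, \code{"task-general"}.
#' @return data.frame with columns \code{name}, \code{x_mm}, \code{y_mm},
#'   \code{z_mm}, \code{radius_mm}, \code{system}, \code{max_distance_mm}.
#' @examples
#' defaultSeeds()
#' @export
defaultSeeds <- function(system = NULL) {
  path <- system.file("extdata", "seed_regions.tsv", package = "agefc")
  seeds <- read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(system)) {
    system <- match.arg(system, unique(seeds$system))
    seeds <- seeds[seeds$system == system, , drop = FALSE]
    rownames(seeds) <- NULL
  }
  seeds
}

#' Packaged multi-site acquisition profiles
#'
#' Six acquisition profiles across the four contributing sites of the
#' reference cohort (n = 399): site label, subject count, repetition time in
#' seconds, number of volumes, field strength and age summary.
#'
#' @return data.frame with one row per acquisition profile.
#' @export
defaultSiteProfiles <- function() {
  path <- system.file("extdata", "site_profiles.tsv", package = "agefc")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Reference age-effect table
#'
#' The thirteen connections of the nine-seed network with significant
#' age-related connectivity change in the reference cohort: mean correlation
#' in the 100 youngest and 100 oldest participants, the Spearman correlation
#' of Fisher-Z connectivity with age, and whether each group mean differed
#' significantly from zero. Usable directly as generative ground truth via
#' [calibrateTruth()].
#'
#' @return data.frame with columns \code{region_i}, \code{region_j},
#'   \code{mean_r_young}, \code{mean_r_old}, \code{rho_s}, \code{sig_young},
#'   \code{sig_old}.
#' @export
referenceAgeEffects <- function() {
  path <- system.file("extdata", "age_effects_reference.tsv",
                      package = "agefc")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Compress seed coordinates into a small synthetic grid
#'
#' MNI peak coordinates extend to |x| = 50, z = 60 mm and fall outside the
#' default desk-scale grid (+-46.5 mm). The documented compression is a
#' uniform scale applied to the mm peaks; radii are untouched so sphere
#' extraction still means 5 mm.
#'
#' @param seeds a seed data.frame as returned by [defaultSeeds()].
#' @param scale uniform scale factor applied to \code{x_mm,y_mm,z_mm}
#'   (default 0.5).
#' @return the seed data.frame with scaled coordinates.
#' @export
compressSeeds <- function(seeds, scale = 0.5) {
  stopifnot(is.numeric(scale), scale > 0)
  seeds$x_mm <- seeds$x_mm * scale
  seeds$y_mm <- seeds$y_mm * scale
  seeds$z_mm <- seeds$z_mm * scale
  seeds
}

#' Canonical connection index of a region set
#'
#' The 36 unordered pairs of a nine-region network, ordered lexicographically
#' by position in the seed table (i < j). Every long-format output and every
#' column of a group Fisher-Z matrix follows this order.
#'
#' @param regionNames character vector of region labels.
#' @return data.frame with columns \code{i}, \code{j} (indices),
#'   \code{region_i}, \code{region_j}, \code{connection} ("A--B" label).
#' @examples
#' nrow(connectionIndex(defaultSeeds()$name))  # 36
#' @export
connectionIndex <- function(regionNames) {
  n <- length(regionNames)
  stopifnot(n >= 2L, !anyDuplicated(regionNames))
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  data.frame(
    i = ij[, 1], j = ij[, 2],
    region_i = regionNames[ij[, 1]], region_j = regionNames[ij[, 2]],
    connection = paste(regionNames[ij[, 1]], regionNames[ij[, 2]],
                       sep = "--"),
    stringsAsFactors = FALSE
  )
}

## Flatten the upper triangle of a symmetric matrix in connectionIndex order.
.upperVec <- function(m) {
  n <- nrow(m)
  ci <- which(upper.tri(m), arr.ind = TRUE)
  ci <- ci[order(ci[, 1], ci[, 2]), , drop = FALSE]
  m[ci]
}

## Inverse of .upperVec: symmetric matrix with given diagonal value.
.symFromVec <- function(v, n, diagValue = 0) {
  m <- matrix(0, n, n)
  ci <- which(upper.tri(m), arr.ind = TRUE)
  ci <- ci[order(ci[, 1], ci[, 2]), , drop = FALSE]
  m[ci] <- v
  m <- m + t(m)
  diag(m) <- diagValue
  m
}
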