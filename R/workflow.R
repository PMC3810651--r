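## End-to-end orchestration: simulate -> preprocess -> extract -> connect ->
## group statistics, and foci -> MACM -> conjunction, with config validation
## and a hash manifest.

#' Default pipeline configuration
#'
#' A named list of every stage's parameters. Defaults give a desk-scale
#' demonstration run: 60 subjects on a 24-voxel 3 mm grid (seed coordinates
#' compressed by 0.35), extreme groups of 20, and a 16-voxel 4 mm
#' meta-analysis grid. Every stochastic stage derives its sub-seed from
#' \code{seed} by a fixed counter offset, so one master seed reproduces the
#' whole run bit-for-bit.
#'
#' @param ... overrides of the default entries.
#' @return a config list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    nSubjects = 60L,
    ageRange = c(18, 85),
    siteProfiles = defaultSiteProfiles(),
    gridDim = c(24L, 24L, 24L),
    voxelSize = 3,
    seedCompression = 0.35,
    seedRadius = 5,
    low = 0.01, high = 0.08,
    q = 0.05,
    k = 20L,
    groupAlpha = 0.05,
    noise = list(),
    truth = NULL,            # NULL: calibrated from the reference table
    macmGridDim = c(16L, 16L, 16L),
    macmVoxelSize = 4,
    macmK = 100L,
    nExperiments = 120L,
    formingP = 0.001,
    clusterAlpha = 0.05,
    nPerm = 500L,
    nNull = 5e4,
    scatterSd = 5,
    backgroundRate = 2
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

.validateConfig <- function(cfg) {
  maxTR <- max(cfg$siteProfiles$tr_s)
  nyq <- 1 / (2 * maxTR)
  if (cfg$high > nyq)
    stop(sprintf(
      "config invalid: high edge %.3g Hz exceeds Nyquist %.3g Hz at TR %.3g s",
      cfg$high, nyq, maxTR))
  if (cfg$low < 0 || cfg$low >= cfg$high)
    stop("config invalid: need 0 <= low < high")
  if (2L * cfg$k > cfg$nSubjects)
    stop("config invalid: 2k exceeds the cohort size")
  if (cfg$nSubjects < 4L) stop("config invalid: need at least 4 subjects")
  invisible(TRUE)
}

.writeManifest <- function(outDir, params) {
  if (requireNamespace("yaml", quietly = TRUE)) {
    keep <- Filter(function(x) !is.data.frame(x) && !isS4(x), params)
    yaml::write_yaml(keep, file.path(outDir, "config.yaml"))
  }
  files <- sort(setdiff(list.files(outDir, recursive = TRUE),
                        "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(md5sum(file.path(outDir, files))),
    stringsAsFactors = FALSE
  )
  writeTsv(manifest, file.path(outDir, "manifest.tsv"))
  invisible(manifest)
}

#' Run the full resting-state pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> preprocess -> extract -> connect -> group
#' statistics, materialising every intermediate artifact under
#' \code{outDir} (cohort, motion and seed-timeseries TSVs, per-subject
#' NIfTI volumes, the long-format connectivity table, the per-connection
#' statistics table) plus an md5 manifest. The configuration is validated
#' before any compute; rerunning with the same config and seed reproduces
#' every output bit-for-bit.
#'
#' @param config a list from [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @param writeVolumes write per-subject NIfTI volumes (default TRUE; the
#'   statistics do not depend on them).
#' @return list with \code{stats} (the per-connection table),
#'   \code{cohort}, \code{truth}, \code{z} (subjects x connections),
#'   \code{manifest}.
#' @export
runFullPipeline <- function(config = pipelineConfig(), outDir,
                            writeVolumes = TRUE) {
  .validateConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seeds <- defaultSeeds()
  seeds$radius_mm <- config$seedRadius
  gseeds <- compressSeeds(seeds, config$seedCompression)
  geometry <- makeGeometry(config$gridDim, config$voxelSize)
  tissue <- .makeTissue(geometry, gseeds)
  noise <- do.call(makeNoiseSpec, config$noise)
  truth <- config$truth
  if (is.null(truth))
    truth <- calibrateTruth(regionNames = seeds$name,
                            n = config$nSubjects, k = config$k,
                            ageRange = config$ageRange)

  cohort <- generateCohort(config$nSubjects, config$ageRange,
                           config$siteProfiles,
                           seed = .subSeed(config$seed, 1L))
  writeTsv(cohort, file.path(outDir, "cohort.tsv"))
  writeTsv(data.frame(region_i = connectionIndex(seeds$name)$region_i,
                      region_j = connectionIndex(seeds$name)$region_j,
                      base_z = .upperVec(baseCoupling(truth)),
                      slope_z = .upperVec(ageSlope(truth))),
           file.path(outDir, "truth.tsv"))
  writeTsv(gseeds, file.path(outDir, "seeds_grid.tsv"))

  results <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    sub <- simulateSubject(cohort[i, ], truth, gseeds, noise, geometry,
                           seed = .subSeed(config$seed, 100L + i),
                           tissue = tissue)
    sid <- cohort$subject_id[i]
    writeTsv(sub$motion, file.path(outDir, sprintf("%s_motion.tsv", sid)))
    if (writeVolumes) {
      writeBoldScan(sub$scan, file.path(outDir, sprintf("%s_bold.nii", sid)),
                    if (i == 1L) file.path(outDir, "tissue.nii"))
    }
    pre <- preprocessBold(sub$scan, sub$motion, config$low, config$high)
    ts <- extractSeedTimeseries(pre$scan, gseeds)
    writeTsv(data.frame(frame = seq_len(ncol(ts)), t(ts),
                        check.names = FALSE),
             file.path(outDir, sprintf("%s_timeseries.tsv", sid)))
    results[[i]] <- pairwiseCorrelation(ts, subjectId = sid)
  }

  writeTsv(connectivityLong(results),
           file.path(outDir, "connectivity.tsv"))
  z <- groupZMatrix(results)
  stats <- connectionStats(z, cohort$age, q = config$q, k = config$k,
                           groupAlpha = config$groupAlpha)
  writeTsv(stats, file.path(outDir, "connection_stats.tsv"))
  manifest <- .writeManifest(outDir, config)
  list(stats = stats, cohort = cohort, truth = truth, z = z,
       manifest = manifest)
}

#' Run the meta-analysis pipeline: foci -> seed MACMs -> conjunction
#'
#' Generates (or accepts) a foci database, runs the ALE cluster-level
#' inference for each fMRI-derived seed, intersects the surviving masks
#' with the minimum-statistic conjunction, and writes ALE/z/p volumes,
#' cluster tables, the conjunction volume and component table, and an md5
#' manifest.
#'
#' @param config a list from [pipelineConfig()].
#' @param outDir output directory.
#' @param db optional [FociDatabase-class]; by default one is generated
#'   with the task-general peaks planted as convergence zones shared by all
#'   experiments.
#' @return list with \code{macm} (per-seed [clusterFwe()] results),
#'   \code{conjunction}, \code{db}, \code{manifest}.
#' @export
runMacmPipeline <- function(config = pipelineConfig(), outDir, db = NULL) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  geometry <- makeGeometry(config$macmGridDim, config$macmVoxelSize)
  scale <- config$seedCompression
  fmriSeeds <- compressSeeds(defaultSeeds(), scale)
  fmriSeeds <- fmriSeeds[fmriSeeds$system != "task-general", , drop = FALSE]
  zones <- compressSeeds(defaultSeeds("task-general"), scale)

  if (is.null(db)) {
    db <- generateFociDatabase(
      config$nExperiments,
      seedCoords = cbind(fmriSeeds$x_mm, fmriSeeds$y_mm, fmriSeeds$z_mm),
      plantedZones = cbind(zones$x_mm, zones$y_mm, zones$z_mm),
      scatterSd = config$scatterSd,
      backgroundRate = config$backgroundRate,
      geometry = geometry, seed = .subSeed(config$seed, 2L)
    )
  }
  writeFociDatabase(db, file.path(outDir, "foci.tsv"))

  macm <- vector("list", nrow(fmriSeeds))
  names(macm) <- fmriSeeds$name
  for (s in seq_len(nrow(fmriSeeds))) {
    res <- macmAnalysis(db, c(fmriSeeds$x_mm[s], fmriSeeds$y_mm[s],
                              fmriSeeds$z_mm[s]),
                        k = min(config$macmK,
                                nrow(experimentTable(db))),
                        geometry = geometry, formingP = config$formingP,
                        clusterAlpha = config$clusterAlpha,
                        nPerm = config$nPerm, nNull = config$nNull,
                        seed = .subSeed(config$seed, 200L + s))
    tag <- gsub("[^A-Za-z0-9]+", "_", fmriSeeds$name[s])
    writeVolume(aleValues(res$ale), geometry,
                file.path(outDir, sprintf("%s_ale.nii", tag)))
    writeVolume(aleZ(res$ale), geometry,
                file.path(outDir, sprintf("%s_z.nii", tag)))
    writeTsv(clusterTable(res$clusterSet),
             file.path(outDir, sprintf("%s_clusters.tsv", tag)))
    macm[[s]] <- res
  }

  conj <- minimumStatisticConjunction(
    lapply(macm, `[[`, "clusterSet"), geometry,
    statMaps = lapply(macm, function(r) aleValues(r$ale))
  )
  writeVolume(conj$mask, geometry, file.path(outDir, "conjunction.nii"))
  writeTsv(conj$components, file.path(outDir, "conjunction_components.tsv"))
  manifest <- .writeManifest(outDir, config)
  list(macm = macm, conjunction = conj, db = db, manifest = manifest)
}
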