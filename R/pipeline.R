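#' Build and validate a pipeline run configuration
#'
#' Collects every stage parameter and — crucially — an explicit seed for
#' every stochastic stage (simulation, encoder weights, K-means, cohort
#' split, model fitting). The configuration's hash is embedded in each
#' output so artifacts are traceable to their settings.
#'
#' @param outDir output directory for all stage artifacts.
#' @param patchTable optional path to an existing patch-table CSV; when
#'   \code{NULL} the simulate stage generates one.
#' @param clinicalTable optional path to an existing clinical CSV.
#' @param nPatients simulated cohort size (used when simulating).
#' @param seeds named list/vector with entries \code{simulation},
#'   \code{encoder}, \code{kmeans}, \code{split}, \code{model}.
#' @param weightScheme contiguity scheme for Gi*, "queen" or "rook".
#' @param hotThreshold z cutoff for hot patches, default 1.96.
#' @param varianceTarget PCA cumulative-variance goal, default 0.95.
#' @param candidateKs candidate cluster numbers, default 2:6.
#' @param validationFraction held-out share of the cohort, default 0.2.
#' @param blockPx rendering block size, default 8.
#' @return validated list of class \code{runConfig}
#' @export
runConfig <- function(outDir,
                      patchTable = NULL, clinicalTable = NULL,
                      nPatients = 200L,
                      seeds = list(simulation = 1L, encoder = 1L,
                                   kmeans = 1L, split = 1L, model = 1L),
                      weightScheme = "queen", hotThreshold = 1.96,
                      varianceTarget = 0.95, candidateKs = 2:6,
                      validationFraction = 0.2, blockPx = 8L) {
  need <- c("simulation", "encoder", "kmeans", "split", "model")
  miss <- setdiff(need, names(seeds))
  if (length(miss))
    stop("config is missing seeds for stage(s): ", paste(miss, collapse = ", "))
  bad <- !vapply(seeds[need], function(s)
    is.numeric(s) && length(s) == 1L && is.finite(s), logical(1))
  if (any(bad))
    stop("non-integer seed for stage(s): ", paste(need[bad], collapse = ", "))
  cfg <- list(outDir = outDir, patchTable = patchTable,
              clinicalTable = clinicalTable, nPatients = as.integer(nPatients),
              seeds = lapply(seeds[need], as.integer),
              weightScheme = weightScheme, hotThreshold = hotThreshold,
              varianceTarget = varianceTarget,
              candidateKs = as.integer(candidateKs),
              validationFraction = validationFraction,
              blockPx = as.integer(blockPx))
  cfg$hash <- configHash(cfg[setdiff(names(cfg), "outDir")])
  structure(cfg, class = "runConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of [runConfig()].
#' @return a \code{runConfig}
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(runConfig, y)
}

stageMessage <- function(log, stage, ...) {
  line <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  message(line)
  c(log, line)
}

#' Run the full spatial-TIL / LNM pipeline
#'
#' Executes the stage sequence score -> hotspot -> cluster -> model on a
#' patch table (simulated when none is supplied), writing intermediate CSVs
#' at every stage plus a JSON report and a run manifest with seeds, timings
#' and record counts. Re-running with an identical configuration reproduces
#' identical outputs. A stage failure aborts with the stage name and the
#' offending slide or patient id.
#'
#' @param config a \code{runConfig} (or path to its YAML file).
#' @return a [ModelComparisonReport-class], invisibly; artifacts under
#'   \code{config$outDir}
#' @export
runFullPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  t0 <- Sys.time()

  # -- simulate ----------------------------------------------------------
  if (is.null(config$patchTable)) {
    log <- stageMessage(log, "simulate", "generating ", config$nPatients,
                        "-patient synthetic cohort")
    cohort <- generateCohort(cohortSpec(nPatients = config$nPatients,
                                        seed = config$seeds$simulation))
    paths <- writeCohortCSV(cohort, config$outDir)
    config$patchTable <- paths[["patches"]]
    config$clinicalTable <- paths[["clinical"]]
  }

  # -- score -------------------------------------------------------------
  log <- stageMessage(log, "score", "reading ", config$patchTable)
  grids <- readPatchTable(config$patchTable)
  scoreTab <- tryCatch(
    writeScoreTable(grids, file.path(config$outDir, "til_scores.csv")),
    error = function(e) stop("stage score failed: ", conditionMessage(e)))
  log <- stageMessage(log, "score", nrow(scoreTab), " slides scored")

  # -- hotspot -----------------------------------------------------------
  hmaps <- lapply(grids, function(g) {
    tryCatch(
      localGiStar(g, buildLatticeWeights(g, scheme = config$weightScheme),
                  hotThreshold = config$hotThreshold),
      error = function(e) stop("stage hotspot failed on slide ", slideId(g),
                               ": ", conditionMessage(e)))
  })
  giTab <- do.call(rbind, lapply(hmaps, function(h)
    data.frame(slide_id = h@slideId, row = h@coords[, "row"],
               col = h@coords[, "col"], z = h@z,
               hot = as.integer(h@z >= h@hotThreshold))))
  utils::write.csv(giTab, file.path(config$outDir, "gi_star.csv"),
                   row.names = FALSE, quote = FALSE)
  log <- stageMessage(log, "hotspot", length(hmaps), " hot spot maps computed")

  # -- cluster -----------------------------------------------------------
  # the modeling stage needs the named two-cluster sTILC representation, so
  # the final partition is pinned at k = 2; the consensus vote over all
  # candidate k is still computed and recorded in the manifest
  fs <- tryCatch(
    deriveSpatialClusters(hmaps,
                          cfg = encoderConfig(weightSeed = config$seeds$encoder),
                          varianceTarget = config$varianceTarget,
                          candidateKs = config$candidateKs,
                          kmeansSeed = config$seeds$kmeans,
                          blockPx = config$blockPx, k = 2L),
    error = function(e) stop("stage cluster failed: ", conditionMessage(e)))
  clusterTab <- data.frame(slide_id = fs@slideIds,
                           cluster = fs@clusterLabels,
                           stilc = if (length(fs@stilcLabels)) fs@stilcLabels
                                   else NA_character_,
                           config_hash = config$hash)
  utils::write.csv(clusterTab, file.path(config$outDir, "stilc.csv"),
                   row.names = FALSE, quote = FALSE)
  log <- stageMessage(log, "cluster", "consensus k = ", selectedK(fs@vote),
                      "; partitioned at k = 2 for sTILC naming")

  # -- model -------------------------------------------------------------
  clinical <- utils::read.csv(config$clinicalTable)
  if (length(fs@stilcLabels)) {
    # overwrite stilc with the recovered spatial clusters (first slide per
    # patient; synthetic cohorts have one slide per patient)
    slidePatient <- vapply(grids, patientId, character(1))
    firstSlide <- names(grids)[match(clinical$patient_id, slidePatient)]
    rec <- stilcLabels(fs)[firstSlide]
    clinical$stilc <- ifelse(rec == "sTILC1", 1L, 2L)
  }
  sc <- splitCohort(clinical, config$validationFraction,
                    seed = config$seeds$split)
  report <- tryCatch(
    compareLNMModels(sc$training,
                     list(training = sc$training,
                          validation = sc$validation),
                     seed = config$seeds$model,
                     configHashValue = config$hash),
    error = function(e) stop("stage model failed: ", conditionMessage(e)))

  # -- report ------------------------------------------------------------
  reportJSON <- lapply(report@cohorts, function(co)
    co[c("aucM1", "aucM2", "delongZ", "delongP", "brierM1", "brierM2")])
  jsonlite::write_json(
    list(cohorts = reportJSON, seeds = config$seeds,
         config_hash = config$hash),
    file.path(config$outDir, "report.json"), auto_unbox = TRUE, digits = NA)
  shapTab <- do.call(rbind, lapply(names(report@cohorts), function(nm) {
    sh <- report@cohorts[[nm]]$shapley
    if (is.null(sh)) return(NULL)
    data.frame(cohort = nm, feature = names(sh$importance),
               mean_abs_shap = unname(sh$importance))
  }))
  if (!is.null(shapTab))
    utils::write.csv(shapTab, file.path(config$outDir, "shapley.csv"),
                     row.names = FALSE, quote = FALSE)
  manifest <- list(config_hash = config$hash, seeds = config$seeds,
                   consensus_k = selectedK(fs@vote),
                   n_slides = length(grids), n_patients = nrow(clinical),
                   elapsed_sec = as.numeric(difftime(Sys.time(), t0, "secs")),
                   log = log)
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(report)
}
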