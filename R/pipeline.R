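#' Run the full analysis pipeline
#'
#' Orchestrates generate -> preprocess -> solve -> features ->
#' correlate -> train on a synthetic cohort, writing every stage
#' artifact plus a run manifest (config snapshot, seed, package
#' version, per-artifact MD5 hashes and stage timings). Re-running with
#' the same configuration and seed reproduces the feature table
#' bit-for-bit.
#'
#' @param cohort a [cohortConfig()]; its `seed` drives all randomness.
#' @param outDir output directory.
#' @param surrogate replace the finite-element solves with the
#'   closed-form Laplace screening statistics (fast mode).
#' @param materials tissue materials.
#' @param solver a [solverConfig()].
#' @param rf an [rfConfig()] (its seed is overridden by the cohort
#'   seed).
#' @param targetEdgeLength FE mesh resolution (mm).
#' @param progress print stage progress.
#' @return the manifest list, invisibly; artifacts on disk:
#'   `contours/*.json`, `features.csv`, `correlations.csv`,
#'   `model_report.json`, `manifest.json`.
#' @examples
#' \donttest{
#' cfg <- cohortConfig(nPatients = 2, slicesPerPatient = c(5, 5),
#'                     totalSlices = NULL)
#' man <- runPipeline(cfg, tempfile("run"), surrogate = TRUE)
#' names(man$hashes)
#' }
#' @export
runPipeline <- function(cohort = cohortConfig(), outDir,
                        surrogate = FALSE,
                        materials = vesselMaterials(),
                        solver = solverConfig(),
                        rf = rfConfig(),
                        targetEdgeLength = 0.12,
                        progress = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rf$seed <- cohort$seed
  stamp <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    list(value = v, seconds = proc.time()[["elapsed"]] - t0)
  }
  timing <- list()

  st <- stamp(generateCohort(cohort))
  pairs <- st$value; timing$generate <- st$seconds
  st <- stamp(writeContours(pairs, file.path(outDir, "contours")))
  timing$contours <- st$seconds

  st <- stamp(computeCohortFeatures(pairs, materials, surrogate, solver,
                                    targetEdgeLength, progress = progress))
  feats <- st$value; timing$features <- st$seconds
  featFile <- file.path(outDir, "features.csv")
  utils::write.csv(feats, featFile, row.names = FALSE)

  st <- stamp(correlationScreen(feats))
  screen <- st$value; timing$correlate <- st$seconds
  corrFile <- file.path(outDir, "correlations.csv")
  writeCorrelations(screen, corrFile)

  st <- stamp(trainProgressionModel(feats, rf))
  model <- st$value; timing$train <- st$seconds
  reportFile <- file.path(outDir, "model_report.json")
  jsonlite::write_json(list(
    mtry = model@mtry, ntree = model@ntree, oob_error = model@oobError,
    selected_factors = model@selected,
    gini_importance = as.list(model@importance),
    confusion = list(tp = model@confusion@tp, fn = model@confusion@fn,
                     fp = model@confusion@fp, tn = model@confusion@tn,
                     positive = model@confusion@positive),
    metrics = as.list(model@metrics)), reportFile,
    auto_unbox = TRUE, digits = NA)

  files <- c(features = featFile, correlations = corrFile,
             model_report = reportFile)
  manifest <- list(
    seed = cohort$seed,
    surrogate = surrogate,
    package_version = as.character(utils::packageVersion("plaqueFatigue")),
    config = unclass(cohort),
    solver = unclass(solver),
    n_pairs = length(pairs),
    label_split = as.list(table(feats$label)),
    hashes = as.list(tools::md5sum(files)),
    timing = timing)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(c(manifest, list(features = feats, screen = screen,
                             model = model)))
}
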