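# Orchestration: preprocess -> angiogram -> segment -> centerlines ->
# label/trim -> quantify -> CVC/CVR, in memory or against a dataset
# directory, with every result-altering parameter recorded.

defaultPipelineParams <- function() {
  list(
    bgOrder = 1L,
    thresholdMethod = "background",
    thresholdValue = NULL,
    minComponentSize = 27L,
    trimJunction = 2L,
    trimEndpoint = 3L,
    mode = "all_conditions",
    magPercentile = 0.05,
    velFraction = 0.05,
    gm = NULL,
    wm = NULL
  )
}

#' Quantify one volume: segment, extract centerlines, label, measure
#'
#' The measurement half of the pipeline for a single (already decoded)
#' velocity volume: optional preprocessing (aliasing and background
#' correction), PC-MRA angiogram, lumen segmentation, centerline extraction,
#' seed labeling with trimming, and per-vessel flow/CSA measurement.
#'
#' @param vol a \linkS4class{VelocityVolume}.
#' @param seeds named list of world-cm vessel seed points.
#' @param params pipeline parameters (see \code{defaultPipelineParams()}).
#' @param preprocess run aliasing/background correction first (default
#'   TRUE).
#' @param condition condition label carried into the measurement table.
#' @return list: \code{measurements}, \code{mask}, \code{tree},
#'   \code{report}.
#' @export
quantifyVolume <- function(vol, seeds, params = list(), preprocess = TRUE,
                           condition = NA_character_) {
  p <- utils::modifyList(defaultPipelineParams(), params)
  report <- list()
  if (preprocess) {
    pre <- preprocessVolume(
      vol,
      bgOrder = p$bgOrder, magPercentile = p$magPercentile,
      velFraction = p$velFraction
    )
    vol <- pre$volume
    report$unwrapCorrections <- pre$unwrapCorrections
    report$backgroundModel <- pre$model
  }
  angio <- computePCMRA(vol)
  mask <- segmentVessels(
    angio,
    method = p$thresholdMethod, value = p$thresholdValue,
    minSize = p$minComponentSize
  )
  tree <- extractCenterlines(mask, voxelSize(angio))
  tree <- labelAndTrim(tree, seeds, k = p$trimJunction, m = p$trimEndpoint)
  report$segmentationThreshold <- attr(mask, "threshold")
  list(
    measurements = measureAllVessels(vol, mask, tree, condition = condition),
    mask = mask, tree = tree, report = report
  )
}

#' Analyze a hypercapnia study
#'
#' Runs the full measurement pipeline on each condition of a simulated (or
#' loaded) study: aliasing correction, background phase-offset removal,
#' PC-MRA angiogram, lumen segmentation, centerline extraction,
#' seed-labeling with junction/endpoint trimming, per-vessel flow and CSA
#' measurement; then conductance and CVR fits per vessel and globally.
#'
#' @param study a \linkS4class{PhantomStudy}, or a dataset directory written
#'   by \code{\link{writeStudy}}.
#' @param params pipeline parameters; see \code{defaultPipelineParams()}
#'   (partial lists are merged over the defaults).
#' @param subject subject id carried into the result tables.
#' @return list: \code{measurements} (vessel x condition flow/CSA table),
#'   \code{cvr} (per-scope slope table), \code{reports} (per-condition
#'   unwrap counts, background model, segmentation threshold).
#' @export
analyzeStudy <- function(study, params = list(), subject = "S01") {
  p <- utils::modifyList(defaultPipelineParams(), params)
  if (is.character(study)) {
    dir <- study
    conditions <- readConditionTable(dir)
    seeds <- readSeeds(dir)
    getVolume <- function(cond) readVelocityDataset(dir, cond)
  } else {
    conditions <- study@conditions
    seeds <- study@seeds
    getVolume <- function(cond) study@volumes[[cond]]
  }
  measurements <- list()
  reports <- list()
  for (cond in conditions$condition) {
    q <- quantifyVolume(
      getVolume(cond), seeds,
      params = p, condition = cond
    )
    measurements[[cond]] <- q$measurements
    reports[[cond]] <- q$report
  }
  measurements <- do.call(rbind, measurements)
  rownames(measurements) <- NULL
  cvr <- cvrTable(
    measurements, conditions,
    mode = p$mode, gm = p$gm, wm = p$wm, subject = subject
  )
  list(measurements = measurements, cvr = cvr, reports = reports)
}

#' Run the pipeline from a configuration
#'
#' Reads a dataset directory, executes every stage and writes
#' \code{measurements.csv}, \code{cvr_results.csv}, the resolved
#' configuration (\code{config_resolved.json}) and a run log into the
#' output directory. A fixed seed gives identical numeric outputs.
#'
#' @param config named list or path to a YAML file. Required: \code{input}
#'   (dataset directory) and \code{out} (output directory); optional:
#'   \code{seed} and any \code{defaultPipelineParams()} entry.
#' @return the \code{\link{analyzeStudy}} result, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$input)) stop("config is missing 'input'")
  if (is.null(config$out)) stop("config is missing 'out'")
  if (!dir.exists(config$input)) stop("input directory not found: ", config$input)
  # fail before writing anything: the dataset must be loadable
  conditions <- readConditionTable(config$input)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  params <- config[intersect(names(config), names(defaultPipelineParams()))]
  subject <- if (is.null(config$subject)) "S01" else config$subject

  res <- withr::with_seed(
    seed,
    analyzeStudy(config$input, params = params, subject = subject)
  )

  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  write.csv(
    res$measurements, file.path(config$out, "measurements.csv"),
    row.names = FALSE
  )
  write.csv(
    res$cvr, file.path(config$out, "cvr_results.csv"),
    row.names = FALSE
  )
  resolved <- utils::modifyList(defaultPipelineParams(), params)
  resolved$input <- config$input
  resolved$out <- config$out
  resolved$seed <- seed
  resolved$package_version <- as.character(utils::packageVersion("cvrflow"))
  jsonlite::write_json(
    resolved[!vapply(resolved, is.null, logical(1))],
    file.path(config$out, "config_resolved.json"),
    auto_unbox = TRUE, digits = NA
  )
  logLines <- c(
    paste0("conditions: ", paste(conditions$condition, collapse = ", ")),
    paste0("threshold method: ", resolved$thresholdMethod),
    paste0("trim margins: junction ", resolved$trimJunction,
      ", endpoint ", resolved$trimEndpoint),
    paste0("fit mode: ", resolved$mode),
    vapply(names(res$reports), function(cc) {
      paste0(
        cc, ": unwrap corrections ", res$reports[[cc]]$unwrapCorrections,
        ", segmentation threshold ",
        signif(res$reports[[cc]]$segmentationThreshold, 5)
      )
    }, character(1))
  )
  writeLines(logLines, file.path(config$out, "run.log"))
  invisible(res)
}
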