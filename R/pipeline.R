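# End-to-end orchestration: centerline prep -> network correction -> QC,
# plus the lambda-sweep utility and YAML config plumbing. Input files are
# never mutated; all artifacts land in the caller's output directory with a
# provenance sidecar (config hash, seed, package version).

#' Read / write a pipeline configuration as YAML
#'
#' The configuration nests the per-module settings: `centerlineMode`
#' (`"y"`, `"xy"` or `"off"`), `referencePolicy`, a `loss` block
#' ([lossConfig()] fields), a `train` block ([trainConfig()] fields), and a
#' global `seed`.
#'
#' @param path YAML file
#' @param config a configuration list
#' @return `readPipelineConfig`: the configuration list;
#'   `writePipelineConfig`: invisibly, the path
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  normalizePipelineConfig(cfg)
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

normalizePipelineConfig <- function(cfg) {
  cfg$centerlineMode <- cfg$centerlineMode %||% "y"
  if (!cfg$centerlineMode %in% c("y", "xy", "off"))
    stop("centerlineMode must be 'y', 'xy' or 'off'")
  cfg$referencePolicy <- cfg$referencePolicy %||% "first"
  cfg$seed <- cfg$seed %||% 1
  lc <- cfg$loss %||% list()
  cfg$lossConfig <- lossConfig(sim = lc$sim %||% "ncc",
                               lambda = lc$lambda %||% 0.01,
                               nccWindow = lc$nccWindow %||% 3,
                               imageSigma = lc$imageSigma %||% 1,
                               eps = lc$eps %||% 1e-5)
  tr <- cfg$train %||% list()
  cfg$trainConfig <- trainConfig(
    learningRate = tr$learningRate %||% 1e-4,
    batchSize = tr$batchSize %||% 100,
    epochs = tr$epochs %||% 200,
    stepsPerEpoch = tr$stepsPerEpoch %||% 150,
    splitFraction = tr$splitFraction %||% 0.7,
    referencePolicy = cfg$referencePolicy,
    loss = cfg$lossConfig,
    seed = cfg$seed)
  cfg
}

provenanceSidecar <- function(path, config, seed) {
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config[!vapply(config, is.function, logical(1))], tmp)
  side <- list(configHash = unname(tools::md5sum(tmp)), seed = seed,
               package = "SpineMoCo",
               version = as.character(utils::packageVersion("SpineMoCo")),
               created = "run-time")
  unlink(tmp)
  jsonlite::write_json(side, path, auto_unbox = TRUE)
  invisible(path)
}

#' Run the full correction pipeline on one series
#'
#' Stages, in order: per-volume min-max normalization; centerline
#' realignment (skippable with `centerlineMode = "off"`, or driven by an
#' externally supplied track); network correction with the given or freshly
#' trained weights; QC comparison of raw vs corrected (skippable). Every
#' artifact is written under `outDir` with a provenance sidecar.
#'
#' @param series a [VolumeSeries-class] (raw) or a NIfTI path
#' @param outDir output directory (created if needed)
#' @param weights a [ModelWeights-class], a checkpoint path, or NULL to
#'   train on the input itself at the scale given in `config$train`
#' @param cordMask,csfMask optional [RoiMask-class] or NIfTI paths
#' @param config configuration list (see [readPipelineConfig()]); the
#'   `train` block is only consulted when `weights` is NULL
#' @param externalTrack optional centerline TSV path (must be y-only
#'   consistent: supplying an x-bearing track with `centerlineMode = "y"`
#'   is fine, but an external track cannot be combined with
#'   `centerlineMode = "off"`)
#' @param skipQc skip the QC stage
#' @return list of output paths (`corrected`, `qc`, `shifts`, `weights`,
#'   `provenance`) and in-memory results (`correctedSeries`, `fields`,
#'   `qcReport`, `realignment`)
#' @export
runPipeline <- function(series, outDir, weights = NULL, cordMask = NULL,
                        csfMask = NULL, config = list(),
                        externalTrack = NULL, skipQc = FALSE) {
  config <- normalizePipelineConfig(config)
  if (!is.null(externalTrack) && config$centerlineMode == "off")
    stop("invalid configuration: external centerline track supplied but ",
         "centerlineMode is 'off'")
  if (is.character(series)) series <- readVolumeSeries(series)
  if (is.character(cordMask)) cordMask <- readRoiMask(cordMask, "cord")
  if (is.character(csfMask)) csfMask <- readRoiMask(csfMask, "csf")
  if (is.character(weights)) weights <- loadModelWeights(weights)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  stage <- "normalize"
  res <- tryCatch({
    norm <- minmaxNormalize(series)

    stage <- "prep"
    shifts <- NULL
    if (config$centerlineMode != "off") {
      track <- if (!is.null(externalTrack)) readCenterlineTsv(externalTrack)
               else extractCenterline(norm, cordMask)
      track <- repairOutliers(track)
      ra <- realignSeries(norm, track,
                          mode = if (config$centerlineMode == "xy") "xy"
                                 else "y_only")
      prepped <- ra@series
      shifts <- ra
      paths$shifts <- file.path(outDir, "applied_shifts.tsv")
      writeShiftsTsv(ra, paths$shifts)
    } else prepped <- norm

    stage <- "train"
    if (is.null(weights)) {
      runs <- list(fmriRun(prepped, subject = "s1", cordMask = cordMask,
                           csfMask = csfMask))
      tr <- suppressWarnings(
        trainModel(runs, modelSpec("drm2"), config$trainConfig))
      weights <- tr$weights
      paths$weights <- file.path(outDir, "weights.rds")
      saveModelWeights(weights, paths$weights)
    }

    stage <- "correct"
    cor <- correctSeries(prepped, weights, config$referencePolicy)
    paths$corrected <- file.path(outDir, "corrected.nii.gz")
    writeVolumeSeries(cor$series, paths$corrected)

    stage <- "qc"
    qc <- NULL
    if (!skipQc) {
      qc <- qcReport(norm, cor$series, cordMask, csfMask,
                     config$referencePolicy)
      paths$qc <- file.path(outDir, "qc_report.csv")
      writeQcCsv(qc$table, paths$qc)
    }
    list(correctedSeries = cor$series, fields = cor$fields, qcReport = qc,
         realignment = shifts)
  }, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))

  paths$provenance <- file.path(outDir, "provenance.json")
  provenanceSidecar(paths$provenance,
                    config[c("centerlineMode", "referencePolicy", "seed")],
                    config$seed)
  c(paths, res)
}

#' Sweep the regularization weight
#'
#' Trains one model per lambda on the same runs, config and seed, and
#' reports the best validation cord tSNR reached for each. Mirrors the
#' regularization analysis in which quality peaks at small lambda and
#' deteriorates as the penalty grows.
#'
#' @param runs list of [fmriRun()]
#' @param spec a [ModelSpec-class]
#' @param config a [trainConfig()]
#' @param lambdas numeric vector of at least 2 lambda values
#' @return data.frame with columns `lambda` and `valTsnr`
#' @export
sweepLambda <- function(runs, spec, config, lambdas) {
  if (length(lambdas) < 2) stop("need at least 2 lambda values")
  res <- lapply(lambdas, function(l) {
    cfg <- config
    cfg$loss$lambda <- l
    tr <- suppressWarnings(trainModel(runs, spec, cfg))
    v <- tr$history$valTsnr
    data.frame(lambda = l,
               valTsnr = if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  })
  do.call(rbind, res)
}
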