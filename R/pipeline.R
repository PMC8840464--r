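#' Assemble a pipeline configuration
#'
#' A single list drives the end-to-end run: input, stratified split,
#' training-set augmentation, feature extraction, the two selectors,
#' fusion and evaluation. Every stage seed is derived deterministically
#' from the global `seed`, so two runs with the same configuration are
#' identical. The configuration round-trips losslessly through YAML
#' ([writePipelineConfig()] / [readPipelineConfig()]).
#'
#' @param input one of: `list(type = "synthetic_images", nPerClass,
#'   height, width)`, `list(type = "images", dir = ...)`, or
#'   `list(type = "features", path = ...)` /
#'   `list(type = "synthetic_features", nPerClass, nFeatures,
#'   nInformative, nRedundant, classSep)`.
#' @param splitFraction training fraction (default 0.5).
#' @param augmentTarget per-class training target after augmentation;
#'   `NULL` skips augmentation. Ignored for feature-table inputs.
#' @param extractorDim mock extractor width (default 64 for desk-scale
#'   runs).
#' @param de,gwo,fusion,fitness named lists of overrides for
#'   [deConfig()], [gwoConfig()], [fusionConfig()] and
#'   [fitnessControl()].
#' @param registry classifier names to evaluate (subset of
#'   [classifierRegistry()]); `NULL` = all.
#' @param seed global integer seed.
#' @param outDir optional directory for artifacts + JSON manifests.
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(input, splitFraction = 0.5,
                           augmentTarget = NULL, extractorDim = 64L,
                           de = list(), gwo = list(), fusion = list(),
                           fitness = list(), registry = NULL,
                           seed = 1L, outDir = NULL) {
  stopifnot(is.list(input), !is.null(input$type))
  structure(list(input = input, splitFraction = splitFraction,
                 augmentTarget = augmentTarget,
                 extractorDim = as.integer(extractorDim),
                 de = de, gwo = gwo, fusion = fusion,
                 fitness = fitness, registry = registry,
                 seed = as.integer(seed), outDir = outDir),
            class = "pipelineConfig")
}

#' @rdname pipelineConfig
#' @param config a `pipelineConfig` list.
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipelineConfig, cfg)
}

stageManifest <- function(outDir, stage, params, files = character(0)) {
  if (is.null(outDir)) return(invisible(NULL))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  md5 <- if (length(files)) as.list(tools::md5sum(files)) else NULL
  jsonlite::write_json(
    list(stage = stage, params = params, artifacts = md5,
         package_version = as.character(utils::packageVersion("sonoselect"))),
    file.path(outDir, paste0("manifest_", stage, ".json")),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(NULL)
}

#' Run the full pipeline
#'
#' Executes input -> stratified split -> training-set augmentation ->
#' feature extraction -> the two selectors -> probability fusion ->
#' classifier evaluation (fused features, train/test hold-out). Feature
#' -table inputs skip the image stages and run the selectors directly.
#' When `outDir` is set, every stage writes its artifact and a JSON
#' manifest (parameters, derived seeds, md5 of the artifact). Any stage
#' failure aborts with the stage name and cause.
#'
#' @param config a [pipelineConfig()] list.
#' @return list with `features` (train/test [FeatureMatrix-class]),
#'   `rde`, `rbgw` ([SelectionResult-class]), `fusion`
#'   ([FusionResult-class]) and `report` ([EvaluationReport-class]).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  seed <- config$seed
  outDir <- config$outDir
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  inp <- config$input
  if (inp$type %in% c("features", "synthetic_features")) {
    fmAll <- stage("input", switch(inp$type,
      features = readFeatureCSV(inp$path),
      synthetic_features = makeFeatureMatrix(
        nPerClass = inp$nPerClass, nFeatures = inp$nFeatures,
        nInformative = inp$nInformative,
        nRedundant = inp$nRedundant %||% 0L,
        classSep = inp$classSep %||% 1, seed = seed + 11L)))
    sp <- stage("split", splitDataset(fmAll, config$splitFraction,
                                      seed = seed + 13L))
    train <- sp$train; test <- sp$test
    stageManifest(outDir, "input", inp)
  } else {
    imgs <- stage("input", switch(inp$type,
      synthetic_images = makeImageSet(
        unlist(inp$nPerClass), height = inp$height %||% 64L,
        width = inp$width %||% 64L, seed = seed + 11L),
      images = readImageSet(inp$dir),
      stop("unknown input type '", inp$type, "'")))
    stageManifest(outDir, "input", inp)
    sp <- stage("split", splitDataset(imgs, config$splitFraction,
                                      seed = seed + 13L))
    trainImgs <- sp$train
    if (!is.null(config$augmentTarget)) {
      trainImgs <- stage("augment",
        augmentDataset(trainImgs, config$augmentTarget,
                       seed = seed + 17L))
      stageManifest(outDir, "augment",
                    list(target = config$augmentTarget,
                         seed = seed + 17L))
    }
    extractor <- mockDeepExtractor(config$extractorDim,
                                   seed = seed + 19L)
    train <- stage("extract", extractFeatures(trainImgs, extractor))
    test <- stage("extract", extractFeatures(sp$test, extractor))
    if (!is.null(outDir)) {
      writeFeatureCSV(train, file.path(outDir, "features_train.csv"))
      writeFeatureCSV(test, file.path(outDir, "features_test.csv"))
    }
    stageManifest(outDir, "extract",
                  list(dim = config$extractorDim, seed = seed + 19L),
                  if (!is.null(outDir))
                    file.path(outDir, c("features_train.csv",
                                        "features_test.csv")))
  }

  D <- nrow(train)
  fitCtl <- do.call(fitnessControl,
                    modifyList(list(seed = seed + 23L), config$fitness))
  deCfg <- do.call(deConfig,
                   modifyList(list(dims = D, seed = seed + 29L),
                              config$de))
  gwoCfg <- do.call(gwoConfig,
                    modifyList(list(dims = D, seed = seed + 31L),
                               config$gwo))

  selDE <- stage("select-rde", runRDE(train, config = deCfg,
                                      fitControl = fitCtl))
  selGW <- stage("select-rbgw", runRBGW(train, config = gwoCfg,
                                        fitControl = fitCtl))
  if (!is.null(outDir)) {
    writeSelectionJSON(selDE, file.path(outDir, "rde.json"))
    writeSelectionJSON(selGW, file.path(outDir, "rbgw.json"))
  }
  stageManifest(outDir, "select",
                list(de = unclass(deCfg), gwo = unclass(gwoCfg),
                     fitness = unclass(fitCtl)),
                if (!is.null(outDir))
                  file.path(outDir, c("rde.json", "rbgw.json")))

  fuseCfg <- do.call(fusionConfig,
                     modifyList(list(seed = seed + 37L), config$fusion))
  fused <- stage("fuse", probabilityFuse(selDE, selGW, train, fuseCfg))
  fusedTrain <- asFeatureMatrix(fused)
  # apply the fused column selection to the held-out test features
  keepIdx <- match(fusionProvenance(fused)$sourceFeature,
                   featureIds(test))
  testVals <- featureValues(test)[, keepIdx, drop = FALSE]
  colnames(testVals) <- colnames(fused@values)
  fusedTest <- FeatureMatrix(testVals, sampleLabels(test),
                             featureIds = colnames(testVals))
  if (!is.null(outDir)) {
    writeFeatureCSV(fusedTrain, file.path(outDir, "fused_train.csv"))
    jsonlite::write_json(fusionProvenance(fused),
                         file.path(outDir, "fused_provenance.json"),
                         digits = NA)
  }
  stageManifest(outDir, "fuse", unclass(fuseCfg),
                if (!is.null(outDir))
                  file.path(outDir, "fused_train.csv"))

  registry <- classifierRegistry(config$registry)
  report <- stage("evaluate",
                  evaluateClassifiers(fusedTrain, fusedTest,
                                      registry = registry,
                                      seed = seed + 41L))
  if (!is.null(outDir)) {
    utils::write.csv(reportMetrics(report),
                     file.path(outDir, "metrics.csv"),
                     row.names = FALSE)
  }
  stageManifest(outDir, "evaluate",
                list(registry = names(registry), seed = seed + 41L),
                if (!is.null(outDir)) file.path(outDir, "metrics.csv"))

  list(features = list(train = train, test = test),
       rde = selDE, rbgw = selGW, fusion = fused, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
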