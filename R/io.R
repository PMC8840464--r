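#' Write a FeatureMatrix to CSV
#'
#' Schema: header `sample_id,label,f0001,...`; one row per sample.
#' When the matrix carries ground-truth informative column ids, they are
#' written to a JSON sidecar `<path>.truth.json`.
#'
#' @param fm a [FeatureMatrix-class].
#' @param path output CSV path.
#' @param digits significant digits retained (default 10).
#' @return `path`, invisibly.
#' @export
writeFeatureCSV <- function(fm, path, digits = 10) {
  stopifnot(is(fm, "FeatureMatrix"))
  X <- featureValues(fm)
  df <- data.frame(sample_id = colnames(fm),
                   label = as.character(sampleLabels(fm)),
                   signif(X, digits), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", "label", featureIds(fm))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  inf <- informativeFeatures(fm)
  if (!is.null(inf))
    jsonlite::write_json(list(informative = inf),
                         paste0(path, ".truth.json"))
  invisible(path)
}

#' Read a FeatureMatrix from CSV
#'
#' Inverse of [writeFeatureCSV()]; restores the ground-truth sidecar
#' when present.
#'
#' @param path CSV path written by [writeFeatureCSV()].
#' @return A [FeatureMatrix-class].
#' @export
readFeatureCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% colnames(df)[1:2]))
    stop("expected header 'sample_id,label,f0001,...'", call. = FALSE)
  X <- as.matrix(df[, -(1:2), drop = FALSE])
  inf <- NULL
  sidecar <- paste0(path, ".truth.json")
  if (file.exists(sidecar))
    inf <- unlist(jsonlite::read_json(sidecar)$informative)
  FeatureMatrix(X, df$label, featureIds = colnames(df)[-(1:2)],
                sampleIds = df$sample_id, informative = inf)
}

#' Write a LabeledImageSet as PNG files
#'
#' One subdirectory per class under `dir` (the common on-disk layout for
#' labelled image datasets), plus a `manifest.json` recording labels and
#' augmentation provenance.
#'
#' @param imageSet a [LabeledImageSet-class].
#' @param dir output directory; created if missing.
#' @return `dir`, invisibly.
#' @export
writeImageSet <- function(imageSet, dir) {
  stopifnot(is(imageSet, "LabeledImageSet"))
  files <- character(length(imageSet))
  for (i in seq_len(length(imageSet))) {
    cls <- as.character(imageSet@labels[i])
    d <- file.path(dir, cls)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    files[i] <- file.path(cls, sprintf("img%05d.png", i))
    png::writePNG(imageSet@images[[i]], file.path(dir, files[i]))
  }
  jsonlite::write_json(
    data.frame(file = files, label = as.character(imageSet@labels),
               provenance = imageSet@provenance),
    file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read a LabeledImageSet from a class-per-subdirectory tree
#'
#' Reads every PNG under `dir`, one subdirectory per class. When a
#' `manifest.json` written by [writeImageSet()] is present its
#' provenance is restored.
#'
#' @param dir directory with `class_name/` subdirectories of PNGs.
#' @return A [LabeledImageSet-class].
#' @export
readImageSet <- function(dir) {
  classes <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
  files <- character(0); labels <- character(0)
  for (cls in classes) {
    f <- list.files(file.path(dir, cls), pattern = "\\.png$",
                    full.names = FALSE)
    files <- c(files, file.path(cls, f))
    labels <- c(labels, rep(cls, length(f)))
  }
  if (length(files) == 0L)
    stop("no PNG files found under '", dir, "'", call. = FALSE)
  images <- lapply(file.path(dir, files), function(p) {
    im <- png::readPNG(p)
    if (length(dim(im)) == 3L) im <- im[, , 1]  # collapse to grayscale
    im
  })
  prov <- rep("", length(files))
  mpath <- file.path(dir, "manifest.json")
  if (file.exists(mpath)) {
    man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
    m <- match(files, man$file)
    ok <- !is.na(m)
    prov[ok] <- man$provenance[m[ok]]
  }
  LabeledImageSet(images, factor(labels), prov)
}

#' Write a SelectionResult mask as JSON
#'
#' @param result a [SelectionResult-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeSelectionJSON <- function(result, path) {
  stopifnot(is(result, "SelectionResult"))
  jsonlite::write_json(
    list(selector = result@selector,
         selected = selectedFeatures(result),
         n_candidates = length(result@mask),
         fitness = result@fitness,
         fitness_history = result@fitnessHistory),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
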