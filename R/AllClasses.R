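#' @import methods
#' @importFrom stats sd var rnorm runif quantile median predict cor
#' @importFrom utils head modifyList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' LabeledImageSet: grayscale images with class labels and provenance
#'
#' A container for a set of 2-D grayscale images (numeric matrices with
#' values in \[0, 1\]), one class label per image, and an augmentation
#' provenance string per image ("" for originals, otherwise the op chain
#' such as `"horizontal_flip+rotate90"` applied to the named source).
#'
#' @slot images list of numeric matrices, pixel values in \[0, 1\].
#' @slot labels factor of class labels, one per image.
#' @slot provenance character vector; "" marks an original image,
#'   otherwise `"<source index>:<op1>+<op2>..."`.
#'
#' @exportClass LabeledImageSet
setClass("LabeledImageSet",
  representation(images = "list", labels = "factor", provenance = "character"),
  validity = function(object) {
    n <- length(object@images)
    if (length(object@labels) != n)
      return("labels length must match number of images")
    if (length(object@provenance) != n)
      return("provenance length must match number of images")
    for (im in object@images) {
      if (!is.matrix(im) || !is.numeric(im))
        return("every image must be a numeric matrix")
      if (anyNA(im) || min(im) < 0 || max(im) > 1)
        return("pixel values must lie in [0, 1]")
    }
    TRUE
  }
)

#' Construct a LabeledImageSet
#'
#' @param images list of numeric matrices in \[0, 1\].
#' @param labels factor or character vector of class labels.
#' @param provenance optional provenance strings ("" = original).
#' @return A [LabeledImageSet-class] object.
#' @export
LabeledImageSet <- function(images, labels, provenance = NULL) {
  if (is.null(provenance)) provenance <- rep("", length(images))
  new("LabeledImageSet",
      images = images,
      labels = as.factor(labels),
      provenance = provenance)
}

#' @describeIn LabeledImageSet number of images in the set
#' @param x a `LabeledImageSet`
#' @export
setMethod("length", "LabeledImageSet", function(x) length(x@images))

#' Subset a LabeledImageSet
#' @param x a `LabeledImageSet`
#' @param i index vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "LabeledImageSet", function(x, i, j, ..., drop = FALSE) {
  new("LabeledImageSet",
      images = x@images[i],
      labels = droplevels(x@labels[i]),
      provenance = x@provenance[i])
})

setMethod("show", "LabeledImageSet", function(object) {
  cat("LabeledImageSet with", length(object), "images\n")
  if (length(object) > 0) {
    d <- dim(object@images[[1]])
    cat("  first image:", d[1], "x", d[2], "pixels\n")
    cat("  classes:", paste(sprintf("%s (%d)",
        names(table(object@labels)), table(object@labels)), collapse = ", "),
        "\n")
    cat("  augmented:", sum(nzchar(object@provenance)), "of", length(object),
        "\n")
  }
})

#' Image labels
#' @param x a `LabeledImageSet` or `FeatureMatrix`
#' @return factor of class labels, one per sample.
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname sampleLabels
#' @export
setMethod("sampleLabels", "LabeledImageSet", function(x) x@labels)

#' Augmentation provenance strings
#' @param x a `LabeledImageSet`
#' @return character vector, "" for originals.
#' @export
imageProvenance <- function(x) {
  stopifnot(is(x, "LabeledImageSet"))
  x@provenance
}

#' Extract the list of image matrices
#' @param x a `LabeledImageSet`
#' @return list of numeric matrices.
#' @export
imageData <- function(x) {
  stopifnot(is(x, "LabeledImageSet"))
  x@images
}

# ---------------------------------------------------------------------------

#' FeatureMatrix: a labelled sample-by-feature matrix
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a single
#' assay `"features"` (rows = features, columns = samples), a `label`
#' column in `colData`, and (for synthetic data) the ground-truth
#' informative feature ids in `metadata(x)$informative`.
#'
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  contains = "SummarizedExperiment",
  validity = function(object) {
    if (!"features" %in% SummarizedExperiment::assayNames(object))
      return("assay 'features' is required")
    a <- SummarizedExperiment::assay(object, "features")
    if (!is.numeric(a) || anyNA(a) || any(!is.finite(a)))
      return("assay 'features' must be finite numeric")
    if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
      return("colData must contain a 'label' column")
    TRUE
  }
)

#' Construct a FeatureMatrix
#'
#' @param values numeric matrix, samples in rows and features in columns.
#' @param labels class label per sample (factor or character).
#' @param featureIds optional feature ids; default `f0001 ...`.
#' @param sampleIds optional sample ids; default `s0001 ...`.
#' @param informative optional character vector of ground-truth
#'   informative feature ids (synthetic data only).
#' @return A [FeatureMatrix-class] object.
#' @export
FeatureMatrix <- function(values, labels, featureIds = NULL, sampleIds = NULL,
                          informative = NULL) {
  values <- as.matrix(values)
  n <- nrow(values); D <- ncol(values)
  if (is.null(featureIds)) featureIds <- sprintf("f%04d", seq_len(D))
  if (is.null(sampleIds)) sampleIds <- sprintf("s%04d", seq_len(n))
  a <- t(values)
  dimnames(a) <- list(featureIds, sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = a),
    colData = S4Vectors::DataFrame(label = as.factor(labels),
                                   row.names = sampleIds),
    metadata = list(informative = informative))
  new("FeatureMatrix", se)
}

#' Sample-by-feature matrix of a FeatureMatrix
#' @param x a `FeatureMatrix`
#' @return numeric matrix with samples in rows, features in columns.
#' @export
featureValues <- function(x) {
  stopifnot(is(x, "FeatureMatrix"))
  t(SummarizedExperiment::assay(x, "features"))
}

#' @rdname sampleLabels
#' @export
setMethod("sampleLabels", "FeatureMatrix", function(x)
  SummarizedExperiment::colData(x)$label)

#' Feature identifiers
#' @param x a `FeatureMatrix`
#' @return character vector of feature ids (column ids).
#' @export
featureIds <- function(x) {
  stopifnot(is(x, "FeatureMatrix"))
  rownames(x)
}

#' Ground-truth informative feature ids of a synthetic FeatureMatrix
#' @param x a `FeatureMatrix`
#' @return character vector, or `NULL` when unknown.
#' @export
informativeFeatures <- function(x) {
  stopifnot(is(x, "FeatureMatrix"))
  S4Vectors::metadata(x)$informative
}

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", ncol(object), "samples x", nrow(object), "features\n")
  tb <- table(sampleLabels(object))
  cat("  classes:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "),
      "\n")
  inf <- informativeFeatures(object)
  if (!is.null(inf))
    cat("  ground-truth informative features:", length(inf), "\n")
})

# ---------------------------------------------------------------------------

#' FeatureExtractor: the feature-extraction contract
#'
#' An extractor maps a 2-D grayscale image to a fixed-length real vector.
#' The contract demands determinism (same image, same vector), a fixed
#' output length `dim`, and finite values. The deterministic multiscale
#' mock extractor ([mockDeepExtractor()]) fulfils it without any trained
#' network; an adapter to a pretrained backbone can fulfil the same
#' contract.
#'
#' @slot dim integer, length of the output vector.
#' @slot fun function(image matrix) -> numeric vector of length `dim`.
#' @slot name character label for provenance.
#' @exportClass FeatureExtractor
setClass("FeatureExtractor",
  representation(dim = "integer", fun = "function", name = "character"),
  validity = function(object) {
    if (object@dim < 1L) return("dim must be positive")
    TRUE
  }
)

setMethod("show", "FeatureExtractor", function(object) {
  cat("FeatureExtractor '", object@name, "' (dim = ", object@dim, ")\n",
      sep = "")
})

#' Output dimensionality of a FeatureExtractor
#' @param x a `FeatureExtractor`
#' @return integer feature count.
#' @export
extractorDim <- function(x) {
  stopifnot(is(x, "FeatureExtractor"))
  x@dim
}

# ---------------------------------------------------------------------------

#' SelectionResult: output of a wrapper feature selector
#'
#' @slot mask logical vector over the candidate features; at least one
#'   bit set.
#' @slot featureIds character ids of all candidate features (same length
#'   as `mask`).
#' @slot fitnessHistory numeric best-fitness trajectory, one entry per
#'   generation including the initial population; non-increasing.
#' @slot fitness numeric(1) final best fitness.
#' @slot position numeric best position vector (continuous for the DE
#'   selector, 0/1 for the grey-wolf selector).
#' @slot selector character selector identity ("rde" or "rbgw").
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(mask = "logical", featureIds = "character",
                 fitnessHistory = "numeric", fitness = "numeric",
                 position = "numeric", selector = "character"),
  validity = function(object) {
    if (length(object@mask) != length(object@featureIds))
      return("mask and featureIds must have equal length")
    if (!any(object@mask)) return("mask must select at least one feature")
    if (any(diff(object@fitnessHistory) > 1e-12))
      return("fitnessHistory must be non-increasing")
    TRUE
  }
)

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult [", object@selector, "]: ",
      sum(object@mask), " of ", length(object@mask),
      " features selected\n", sep = "")
  cat("  final fitness:", format(object@fitness, digits = 5),
      "over", length(object@fitnessHistory), "recorded generations\n")
})

#' Selected feature mask
#' @param x a `SelectionResult`
#' @return logical vector over candidate features.
#' @export
selectionMask <- function(x) {
  stopifnot(is(x, "SelectionResult"))
  stats::setNames(x@mask, x@featureIds)
}

#' Ids of the selected features
#' @param x a `SelectionResult`
#' @return character vector.
#' @export
selectedFeatures <- function(x) {
  stopifnot(is(x, "SelectionResult"))
  x@featureIds[x@mask]
}

#' Best-fitness trajectory
#' @param x a `SelectionResult`
#' @return numeric vector, non-increasing.
#' @export
fitnessHistory <- function(x) {
  stopifnot(is(x, "SelectionResult"))
  x@fitnessHistory
}

#' Selected sub-matrix of a FeatureMatrix
#' @param x a `SelectionResult`
#' @param fm the `FeatureMatrix` the selector ran on.
#' @return numeric matrix of the selected columns (samples x selected).
#' @export
selectedMatrix <- function(x, fm) {
  stopifnot(is(x, "SelectionResult"), is(fm, "FeatureMatrix"))
  featureValues(fm)[, selectedFeatures(x), drop = FALSE]
}

# ---------------------------------------------------------------------------

#' FusionResult: probability-fused feature set
#'
#' @slot values numeric matrix, samples x fused features.
#' @slot labels factor of sample labels.
#' @slot provenance data.frame with one row per fused column: `selector`
#'   (which selector contributed it), `sourceFeature` (original column
#'   id), `probability` (its importance probability within its source
#'   vector).
#' @slot config list of the fusion parameters used.
#' @exportClass FusionResult
setClass("FusionResult",
  representation(values = "matrix", labels = "factor",
                 provenance = "data.frame", config = "list"),
  validity = function(object) {
    if (ncol(object@values) != nrow(object@provenance))
      return("provenance must have one row per fused column")
    if (nrow(object@values) != length(object@labels))
      return("labels must match sample count")
    TRUE
  }
)

setMethod("show", "FusionResult", function(object) {
  cat("FusionResult:", nrow(object@values), "samples x",
      ncol(object@values), "fused features\n")
  tb <- table(object@provenance$selector)
  cat("  sources:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "),
      "\n")
})

#' Per-column provenance of a FusionResult
#' @param x a `FusionResult`
#' @return data.frame with selector, sourceFeature, probability.
#' @export
fusionProvenance <- function(x) {
  stopifnot(is(x, "FusionResult"))
  x@provenance
}

#' Convert a FusionResult to a FeatureMatrix
#' @param x a `FusionResult`
#' @return a `FeatureMatrix` whose feature ids are
#'   `<selector>.<sourceFeature>`.
#' @export
asFeatureMatrix <- function(x) {
  stopifnot(is(x, "FusionResult"))
  FeatureMatrix(x@values, x@labels,
                featureIds = colnames(x@values))
}

# ---------------------------------------------------------------------------

#' EvaluationReport: classifier benchmark results
#'
#' @slot metrics data.frame with one row per classifier: Classifier,
#'   Sensitivity, Precision, F1, Accuracy, FNR (percents) and Time (s);
#'   failed classifiers carry NA metrics and an Error message.
#' @slot confusions named list of confusion matrices (true x predicted).
#' @slot protocol character, "holdout" or "cv", with fold/ratio detail.
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(metrics = "data.frame", confusions = "list",
                 protocol = "character"))

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport (", object@protocol, ")\n", sep = "")
  print(object@metrics, row.names = FALSE, digits = 4)
})

#' Metric table of an EvaluationReport
#' @param x an `EvaluationReport`
#' @return data.frame mirroring the standard report columns.
#' @export
reportMetrics <- function(x) {
  stopifnot(is(x, "EvaluationReport"))
  x@metrics
}

#' Confusion matrices of an EvaluationReport
#' @param x an `EvaluationReport`
#' @return named list of K x K matrices (rows = true class).
#' @export
reportConfusions <- function(x) {
  stopifnot(is(x, "EvaluationReport"))
  x@confusions
}
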