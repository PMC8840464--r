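#' Generate a synthetic feature matrix with planted structure
#'
#' Emulates a deep-feature table extracted from a global-average-pooling
#' layer: a block of class-informative columns whose class-conditional
#' means are separated by `classSep * noiseSd`, a block of redundant
#' columns that are jittered copies of informative ones (jitter sd =
#' `0.05 * noiseSd`), and label-independent Gaussian noise columns.
#' The ground-truth informative column ids are attached to the result
#' (see [informativeFeatures()]).
#'
#' @param nPerClass samples per class (single integer).
#' @param nClasses number of classes (default 3, mirroring
#'   benign/malignant/normal).
#' @param nFeatures total feature count D.
#' @param nInformative number of class-informative columns.
#' @param nRedundant number of jittered near-duplicate columns.
#' @param classSep standardized mean shift between adjacent class means.
#' @param noiseSd within-class standard deviation.
#' @param seed integer seed; generation is bit-reproducible under it.
#' @return A [FeatureMatrix-class]; `informativeFeatures()` returns the
#'   planted informative column ids.
#' @examples
#' fm <- makeFeatureMatrix(nPerClass = 20, nFeatures = 30,
#'                         nInformative = 5, classSep = 2, seed = 1)
#' informativeFeatures(fm)
#' @export
makeFeatureMatrix <- function(nPerClass, nClasses = 3L, nFeatures,
                              nInformative, nRedundant = 0L,
                              classSep = 1, noiseSd = 1, seed = 1L) {
  nPerClass <- checkCount(nPerClass, "nPerClass", 1L)
  nClasses <- checkCount(nClasses, "nClasses", 2L)
  nFeatures <- checkCount(nFeatures, "nFeatures", 1L)
  nInformative <- checkCount(nInformative, "nInformative", 0L)
  nRedundant <- checkCount(nRedundant, "nRedundant", 0L)
  if (nInformative + nRedundant > nFeatures)
    stop("'nInformative' + 'nRedundant' must not exceed 'nFeatures'",
         call. = FALSE)
  if (classSep < 0) stop("'classSep' must be >= 0", call. = FALSE)
  if (noiseSd <= 0) stop("'noiseSd' must be > 0", call. = FALSE)

  n <- nPerClass * nClasses
  cls <- rep(seq_len(nClasses), each = nPerClass)
  labels <- factor(paste0("class", cls))

  withSeed(seed, {
    X <- matrix(rnorm(n * nFeatures, sd = noiseSd), n, nFeatures)
    # informative columns: class means spaced classSep*noiseSd apart,
    # class order permuted per column so columns are not collinear
    centers <- (seq_len(nClasses) - (nClasses + 1) / 2) * classSep * noiseSd
    for (j in seq_len(nInformative)) {
      perm <- sample(nClasses)
      X[, j] <- X[, j] + centers[perm][cls]
    }
    # redundant columns: jittered copies of informative ones (cycled)
    if (nRedundant > 0L && nInformative > 0L) {
      for (r in seq_len(nRedundant)) {
        src <- ((r - 1L) %% nInformative) + 1L
        X[, nInformative + r] <- X[, src] +
          rnorm(n, sd = 0.05 * noiseSd)
      }
    }
    ids <- sprintf("f%04d", seq_len(nFeatures))
    FeatureMatrix(X, labels, featureIds = ids,
                  informative = ids[seq_len(nInformative)])
  })
}

#' Generate a synthetic grayscale ultrasound-like image set
#'
#' Produces toy images whose classes differ in lesion shape and texture
#' statistics on a multiplicative speckle background: the "benign"-like
#' class renders one smooth dark ellipse, the "malignant"-like class an
#' irregular dark polygon blob, and the "normal" class speckle only.
#' Lesion classes therefore have a lower mean intensity than the normal
#' class.
#'
#' @param nPerClass integer vector of per-class counts, matched by
#'   position to `classes`.
#' @param classes class names; default `c("normal", "malignant",
#'   "benign")`.
#' @param height,width image size in pixels (>= 32).
#' @param seed integer seed; reproducible under it.
#' @return A [LabeledImageSet-class]. If every count is zero an empty
#'   set is returned with a warning.
#' @examples
#' imgs <- makeImageSet(c(3, 3, 3), height = 32, width = 32, seed = 1)
#' length(imgs)
#' @export
makeImageSet <- function(nPerClass, classes = c("normal", "malignant", "benign"),
                         height = 64L, width = 64L, seed = 1L) {
  if (length(nPerClass) != length(classes))
    stop("'nPerClass' must have one count per class", call. = FALSE)
  if (height < 32L || width < 32L)
    stop("'height' and 'width' must be >= 32", call. = FALSE)
  if (all(nPerClass == 0L)) {
    warning("all class counts are zero; returning an empty set")
    return(LabeledImageSet(list(), factor(character(0), levels = classes)))
  }

  withSeed(seed, {
    images <- list()
    labels <- character(0)
    for (ci in seq_along(classes)) {
      for (k in seq_len(nPerClass[ci])) {
        images[[length(images) + 1L]] <-
          renderClassImage(classes[ci], height, width)
        labels <- c(labels, classes[ci])
      }
    }
    LabeledImageSet(images, factor(labels, levels = classes[nPerClass > 0]))
  })
}

# Speckle background: base intensity under multiplicative uniform noise.
renderSpeckle <- function(height, width) {
  base <- 0.6
  img <- matrix(base * runif(height * width, 0.55, 1.45), height, width)
  pmin(pmax(img, 0), 1)
}

renderClassImage <- function(klass, height, width) {
  img <- renderSpeckle(height, width)
  if (klass == "normal") return(img)
  cy <- runif(1, 0.35, 0.65) * height
  cx <- runif(1, 0.35, 0.65) * width
  yy <- matrix(seq_len(height), height, width)
  xx <- matrix(seq_len(width), height, width, byrow = TRUE)
  if (klass == "benign") {
    # smooth dark ellipse with a soft edge
    a <- runif(1, 0.12, 0.22) * height
    b <- runif(1, 0.12, 0.22) * width
    th <- runif(1, 0, pi)
    dy <- yy - cy; dx <- xx - cx
    u <- cos(th) * dy + sin(th) * dx
    v <- -sin(th) * dy + cos(th) * dx
    d <- sqrt((u / a)^2 + (v / b)^2)
    dark <- 0.3 + 0.7 / (1 + exp(-8 * (d - 1)))
    img <- img * dark
  } else {
    # irregular polygon blob: star-shaped region with jagged radius
    nA <- 12L
    radii <- runif(nA, 0.08, 0.25) * min(height, width)
    ang <- atan2(yy - cy, xx - cx)
    idx <- floor((ang + pi) / (2 * pi) * nA)
    idx <- pmin(idx, nA - 1L)
    frac <- (ang + pi) / (2 * pi) * nA - idx
    r0 <- radii[idx + 1L]
    r1 <- radii[(idx + 1L) %% nA + 1L]
    rEdge <- r0 * (1 - frac) + r1 * frac
    d <- sqrt((yy - cy)^2 + (xx - cx)^2)
    img[d < rEdge] <- img[d < rEdge] * 0.3
  }
  pmin(pmax(img, 0), 1)
}
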