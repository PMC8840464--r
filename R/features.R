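# Fixed-length multiscale statistics of a grayscale image: an 8x8 grid
# of block mean intensities, a 4x4 grid of block mean gradient
# magnitudes, and 8 global summaries. Works for any image >= 32 px.
imageStatistics <- function(img) {
  blockMeans <- function(m, g) {
    ri <- as.integer(cut(seq_len(nrow(m)), g, labels = FALSE))
    ci <- as.integer(cut(seq_len(ncol(m)), g, labels = FALSE))
    out <- matrix(0, g, g)
    for (i in seq_len(g)) for (j in seq_len(g))
      out[i, j] <- mean(m[ri == i, ci == j])
    as.vector(out)
  }
  gy <- img[-1, , drop = FALSE] - img[-nrow(img), , drop = FALSE]
  gx <- img[, -1, drop = FALSE] - img[, -ncol(img), drop = FALSE]
  gmag <- sqrt(gy[, -ncol(gy), drop = FALSE]^2 +
               gx[-nrow(gx), , drop = FALSE]^2)
  q <- quantile(img, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  c(blockMeans(img, 8L), blockMeans(gmag, 4L),
    mean(img), sd(img), min(img), q, max(img))
}

N_IMAGE_STATS <- 89L

#' Deterministic mock deep-feature extractor
#'
#' Stands in for a pretrained backbone's global-average-pooling output:
#' multiscale intensity and gradient statistics of the image are passed
#' through a fixed seeded random projection and a leaky rectifier. The
#' extractor is pure — the same image always yields the same vector —
#' and label-independent. At moderate `dim` the lesion classes produced
#' by [makeImageSet()] become (approximately) linearly separable in the
#' extracted space.
#'
#' @param dim output feature count D (>= 8); default 1024 mimics a
#'   typical global-average-pooling width.
#' @param seed integer seed fixing the random projection.
#' @return A [FeatureExtractor-class].
#' @examples
#' ex <- mockDeepExtractor(dim = 32, seed = 1)
#' extractorDim(ex)
#' @export
mockDeepExtractor <- function(dim = 1024L, seed = 1L) {
  dim <- checkCount(dim, "dim", 8L)
  proj <- withSeed(seed, {
    list(W = matrix(rnorm(dim * N_IMAGE_STATS) / sqrt(N_IMAGE_STATS),
                    dim, N_IMAGE_STATS),
         b = rnorm(dim, sd = 0.1))
  })
  fun <- function(image) {
    if (!is.matrix(image) || !is.numeric(image))
      stop("'image' must be a 2-D numeric matrix", call. = FALSE)
    z <- drop(proj$W %*% imageStatistics(image)) + proj$b
    # leaky rectifier keeps sign information without dead units
    ifelse(z > 0, z, 0.1 * z)
  }
  new("FeatureExtractor", dim = dim, fun = fun,
      name = sprintf("mock-deep-%d", dim))
}

#' Extract a feature matrix from an image set
#'
#' Applies a [FeatureExtractor-class] to every image; row order matches
#' the dataset order, labels are carried through, and feature columns
#' are named `f0001 .. fD`.
#'
#' @param imageSet a non-empty [LabeledImageSet-class].
#' @param extractor a [FeatureExtractor-class].
#' @return A [FeatureMatrix-class] of size n_images x D.
#' @export
extractFeatures <- function(imageSet, extractor) {
  stopifnot(is(imageSet, "LabeledImageSet"),
            is(extractor, "FeatureExtractor"))
  if (length(imageSet) == 0L)
    stop("cannot extract features from an empty image set", call. = FALSE)
  rows <- lapply(imageSet@images, extractor@fun)
  lens <- lengths(rows)
  if (any(lens != extractor@dim))
    stop("extractor returned length ", lens[lens != extractor@dim][1],
         " but declares dim ", extractor@dim, call. = FALSE)
  X <- do.call(rbind, rows)
  if (any(!is.finite(X)))
    stop("extractor produced non-finite values", call. = FALSE)
  FeatureMatrix(X, imageSet@labels)
}
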