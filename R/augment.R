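#' Exact-permutation augmentation operations
#'
#' The three supported operations — `"horizontal_flip"`,
#' `"vertical_flip"` and `"rotate90"` (counter-clockwise) — are exact
#' pixel permutations: no interpolation, the pixel multiset is
#' preserved. Flips are involutions and four quarter-turns compose to
#' the identity.
#'
#' @param image 2-D numeric matrix (grayscale image).
#' @param op one of `"horizontal_flip"`, `"vertical_flip"`,
#'   `"rotate90"`, or a character vector to apply as a chain in order.
#' @return The transformed image; `rotate90` swaps height and width.
#' @examples
#' applyOp(matrix(1:4, 2, 2, byrow = TRUE), "rotate90")
#' @export
applyOp <- function(image, op) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("'image' must be a 2-D numeric matrix", call. = FALSE)
  for (o in op) {
    image <- switch(match.arg(o, c("horizontal_flip", "vertical_flip",
                                   "rotate90")),
      horizontal_flip = image[, ncol(image):1, drop = FALSE],
      vertical_flip = image[nrow(image):1, , drop = FALSE],
      rotate90 = t(image)[ncol(image):1, , drop = FALSE])
  }
  image
}

# Deterministic per-image chain schedule: the three single ops, then all
# 2-op compositions whose chain is not trivially the identity
# (flip followed by the same flip).
augmentChainSchedule <- function() {
  ops <- c("horizontal_flip", "vertical_flip", "rotate90")
  chains <- as.list(ops)
  for (a in ops) for (b in ops) {
    if (a == b && a != "rotate90") next
    chains[[length(chains) + 1L]] <- c(a, b)
  }
  chains
}

#' Balance a class by augmentation up to a target count
#'
#' Applies the flip/rotate operation chains to the class's images until
#' the class holds exactly `target` images. All originals are retained;
#' every augmented image records which op chain produced it from which
#' source. Chains cycle deterministically per image (the three single
#' ops, then the 2-op compositions) before falling back to stochastic
#' chains of length 3-5 drawn under `seed`; an identical op chain is
#' never reused on the same source image.
#'
#' @param imageSet a [LabeledImageSet-class] holding one class (or the
#'   images of one class).
#' @param target desired class size; must be at least the current count.
#' @param seed integer seed for the stochastic chain phase.
#' @return A [LabeledImageSet-class] with exactly `target` images.
#' @export
augmentToCount <- function(imageSet, target, seed = 1L) {
  stopifnot(is(imageSet, "LabeledImageSet"))
  n <- length(imageSet)
  if (n == 0L) stop("cannot augment an empty class", call. = FALSE)
  target <- checkCount(target, "target", 1L)
  if (target < n)
    stop("'target' (", target, ") is below the current count (", n, ")",
         call. = FALSE)
  if (nlevels(droplevels(imageSet@labels)) > 1L)
    stop("augmentToCount expects a single-class image set", call. = FALSE)
  if (target == n) return(imageSet)

  images <- imageSet@images
  labels <- as.character(imageSet@labels)
  prov <- imageSet@provenance
  schedule <- augmentChainSchedule()
  nNeeded <- target - n

  out <- vector("list", nNeeded)
  outProv <- character(nNeeded)
  used <- lapply(seq_len(n), function(i)
    vapply(schedule, paste, "", collapse = "+")[0])
  m <- 0L
  # deterministic phase: stage s applied to every image in order
  for (s in seq_along(schedule)) {
    for (i in seq_len(n)) {
      if (m >= nNeeded) break
      m <- m + 1L
      chain <- schedule[[s]]
      out[[m]] <- applyOp(images[[i]], chain)
      outProv[m] <- paste0(i, ":", paste(chain, collapse = "+"))
      used[[i]] <- c(used[[i]], paste(chain, collapse = "+"))
    }
    if (m >= nNeeded) break
  }
  # stochastic phase: random chains, never repeating a chain on a source
  if (m < nNeeded) {
    withSeed(seed, {
      ops <- c("horizontal_flip", "vertical_flip", "rotate90")
      i <- 0L
      while (m < nNeeded) {
        i <- (i %% n) + 1L
        repeat {
          len <- sample(3:5, 1L)
          chain <- sample(ops, len, replace = TRUE)
          key <- paste(chain, collapse = "+")
          if (!key %in% used[[i]]) break
        }
        used[[i]] <- c(used[[i]], key)
        m <- m + 1L
        out[[m]] <- applyOp(images[[i]], chain)
        outProv[m] <- paste0(i, ":", key)
      }
    })
  }
  LabeledImageSet(c(images, out),
                  factor(c(labels, rep(labels[1], nNeeded))),
                  c(prov, outProv))
}

#' Balance every class of a dataset to a common target
#'
#' @param imageSet a multi-class [LabeledImageSet-class].
#' @param target per-class target count.
#' @param seed integer seed; each class uses a seed derived from it.
#' @return A [LabeledImageSet-class] with `target` images per class.
#' @export
augmentDataset <- function(imageSet, target, seed = 1L) {
  stopifnot(is(imageSet, "LabeledImageSet"))
  parts <- lapply(seq_along(levels(imageSet@labels)), function(ci) {
    lv <- levels(imageSet@labels)[ci]
    augmentToCount(imageSet[imageSet@labels == lv], target,
                   seed = seed + ci)
  })
  LabeledImageSet(
    do.call(c, lapply(parts, function(p) p@images)),
    factor(do.call(c, lapply(parts, function(p) as.character(p@labels))),
           levels = levels(imageSet@labels)),
    do.call(c, lapply(parts, function(p) p@provenance)))
}

#' Stratified train/test split
#'
#' Splits a dataset by class: each class contributes
#' `round(fraction * count)` samples to the training portion. The two
#' portions are disjoint and the partition is reproducible under `seed`.
#' Augmentation should be applied to the training portion only, after
#' splitting, so that no augmented copy of a test image leaks into
#' training.
#'
#' @param x a [LabeledImageSet-class] or [FeatureMatrix-class].
#' @param fraction training fraction in (0, 1); e.g. 0.5, 0.6, 0.7.
#' @param seed integer seed.
#' @return list with elements `train` and `test` of the same class as
#'   `x`.
#' @export
setGeneric("splitDataset", function(x, fraction, seed = 1L)
  standardGeneric("splitDataset"))

splitIdx <- function(y, fraction, seed) {
  if (fraction <= 0 || fraction >= 1)
    stop("'fraction' must lie strictly between 0 and 1", call. = FALSE)
  withSeed(seed, stratifiedTrainIdx(y, fraction))
}

#' @rdname splitDataset
#' @export
setMethod("splitDataset", "LabeledImageSet", function(x, fraction, seed = 1L) {
  tr <- splitIdx(x@labels, fraction, seed)
  list(train = x[tr], test = x[setdiff(seq_len(length(x)), tr)])
})

#' @rdname splitDataset
#' @export
setMethod("splitDataset", "FeatureMatrix", function(x, fraction, seed = 1L) {
  y <- sampleLabels(x)
  tr <- splitIdx(y, fraction, seed)
  te <- setdiff(seq_len(ncol(x)), tr)
  mk <- function(idx) {
    FeatureMatrix(featureValues(x)[idx, , drop = FALSE],
                  droplevels(y[idx]),
                  featureIds = featureIds(x),
                  sampleIds = colnames(x)[idx],
                  informative = informativeFeatures(x))
  }
  list(train = mk(tr), test = mk(te))
})
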