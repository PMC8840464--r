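#' Wrapper fitness configuration
#'
#' The two selectors share one wrapper objective: the held-out
#' misclassification error of a cheap reference classifier (k-nearest
#' neighbours) on the masked columns, plus a small sparsity penalty
#' `lambda * popcount(mask) / D`. Lower is better. The internal
#' stratified split is drawn once under `seed`, so the objective is a
#' deterministic function of the mask within a run.
#'
#' @param k neighbours for the reference k-NN (default 3).
#' @param trainFrac internal training fraction (default 0.7).
#' @param lambda sparsity penalty weight (default 0.01).
#' @param seed integer seed for the internal split.
#' @return list of class `fitnessControl`.
#' @export
fitnessControl <- function(k = 3L, trainFrac = 0.7, lambda = 0.01,
                           seed = 1L) {
  stopifnot(k >= 1L, trainFrac > 0, trainFrac < 1, lambda >= 0)
  structure(list(k = as.integer(k), trainFrac = trainFrac,
                 lambda = lambda, seed = as.integer(seed)),
            class = "fitnessControl")
}

#' Wrapper fitness of a feature mask
#'
#' @param mask logical (or 0/1) vector over the columns of `X`; at
#'   least one column must be selected.
#' @param X numeric sample-by-feature matrix or a
#'   [FeatureMatrix-class].
#' @param y class labels (ignored when `X` is a `FeatureMatrix`).
#' @param control a [fitnessControl()] list.
#' @return numeric(1): held-out error plus sparsity penalty; in
#'   \[0, 1 + lambda\].
#' @examples
#' fm <- makeFeatureMatrix(nPerClass = 20, nFeatures = 10,
#'                         nInformative = 3, classSep = 2, seed = 1)
#' wrapperFitness(rep(TRUE, 10), fm)
#' @export
wrapperFitness <- function(mask, X, y = NULL, control = fitnessControl()) {
  if (is(X, "FeatureMatrix")) {
    y <- sampleLabels(X)
    X <- featureValues(X)
  }
  y <- as.factor(y)
  if (nlevels(y) < 2L)
    stop("wrapper fitness needs at least two classes", call. = FALSE)
  mask <- as.logical(mask)
  if (length(mask) != ncol(X))
    stop("mask length must equal the number of feature columns",
         call. = FALSE)
  if (!any(mask))
    stop("mask must select at least one feature", call. = FALSE)
  Xm <- X[, mask, drop = FALSE]
  err <- withSeed(control$seed, {
    tr <- stratifiedTrainIdx(y, control$trainFrac)
    te <- setdiff(seq_len(nrow(X)), tr)
    pred <- class::knn(Xm[tr, , drop = FALSE], Xm[te, , drop = FALSE],
                       y[tr], k = control$k)
    mean(pred != y[te])
  })
  if (!is.finite(err)) stop("non-finite fitness", call. = FALSE)
  err + control$lambda * sum(mask) / ncol(X)
}
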