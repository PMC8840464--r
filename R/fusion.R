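#' Fusion configuration
#'
#' @param alpha keep ratio in (0, 1\]: a column survives iff its
#'   importance probability reaches `alpha` times the best probability
#'   across both selected vectors. Default 0.5.
#' @param duplicateTol near-duplicate tolerance: two kept columns are
#'   duplicates when their correlation is at least `1 - duplicateTol`
#'   (or they originate from the same source column). Default 0.01.
#' @param probabilityMethod importance definition; currently
#'   `"importance_softmax"`-style normalized eta-squared is the only
#'   method.
#' @param seed integer seed (fusion itself is deterministic; kept for
#'   manifest completeness).
#' @return list of class `fusionConfig`.
#' @export
fusionConfig <- function(alpha = 0.5, duplicateTol = 0.01,
                         probabilityMethod = "importance_softmax",
                         seed = 1L) {
  if (alpha <= 0 || alpha > 1)
    stop("'alpha' must lie in (0, 1]", call. = FALSE)
  if (duplicateTol < 0)
    stop("'duplicateTol' must be >= 0", call. = FALSE)
  probabilityMethod <- match.arg(probabilityMethod, "importance_softmax")
  structure(list(alpha = alpha, duplicateTol = duplicateTol,
                 probabilityMethod = probabilityMethod,
                 seed = as.integer(seed)),
            class = "fusionConfig")
}

#' Per-column importance probabilities
#'
#' Scores each column by its between-class over total variance
#' (eta-squared) against the labels, then normalizes the scores to sum
#' to 1 across the vector's columns. Zero-variance columns score 0
#' before normalization; if every score is 0 the probabilities are
#' uniform.
#'
#' @param selected numeric sample-by-feature matrix (>= 1 column) or a
#'   [FeatureMatrix-class].
#' @param y labels when `selected` is a plain matrix.
#' @return numeric probabilities summing to 1, named by column.
#' @export
featureProbabilities <- function(selected, y = NULL) {
  if (is(selected, "FeatureMatrix")) {
    y <- sampleLabels(selected)
    selected <- featureValues(selected)
  }
  selected <- as.matrix(selected)
  if (ncol(selected) < 1L)
    stop("need at least one column", call. = FALSE)
  score <- etaSquared(selected, y)
  if (sum(score) == 0) p <- rep(1 / length(score), length(score))
  else p <- score / sum(score)
  stats::setNames(p, colnames(selected))
}

#' Probability-based serial fusion of two selected feature sets
#'
#' Importance probabilities are computed separately for each selector's
#' sub-matrix; the reference probability `p*` is the maximum over both
#' vectors. Columns are laid out serially (A then B) and kept iff their
#' probability is at least `alpha * p*`. Among near-duplicate pairs —
#' same source column selected by both, or correlation at least
#' `1 - duplicateTol` — only the higher-probability copy survives
#' (serial order breaks ties), removing the redundancy between the two
#' selected vectors. If the keep rule empties the set, it is relaxed to
#' the top-1 column per source with a warning.
#'
#' @param selA,selB [SelectionResult-class] objects from the same
#'   sample rows of `X`.
#' @param X the [FeatureMatrix-class] both selectors ran on.
#' @param config a [fusionConfig()] list.
#' @return A [FusionResult-class].
#' @export
probabilityFuse <- function(selA, selB, X, config = fusionConfig()) {
  stopifnot(is(selA, "SelectionResult"), is(selB, "SelectionResult"),
            is(X, "FeatureMatrix"))
  y <- sampleLabels(X)
  cand <- data.frame(
    selector = c(rep(selA@selector, sum(selA@mask)),
                 rep(selB@selector, sum(selB@mask))),
    sourceFeature = c(selectedFeatures(selA), selectedFeatures(selB)),
    stringsAsFactors = FALSE)
  matA <- selectedMatrix(selA, X)
  matB <- selectedMatrix(selB, X)
  cand$probability <- c(featureProbabilities(matA, y),
                        featureProbabilities(matB, y))
  vals <- cbind(matA, matB)

  pStar <- max(cand$probability)
  keep <- cand$probability >= config$alpha * pStar
  if (!any(keep)) {
    warning("keep rule removed every column; relaxing to top-1 per source")
    nA <- ncol(matA)
    keep[which.max(cand$probability[seq_len(nA)])] <- TRUE
    keep[nA + which.max(cand$probability[-seq_len(nA)])] <- TRUE
  }
  ki <- which(keep)
  # deduplicate: scan in serial order, drop the lower-probability copy
  drop <- rep(FALSE, length(ki))
  for (a in seq_along(ki)) {
    if (drop[a]) next
    for (b in seq_along(ki)) {
      if (b <= a || drop[b]) next
      i <- ki[a]; j <- ki[b]
      dup <- cand$sourceFeature[i] == cand$sourceFeature[j]
      if (!dup) {
        sdi <- sd(vals[, i]); sdj <- sd(vals[, j])
        if (sdi > 0 && sdj > 0)
          dup <- cor(vals[, i], vals[, j]) >= 1 - config$duplicateTol
        else dup <- sdi == 0 && sdj == 0
      }
      if (dup) {
        # ties keep the serial-earlier (A-side) copy
        if (cand$probability[j] > cand$probability[i]) drop[a] <- TRUE
        else drop[b] <- TRUE
      }
      if (drop[a]) break
    }
  }
  ki <- ki[!drop]
  prov <- cand[ki, , drop = FALSE]
  rownames(prov) <- NULL
  fused <- vals[, ki, drop = FALSE]
  colnames(fused) <- paste(prov$selector, prov$sourceFeature, sep = ".")
  new("FusionResult", values = fused, labels = y, provenance = prov,
      config = unclass(config))
}
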