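#' Confusion matrix
#'
#' Tallies a K x K matrix of counts with rows indexed by the true class
#' and columns by the predicted class; the diagonal holds the correct
#' predictions. Order-invariant in the sample order.
#'
#' @param yTrue,yPred equal-length label vectors (factor, character, or
#'   integers 0..K-1).
#' @param levels optional class levels; defaults to the union of levels
#'   found in `yTrue` and `yPred` (for 0..K-1 integers, `0:(K-1)`).
#' @return integer K x K matrix with dimnames `true` x `predicted`.
#' @export
confusionCounts <- function(yTrue, yPred, levels = NULL) {
  if (length(yTrue) != length(yPred))
    stop("'yTrue' and 'yPred' must have equal length", call. = FALSE)
  if (is.null(levels))
    levels <- sort(unique(c(as.character(yTrue), as.character(yPred))))
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  if (!all(yTrue %in% levels) || !all(yPred %in% levels))
    stop("labels outside the declared levels", call. = FALSE)
  cm <- table(factor(yTrue, levels = levels),
              factor(yPred, levels = levels))
  m <- matrix(as.integer(cm), nrow = length(levels),
              dimnames = list(true = levels, predicted = levels))
  m
}

#' Harmonic-mean F1 from sensitivity and precision
#'
#' `2 S P / (S + P)`, on percent scales. Used for the macro F1 and for
#' checking reported table rows.
#'
#' @param sensitivity,precision percents.
#' @return percent.
#' @export
harmonicF1 <- function(sensitivity, precision) {
  2 * sensitivity * precision / (sensitivity + precision)
}

#' Macro-averaged classification metrics
#'
#' Per-class sensitivity `TP/(TP+FN)` and precision `TP/(TP+FP)`;
#' macro values are unweighted means over classes. Accuracy is
#' `trace/total`. The false-negative rate is `100 - macro sensitivity`
#' (exact, by construction) and the F1 score is the harmonic mean of
#' the macro sensitivity and macro precision. All values are percents
#' rounded to 2 decimals; the per-class breakdown is retained.
#'
#' @param cm confusion matrix from [confusionCounts()]; every true
#'   class must have at least one sample.
#' @return list with `sensitivity`, `precision`, `f1`, `accuracy`,
#'   `fnr` (percents) and `perClass` (data.frame).
#' @export
macroMetrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square",
                                 call. = FALSE)
  if (is.null(rownames(cm)))
    rownames(cm) <- colnames(cm) <- seq_len(nrow(cm))
  rs <- rowSums(cm)
  if (any(rs == 0))
    stop("every true class needs at least one sample", call. = FALSE)
  tp <- diag(cm)
  sens <- tp / rs
  cs <- colSums(cm)
  prec <- ifelse(cs > 0, tp / cs, 0)
  S <- 100 * mean(sens); P <- 100 * mean(prec)
  list(sensitivity = round(S, 2),
       precision = round(P, 2),
       f1 = round(harmonicF1(S, P), 2),
       accuracy = round(100 * sum(tp) / sum(cm), 2),
       fnr = round(100 - S, 2),
       perClass = data.frame(class = rownames(cm),
                             sensitivity = round(100 * sens, 2),
                             precision = round(100 * prec, 2),
                             row.names = NULL))
}

# ---------------------------------------------------------------------------

# A registry entry is list(fit = function(X, y) model,
#                          predict = function(model, X) labels).
svmEntry <- function(kernel, degree = 3, gamma = NULL) {
  list(
    fit = function(X, y) {
      args <- list(x = X, y = y, kernel = kernel, scale = FALSE)
      if (kernel == "polynomial") {
        args$degree <- degree; args$coef0 <- 1
      }
      if (!is.null(gamma)) args$gamma <- gamma
      do.call(e1071::svm, args)
    },
    predict = function(model, X) predict(model, X))
}

knnEntry <- function(k, weighted = FALSE) {
  list(
    fit = function(X, y) list(X = X, y = y, k = k),
    predict = function(model, X) {
      if (!weighted)
        return(class::knn(model$X, X, model$y, k = model$k))
      # distance-weighted vote (1/d), vectorized per test sample
      lv <- levels(model$y)
      pred <- character(nrow(X))
      for (i in seq_len(nrow(X))) {
        d <- sqrt(colSums((t(model$X) - X[i, ])^2))
        nn <- order(d)[seq_len(model$k)]
        w <- 1 / pmax(d[nn], 1e-12)
        pred[i] <- lv[which.max(vapply(lv, function(l)
          sum(w[model$y[nn] == l]), 0))]
      }
      factor(pred, levels = lv)
    })
}

#' Default classifier registry
#'
#' Off-the-shelf classifier families in the conventions of the field's
#' benchmark tables: linear/quadratic/cubic/Gaussian-kernel SVMs
#' (LSVM, QSVM, CSVM, MGSVM), fine and distance-weighted k-NN (FKNN,
#' WKNN), linear discriminant (LD), a decision tree (DT) and a
#' random-forest ensemble (RF). Entries are pluggable: each is a
#' `list(fit = function(X, y), predict = function(model, X))`.
#'
#' @param which optional character vector to subset the registry.
#' @return named list of classifier entries.
#' @export
classifierRegistry <- function(which = NULL) {
  reg <- list(
    LSVM = svmEntry("linear"),
    QSVM = svmEntry("polynomial", degree = 2),
    CSVM = svmEntry("polynomial", degree = 3),
    MGSVM = svmEntry("radial"),
    FKNN = knnEntry(1L),
    WKNN = knnEntry(10L, weighted = TRUE),
    LD = list(
      fit = function(X, y) MASS::lda(X, grouping = y),
      predict = function(model, X) predict(model, X)$class),
    DT = list(
      fit = function(X, y) {
        df <- data.frame(y = y, X)
        rpart::rpart(y ~ ., data = df, method = "class")
      },
      predict = function(model, X)
        predict(model, data.frame(X), type = "class")),
    RF = list(
      fit = function(X, y)
        randomForest::randomForest(X, y, ntree = 200),
      predict = function(model, X) predict(model, X)))
  if (!is.null(which)) reg <- reg[which]
  reg
}

#' Benchmark a classifier registry on a train/test split
#'
#' Fits every registered classifier on the training features, predicts
#' the test set, and emits the macro metric row plus the wall time. A
#' failing classifier is recorded with NA metrics and the error
#' message; the run continues.
#'
#' @param train,test [FeatureMatrix-class] objects sharing feature
#'   columns.
#' @param registry named list from [classifierRegistry()].
#' @param seed integer seed (some learners draw random numbers).
#' @return An [EvaluationReport-class].
#' @export
evaluateClassifiers <- function(train, test,
                                registry = classifierRegistry(),
                                seed = 1L) {
  stopifnot(is(train, "FeatureMatrix"), is(test, "FeatureMatrix"))
  if (length(registry) == 0L) stop("empty classifier registry",
                                   call. = FALSE)
  if (!identical(featureIds(train), featureIds(test)))
    stop("train and test must share feature columns", call. = FALSE)
  Xtr <- featureValues(train); ytr <- sampleLabels(train)
  Xte <- featureValues(test); yte <- sampleLabels(test)
  lv <- union(levels(ytr), levels(yte))
  rows <- list(); confusions <- list()
  for (nm in names(registry)) {
    entry <- registry[[nm]]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      pred <- withSeed(seed, {
        model <- entry$fit(Xtr, ytr)
        entry$predict(model, Xte)
      })
      cm <- confusionCounts(yte, pred, levels = lv)
      list(cm = cm, metrics = macroMetrics(cm), error = NA_character_)
    }, error = function(e) list(cm = NULL, metrics = NULL,
                                error = conditionMessage(e)))
    dt <- proc.time()[["elapsed"]] - t0
    if (is.null(res$metrics)) {
      rows[[nm]] <- data.frame(Classifier = nm, Sensitivity = NA,
                               Precision = NA, F1 = NA, Accuracy = NA,
                               FNR = NA, Time = dt, Error = res$error)
    } else {
      m <- res$metrics
      rows[[nm]] <- data.frame(Classifier = nm,
                               Sensitivity = m$sensitivity,
                               Precision = m$precision, F1 = m$f1,
                               Accuracy = m$accuracy, FNR = m$fnr,
                               Time = dt, Error = NA_character_)
      confusions[[nm]] <- res$cm
    }
  }
  new("EvaluationReport",
      metrics = do.call(rbind, c(rows, list(make.row.names = FALSE))),
      confusions = confusions,
      protocol = sprintf("holdout (train %d / test %d)",
                         ncol(train), ncol(test)))
}

#' K-fold cross-validated classifier benchmark
#'
#' Stratified k-fold cross-validation of the registry on one labelled
#' feature matrix; confusion counts are pooled over folds before the
#' macro metrics are computed. Also returns the per-fold accuracy
#' matrix (classifiers x folds) for rank analysis.
#'
#' @param fm a [FeatureMatrix-class].
#' @param folds number of folds (default 10).
#' @param registry named list from [classifierRegistry()].
#' @param seed integer seed for the fold assignment.
#' @return list with `report` (an [EvaluationReport-class]) and
#'   `foldAccuracy` (matrix, classifiers x folds, percents).
#' @export
crossValidateClassifiers <- function(fm, folds = 10L,
                                     registry = classifierRegistry(),
                                     seed = 1L) {
  stopifnot(is(fm, "FeatureMatrix"))
  y <- sampleLabels(fm); X <- featureValues(fm)
  folds <- checkCount(folds, "folds", 2L)
  foldId <- withSeed(seed, {
    id <- integer(length(y))
    for (lv in levels(y)) {
      k <- which(y == lv)
      id[k] <- sample(rep(seq_len(folds), length.out = length(k)))
    }
    id
  })
  lv <- levels(y)
  pooled <- list(); times <- numeric(length(registry))
  names(times) <- names(registry)
  errs <- stats::setNames(rep(NA_character_, length(registry)),
                          names(registry))
  foldAcc <- matrix(NA_real_, length(registry), folds,
                    dimnames = list(names(registry), NULL))
  for (nm in names(registry)) {
    entry <- registry[[nm]]
    cm <- matrix(0L, length(lv), length(lv),
                 dimnames = list(true = lv, predicted = lv))
    t0 <- proc.time()[["elapsed"]]
    bad <- NULL
    for (f in seq_len(folds)) {
      te <- foldId == f
      res <- tryCatch({
        pred <- withSeed(seed + f, {
          model <- entry$fit(X[!te, , drop = FALSE], droplevels(y[!te]))
          entry$predict(model, X[te, , drop = FALSE])
        })
        cmf <- confusionCounts(y[te], pred, levels = lv)
        foldAcc[nm, f] <- 100 * sum(diag(cmf)) / sum(cmf)
        cmf
      }, error = function(e) e)
      if (inherits(res, "error")) { bad <- conditionMessage(res); break }
      cm <- cm + res
    }
    times[nm] <- proc.time()[["elapsed"]] - t0
    if (is.null(bad)) pooled[[nm]] <- cm else errs[nm] <- bad
  }
  rows <- lapply(names(registry), function(nm) {
    if (!is.na(errs[nm]))
      return(data.frame(Classifier = nm, Sensitivity = NA,
                        Precision = NA, F1 = NA, Accuracy = NA,
                        FNR = NA, Time = times[nm], Error = errs[nm]))
    m <- macroMetrics(pooled[[nm]])
    data.frame(Classifier = nm, Sensitivity = m$sensitivity,
               Precision = m$precision, F1 = m$f1,
               Accuracy = m$accuracy, FNR = m$fnr, Time = times[nm],
               Error = NA_character_)
  })
  report <- new("EvaluationReport",
                metrics = do.call(rbind, c(rows,
                                           list(make.row.names = FALSE))),
                confusions = pooled,
                protocol = sprintf("cv (%d-fold, pooled)", folds))
  list(report = report, foldAccuracy = foldAcc)
}

# ---------------------------------------------------------------------------

#' Nemenyi critical difference
#'
#' `CD = q_alpha(m) * sqrt(m (m + 1) / (6 N))`, where `q_alpha(m)` is
#' the Studentized-range quantile divided by sqrt(2)
#' (`qtukey(1 - alpha, m, Inf) / sqrt(2)`). Two methods differ
#' significantly when their mean-rank gap exceeds CD.
#'
#' @param m number of compared methods (>= 2).
#' @param N number of datasets / folds the ranks are taken over.
#' @param alpha significance level, 0.05 or 0.10.
#' @return numeric(1) critical difference.
#' @examples
#' nemenyiCD(2, 10)  # 1.960 / sqrt(10)
#' @export
nemenyiCD <- function(m, N, alpha = 0.05) {
  m <- checkCount(m, "m", 2L); N <- checkCount(N, "N", 1L)
  if (!alpha %in% c(0.05, 0.10))
    stop("'alpha' must be 0.05 or 0.10", call. = FALSE)
  q <- stats::qtukey(1 - alpha, m, Inf) / sqrt(2)
  q * sqrt(m * (m + 1) / (6 * N))
}

#' Friedman-style mean ranks with Nemenyi significance flags
#'
#' Ranks the methods within every fold (rank 1 = best, average ranks on
#' ties, larger metric values rank better), averages the ranks, and
#' flags every method pair whose mean-rank difference exceeds the
#' Nemenyi critical difference.
#'
#' @param metricTable numeric matrix, methods x folds (e.g. the
#'   `foldAccuracy` of [crossValidateClassifiers()]); no missing cells.
#' @param alpha significance level for the CD.
#' @return list with `meanRanks` (named, averaging to `(m + 1)/2`),
#'   `cd`, `significant` (logical m x m matrix) and `rankMatrix`
#'   (methods x folds).
#' @export
rankMethods <- function(metricTable, alpha = 0.05) {
  metricTable <- as.matrix(metricTable)
  m <- nrow(metricTable); N <- ncol(metricTable)
  if (m < 2L || N < 2L)
    stop("need at least 2 methods and 2 folds", call. = FALSE)
  if (anyNA(metricTable)) stop("missing cells in the metric table",
                               call. = FALSE)
  ranks <- apply(metricTable, 2, function(col)
    rank(-col, ties.method = "average"))
  meanRanks <- rowMeans(ranks)
  cd <- nemenyiCD(m, N, alpha)
  diffM <- abs(outer(meanRanks, meanRanks, "-")) > cd
  diag(diffM) <- FALSE
  list(meanRanks = meanRanks, cd = cd, significant = diffM,
       rankMatrix = ranks)
}
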