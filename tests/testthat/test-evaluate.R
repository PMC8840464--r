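test_that("confusion counts tally correctly and order-invariantly", {
  y <- c(0, 1, 2, 1, 0)
  expect_equal(diag(confusionCounts(y, y, levels = 0:2)),
               c(`0` = 2, `1` = 2, `2` = 1))
  cm <- confusionCounts(c(0, 1, 2), c(0, 0, 0), levels = 0:2)
  expect_equal(unname(colSums(cm)), c(3, 0, 0))  # single nonzero column

  # brute-force pairwise tally oracle on random vectors
  set.seed(1)
  yt <- sample(0:3, 200, TRUE); yp <- sample(0:3, 200, TRUE)
  cm <- confusionCounts(yt, yp, levels = 0:3)
  for (i in 0:3) for (j in 0:3)
    expect_equal(cm[i + 1, j + 1], sum(yt == i & yp == j))
  # order invariance
  perm <- sample(200)
  expect_equal(confusionCounts(yt[perm], yp[perm], levels = 0:3), cm)

  expect_error(confusionCounts(c(0, 5), c(0, 0), levels = 0:2),
               "outside")
  expect_error(confusionCounts(1:3, 1:2), "equal length")
})

test_that("macro metrics satisfy the exact identities on every row", {
  perfect <- diag(c(10L, 20L, 30L))
  dimnames(perfect) <- list(true = 1:3, predicted = 1:3)
  m <- macroMetrics(perfect)
  expect_equal(unlist(m[c("sensitivity", "precision", "f1",
                          "accuracy", "fnr")]),
               c(sensitivity = 100, precision = 100, f1 = 100,
                 accuracy = 100, fnr = 0))

  set.seed(2)
  for (i in 1:20) {
    cm <- matrix(rpois(9, 20) + 1L, 3, 3)
    m <- macroMetrics(cm)
    expect_equal(m$fnr, round(100 - m$sensitivity, 2))
    # the reported F1 is the harmonic mean of the (unrounded) macro
    # values; recomputing from the rounded row agrees to ~0.02
    expect_lt(abs(m$f1 - harmonicF1(m$sensitivity, m$precision)), 0.02)
    expect_equal(m$accuracy, round(100 * sum(diag(cm)) / sum(cm), 2))
    expect_true(all(unlist(m[1:5]) >= 0 & unlist(m[1:5]) <= 100))
  }
  expect_error(macroMetrics(rbind(c(0, 0), c(1, 1))), "at least one")
})

test_that("reported sensitivity/precision pairs reproduce their F1 and FNR", {
  # conventions of the standard benchmark tables: F1 is the harmonic
  # mean of the macro percentages, FNR their complement
  expect_equal(round(harmonicF1(99.10, 99.06), 2), 99.08)
  expect_equal(round(100 - 99.06, 2), 0.94)
})

test_that("every classifier is perfect on a perfectly separated toy", {
  n <- 30
  X <- matrix(c(rnorm(n, 0, 0.1), rnorm(n, 10, 0.1)), ncol = 1)
  y <- rep(c("a", "b"), each = n)
  fm <- FeatureMatrix(X, y)
  sp <- splitDataset(fm, 0.5, seed = 1)
  rep <- evaluateClassifiers(sp$train, sp$test, seed = 1)
  met <- reportMetrics(rep)
  expect_true(all(met$Accuracy == 100))
  expect_true(all(met$FNR == 0))
  expect_true(all(is.na(met$Error)))
  expect_named(reportConfusions(rep), met$Classifier, ignore.order = TRUE)
})

test_that("label permutation drops every classifier to chance", {
  fm <- smallPlantedFM(seed = 6, nPerClass = 40, nFeatures = 10,
                       nInformative = 4, classSep = 2)
  yPerm <- withr::with_seed(3, sample(sampleLabels(fm)))
  fmPerm <- FeatureMatrix(featureValues(fm), yPerm)
  sp <- splitDataset(fmPerm, 0.5, seed = 2)
  met <- reportMetrics(evaluateClassifiers(sp$train, sp$test, seed = 1))
  expect_true(all(met$Accuracy < 60))  # chance is ~33% for 3 classes
})

test_that("a failing classifier is recorded and the run continues", {
  fm <- smallPlantedFM(seed = 7, nPerClass = 20, nFeatures = 6,
                       nInformative = 2)
  sp <- splitDataset(fm, 0.5, seed = 1)
  reg <- c(classifierRegistry("FKNN"),
           list(BAD = list(fit = function(X, y) stop("boom"),
                           predict = function(m, X) NULL)))
  met <- reportMetrics(evaluateClassifiers(sp$train, sp$test,
                                           registry = reg))
  expect_equal(met$Error[met$Classifier == "BAD"], "boom")
  expect_false(is.na(met$Accuracy[met$Classifier == "FKNN"]))
})

test_that("cross-validation pools folds and returns per-fold accuracies", {
  fm <- smallPlantedFM(seed = 8, nPerClass = 30, nFeatures = 8,
                       nInformative = 3, classSep = 2)
  cv <- crossValidateClassifiers(fm, folds = 5,
                                 registry = classifierRegistry(
                                   c("FKNN", "LD")),
                                 seed = 4)
  expect_equal(dim(cv$foldAccuracy), c(2, 5))
  expect_true(all(cv$foldAccuracy >= 0 & cv$foldAccuracy <= 100))
  # pooled confusion counts every sample exactly once
  expect_equal(sum(reportConfusions(cv$report)$FKNN), 90)
})

test_that("fused features beat random subsets of equal size", {
  wins <- 0L
  for (s in 1:10) {
    fm <- makeFeatureMatrix(nPerClass = 50, nFeatures = 60,
                            nInformative = 8, classSep = 2,
                            seed = 400 + s)
    fc <- fitnessControl(seed = 500 + s)
    selA <- runRDE(fm, config = deConfig(popSize = 10, dims = 60,
                                         maxGen = 6, seed = s),
                   fitControl = fc)
    selB <- runRBGW(fm, config = gwoConfig(packSize = 8, iterations = 6,
                                           dims = 60, seed = s),
                    fitControl = fc)
    fused <- probabilityFuse(selA, selB, fm, fusionConfig())
    K <- ncol(fused@values)
    accOf <- function(sub) {
      f2 <- FeatureMatrix(featureValues(fm)[, sub, drop = FALSE],
                          sampleLabels(fm))
      sp <- splitDataset(f2, 0.5, seed = 600 + s)
      reportMetrics(evaluateClassifiers(sp$train, sp$test,
                                        classifierRegistry("FKNN"),
                                        seed = 1))$Accuracy
    }
    fusedCols <- match(fusionProvenance(fused)$sourceFeature,
                       featureIds(fm))
    randCols <- withr::with_seed(700 + s,
                                 sample(ncol(featureValues(fm)), K))
    if (accOf(fusedCols) >= accOf(randCols)) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("the Nemenyi critical difference follows its closed form", {
  expect_equal(nemenyiCD(2, 10), 1.959964 * sqrt(1 / 10),
               tolerance = 1e-5)
  for (N in c(1, 5, 50))
    expect_equal(nemenyiCD(2, N), qtukey(0.95, 2, Inf) / sqrt(2) *
                   sqrt(2 * 3 / (6 * N)))
  expect_lt(nemenyiCD(3, 1e8), 1e-3)  # vanishes as N grows
  cds <- sapply(2:10, nemenyiCD, N = 10)
  expect_true(all(diff(cds) > 0))  # increasing in the method count
  expect_error(nemenyiCD(3, 10, alpha = 0.01), "alpha")
  expect_error(nemenyiCD(1, 10), "m")
})

test_that("mean ranks and significance flags match a brute-force sort", {
  # two identical methods: equal ranks, never significant
  tbl <- rbind(m1 = c(90, 80, 85), m2 = c(90, 80, 85))
  ra <- rankMethods(tbl)
  expect_equal(unname(ra$meanRanks), c(1.5, 1.5))
  expect_false(any(ra$significant))

  # a method dominating every fold has mean rank 1.0
  set.seed(5)
  tbl2 <- rbind(best = rep(99, 10),
                mid = runif(10, 80, 90),
                low = runif(10, 60, 70))
  ra2 <- rankMethods(tbl2)
  expect_equal(unname(ra2$meanRanks["best"]), 1.0)
  expect_equal(mean(ra2$meanRanks), (3 + 1) / 2)  # ranks average to (m+1)/2

  # rank matrix equals an explicit per-fold sort
  for (f in 1:10) {
    ord <- order(-tbl2[, f])
    expect_equal(unname(ra2$rankMatrix[ord, f]), 1:3)
  }
  expect_error(rankMethods(rbind(c(1, NA), c(2, 3))), "missing")
})
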