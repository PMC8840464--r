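# helper: wrap a plain mask as a SelectionResult
mkSel <- function(mask, fm, name) {
  new("SelectionResult", mask = mask, featureIds = featureIds(fm),
      fitnessHistory = 1, fitness = 1,
      position = as.numeric(mask), selector = name)
}

test_that("feature probabilities normalize eta-squared importances", {
  fm <- smallPlantedFM(seed = 1, nPerClass = 30, nFeatures = 8,
                       nInformative = 2)
  X <- featureValues(fm); y <- sampleLabels(fm)

  expect_identical(featureProbabilities(X[, 1, drop = FALSE], y),
                   c(f0001 = 1))
  # two identical columns share the probability equally
  XX <- cbind(a = X[, 1], b = X[, 1])
  expect_equal(unname(featureProbabilities(XX, y)), c(0.5, 0.5))
  # probabilities sum to one and match the brute-force oracle
  p <- featureProbabilities(X, y)
  expect_equal(sum(p), 1)
  oracle <- apply(X, 2, etaSqOracle, y = y)
  expect_equal(unname(p), unname(oracle / sum(oracle)))
  # a zero-variance column scores zero
  XZ <- cbind(X[, 1:2], const = rep(3, nrow(X)))
  expect_equal(unname(featureProbabilities(XZ, y))[3], 0)
  # all-zero scores fall back to uniform
  XC <- cbind(rep(1, nrow(X)), rep(2, nrow(X)))
  expect_equal(unname(featureProbabilities(XC, y)), c(0.5, 0.5))
})

test_that("the top-probability column is informative, not noise", {
  wins <- 0L
  for (s in 1:10) {
    fm <- smallPlantedFM(seed = 300 + s, nPerClass = 40,
                         nFeatures = 20, nInformative = 4, classSep = 2)
    p <- featureProbabilities(featureValues(fm), sampleLabels(fm))
    if (names(which.max(p)) %in% informativeFeatures(fm))
      wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("fusing a selection with itself collapses to one copy", {
  fm <- smallPlantedFM(seed = 2, nPerClass = 30, nFeatures = 12,
                       nInformative = 3)
  mask <- featureIds(fm) %in% informativeFeatures(fm)
  selA <- mkSel(mask, fm, "rde")
  selB <- mkSel(mask, fm, "rbgw")
  fused <- probabilityFuse(selA, selB, fm,
                           fusionConfig(alpha = 1e-6))
  prov <- fusionProvenance(fused)
  expect_equal(nrow(prov), sum(mask))
  expect_true(all(prov$selector == "rde"))  # serial-earlier copy wins ties
  expect_setequal(prov$sourceFeature, informativeFeatures(fm))
})

test_that("a vanishing threshold with disjoint sets is plain concatenation", {
  fm <- smallPlantedFM(seed = 3, nPerClass = 30, nFeatures = 12,
                       nInformative = 4)
  ids <- featureIds(fm)
  selA <- mkSel(ids %in% ids[1:2], fm, "rde")     # informative
  selB <- mkSel(ids %in% ids[7:9], fm, "rbgw")    # noise
  fused <- probabilityFuse(selA, selB, fm,
                           fusionConfig(alpha = 1e-9, duplicateTol = 0))
  prov <- fusionProvenance(fused)
  expect_equal(nrow(prov), 5)
  expect_equal(prov$sourceFeature, c(ids[1:2], ids[7:9]))  # A then B
})

test_that("the 4-column toy resolves exactly as the keep-rule oracle", {
  # two informative columns selected by both sides, one noise column
  # on each side; alpha = 0.5 must keep each informative once and
  # drop both noise columns
  set.seed(9)
  n <- 60
  y <- factor(rep(c("a", "b", "c"), each = n / 3))
  shift <- c(a = -2, b = 0, c = 2)[as.character(y)]
  X <- cbind(f1 = rnorm(n) + shift, f2 = rnorm(n) - shift,
             f3 = rnorm(n), f4 = rnorm(n))
  fm <- FeatureMatrix(X, y, featureIds = colnames(X))
  selA <- mkSel(c(TRUE, TRUE, TRUE, FALSE), fm, "rde")
  selB <- mkSel(c(TRUE, TRUE, FALSE, TRUE), fm, "rbgw")
  cfg <- fusionConfig(alpha = 0.5)
  fused <- probabilityFuse(selA, selB, fm, cfg)
  prov <- fusionProvenance(fused)

  # brute-force oracle for the keep rule on the same inputs
  pOf <- function(cols) {
    s <- apply(X[, cols, drop = FALSE], 2, etaSqOracle, y = y)
    s / sum(s)
  }
  pA <- pOf(c("f1", "f2", "f3")); pB <- pOf(c("f1", "f2", "f4"))
  pStar <- max(c(pA, pB))
  keptA <- names(pA)[pA >= 0.5 * pStar]
  keptB <- names(pB)[pB >= 0.5 * pStar]
  expect_setequal(keptA, c("f1", "f2"))
  expect_setequal(keptB, c("f1", "f2"))
  # after dedup of the shared source columns: one copy each
  expect_setequal(prov$sourceFeature, c("f1", "f2"))
  expect_equal(nrow(prov), 2)
})

test_that("fused size never exceeds the sum of the inputs", {
  fm <- smallPlantedFM(seed = 4, nPerClass = 30, nFeatures = 15,
                       nInformative = 4, nRedundant = 3)
  ids <- featureIds(fm)
  set.seed(11)
  for (i in 1:10) {
    mA <- runif(15) < 0.5; mB <- runif(15) < 0.5
    if (!any(mA)) mA[1] <- TRUE
    if (!any(mB)) mB[1] <- TRUE
    fused <- probabilityFuse(mkSel(mA, fm, "rde"), mkSel(mB, fm, "rbgw"),
                             fm, fusionConfig(alpha = 0.3))
    K <- nrow(fusionProvenance(fused))
    expect_lte(K, sum(mA) + sum(mB))
    expect_gte(K, 1)
    # provenance partition: every fused column maps to one source column
    expect_equal(anyDuplicated(paste(fusionProvenance(fused)$selector,
                                     fusionProvenance(fused)$sourceFeature)),
                 0L)
  }
})

test_that("fusion deduplicates the jittered near-copies", {
  fm <- smallPlantedFM(seed = 5, nPerClass = 40, nFeatures = 10,
                       nInformative = 2, nRedundant = 2)
  ids <- featureIds(fm)
  # A selects the informative pair, B their jittered duplicates
  selA <- mkSel(ids %in% ids[1:2], fm, "rde")
  selB <- mkSel(ids %in% ids[3:4], fm, "rbgw")
  fused <- probabilityFuse(selA, selB, fm,
                           fusionConfig(alpha = 1e-9, duplicateTol = 0.01))
  expect_equal(nrow(fusionProvenance(fused)), 2)

  # determinism
  fused2 <- probabilityFuse(selA, selB, fm,
                            fusionConfig(alpha = 1e-9, duplicateTol = 0.01))
  expect_identical(fused@values, fused2@values)
})

test_that("fusion config validates its ranges", {
  expect_error(fusionConfig(alpha = 0), "alpha")
  expect_error(fusionConfig(alpha = 1.5), "alpha")
  expect_error(fusionConfig(duplicateTol = -1), "duplicateTol")
})
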