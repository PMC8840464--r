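# Shared in-code fixtures: small planted-structure datasets and a
# brute-force eta-squared oracle independent of the package internals.

smallPlantedFM <- function(seed = 1, nPerClass = 40, nFeatures = 30,
                           nInformative = 6, classSep = 2,
                           nRedundant = 0) {
  makeFeatureMatrix(nPerClass = nPerClass, nFeatures = nFeatures,
                    nInformative = nInformative,
                    nRedundant = nRedundant,
                    classSep = classSep, seed = seed)
}

# between-class / total sum of squares of one column, computed the
# long way with an explicit loop over classes
etaSqOracle <- function(x, y) {
  y <- as.factor(y)
  gm <- mean(x)
  ssTot <- sum((x - gm)^2)
  ssB <- 0
  for (lv in levels(y)) ssB <- ssB + sum(y == lv) * (mean(x[y == lv]) - gm)^2
  if (ssTot == 0) 0 else ssB / ssTot
}

# tiny single-class image set for augmentation tests
tinyImageClass <- function(n, seed = 1, side = 32) {
  makeImageSet(c(n, 0, 0), height = side, width = side, seed = seed)
}
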