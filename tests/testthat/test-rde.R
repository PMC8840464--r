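test_that("wrapper fitness is deterministic and signal-sensitive", {
  fm <- smallPlantedFM(seed = 1)
  ctl <- fitnessControl(lambda = 0, seed = 5)
  full <- rep(TRUE, 30)
  expect_identical(wrapperFitness(full, fm, control = ctl),
                   wrapperFitness(full, fm, control = ctl))
  expect_error(wrapperFitness(rep(FALSE, 30), fm), "at least one")
  expect_error(
    wrapperFitness(full, featureValues(fm), rep("a", 120)), "two classes")

  # true informative mask beats an all-noise mask on >= 9/10 seeds
  wins <- 0L
  for (s in 1:10) {
    f <- smallPlantedFM(seed = 100 + s)
    inf <- featureIds(f) %in% informativeFeatures(f)
    c2 <- fitnessControl(seed = 200 + s)
    if (wrapperFitness(inf, f, control = c2) <
        wrapperFitness(!inf, f, control = c2)) wins <- wins + 1L
  }
  expect_gte(wins, 9L)

  # a pure-noise mask sits near chance error plus the penalty
  f <- smallPlantedFM(seed = 42)
  noise <- !(featureIds(f) %in% informativeFeatures(f))
  fit <- wrapperFitness(noise, f, control = fitnessControl(seed = 3))
  expect_lt(abs(fit - (2 / 3 + 0.01 * sum(noise) / 30)), 0.2)
})

test_that("deInit fills the box uniformly and reproducibly", {
  cfgZero <- deConfig(popSize = 5, dims = 4, boundsMin = 0, boundsMax = 0)
  expect_true(all(deInit(cfgZero)$population == 0))

  cfg <- deConfig(popSize = 20, dims = 10, seed = 1)
  set.seed(1); a <- deInit(cfg)
  set.seed(1); b <- deInit(cfg)
  expect_identical(a$population, b$population)
  expect_true(all(a$population >= 0 & a$population < 1))

  # Monte-Carlo: mean of components ~ (zmin + zmax)/2 within 3 SE
  cfg2 <- deConfig(popSize = 10000, dims = 1, boundsMin = 2, boundsMax = 6)
  set.seed(2); big <- deInit(cfg2)$population
  se <- sqrt(var(big) / length(big))
  expect_lt(abs(mean(big) - 4), 3 * se)
})

test_that("mutation follows the strategy formulas and clips to bounds", {
  # replay oracle: regenerate the partner indices with the same RNG
  # stream and recompute rand/1 by hand, including the clipping
  pop <- rbind(c(1, 0), c(0.5, 0.5), c(0, 1), c(0.2, 0.8))
  state <- list(population = pop, fitness = c(4, 3, 2, 1), bestIndex = 4L)
  cfg <- deConfig(popSize = 4, dims = 2, scaleFactor = 0.5,
                  strategy = "rand1")
  set.seed(31)
  M <- deMutate(state, cfg)
  set.seed(31)
  for (j in 1:4) {
    r <- sample(setdiff(1:4, j), 3)
    expected <- pop[r[1], ] + 0.5 * (pop[r[2], ] - pop[r[3], ])
    expect_equal(M[j, ], pmin(pmax(expected, 0), 1))
  }
  # the hand case: r = (1, 2, 3) gives (1.25, -0.25) pre-clip -> (1, 0)
  hand <- pop[1, ] + 0.5 * (pop[2, ] - pop[3, ])
  expect_equal(pmin(pmax(hand, 0), 1), c(1, 0))

  # F = 0 degeneracy: every mutant is some existing population member
  cfg0 <- deConfig(popSize = 4, dims = 2, scaleFactor = 0,
                   strategy = "rand1")
  set.seed(5)
  M0 <- deMutate(state, cfg0)
  for (j in 1:4)
    expect_true(any(apply(pop, 1, function(r) all(r == M0[j, ]))))

  # best/1 cancellation: identical rows make the mutant exactly z_best
  same <- matrix(0.3, 5, 3)
  st <- list(population = same, fitness = rep(1, 5), bestIndex = 2L)
  Mb <- deMutate(st, deConfig(popSize = 5, dims = 3, strategy = "best1"))
  expect_true(all(Mb == 0.3))

  expect_error(deConfig(popSize = 5, dims = 2, strategy = "rand2"),
               "rand2")
})

test_that("binomial crossover forces at least one mutant component", {
  target <- rep(0, 8); mutant <- rep(1, 8)
  set.seed(1)
  expect_equal(deCrossover(target, mutant, 1), mutant)
  tr0 <- deCrossover(target, mutant, 0)
  expect_equal(sum(tr0 == 1), 1)  # only the forced index

  # forced inheritance holds for every crossover rate
  set.seed(2)
  for (i in 1:200) {
    C <- runif(1)
    expect_gte(sum(deCrossover(target, mutant, C) == 1), 1)
  }

  # expected mutant fraction is C + (1 - C)/D at C = 0.3, D = 10
  set.seed(3)
  fr <- replicate(10000, mean(deCrossover(rep(0, 10), rep(1, 10), 0.3)))
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - (0.3 + 0.7 / 10)), 3 * se)
})

test_that("greedy selection keeps ties and rejects worse trials", {
  f <- function(v) sum(v^2)
  res <- deSelect(c(1, 1), c(-1, 1), f(c(1, 1)), f)
  expect_true(res$accepted)  # equal fitness: trial kept
  expect_equal(res$position, c(-1, 1))
  res2 <- deSelect(c(0, 0), c(1, 1), f(c(0, 0)), f)
  expect_false(res2$accepted)
  expect_equal(res2$position, c(0, 0))
  expect_error(deSelect(c(0), c(1), NaN, f), "non-finite")
})

test_that("the DE primitives minimize a quadratic with monotone elitism", {
  # continuous DE loop on f(x) = sum(x - 0.7)^2 composed from the
  # exported primitives; best fitness must be non-increasing and
  # improve between generation 10 and 50
  f <- function(v) sum((v - 0.7)^2)
  cfg <- deConfig(popSize = 15, dims = 3, scaleFactor = 0.7,
                  crossoverRate = 0.9, strategy = "rand1")
  set.seed(17)
  st <- deInit(cfg)
  st$fitness <- apply(st$population, 1, f)
  st$bestIndex <- which.min(st$fitness)
  best <- numeric(50)
  for (g in 1:50) {
    M <- deMutate(st, cfg)
    for (j in 1:15) {
      tr <- deCrossover(st$population[j, ], M[j, ], 0.9)
      r <- deSelect(st$population[j, ], tr, st$fitness[j], f)
      st$population[j, ] <- r$position
      st$fitness[j] <- r$fitness
    }
    st$bestIndex <- which.min(st$fitness)
    best[g] <- min(st$fitness)
  }
  expect_true(all(diff(best) <= 0))
  expect_lte(best[50], best[10])
  expect_lt(best[50], 1e-3)
})

test_that("binarization thresholds and rescues as specified", {
  expect_equal(binarizePosition(c(0.9, 0.1, 0.5), 0.5),
               c(TRUE, FALSE, TRUE))
  resc <- binarizePosition(rep(0.49, 4), 0.5)
  expect_equal(sum(resc), 1)  # argmax rescue
  set.seed(8)
  for (i in 1:50) {
    v <- runif(20); cut <- runif(1, 0.1, 0.9)
    m <- binarizePosition(v, cut)
    expected <- sum(v >= cut)
    expect_equal(sum(m), max(expected, 1))
  }
})

test_that("the SSEoM filter matches its closed form", {
  expect_equal(sseomFilter(rep(0.4, 6)), rep(TRUE, 6))  # sd = 0 -> all
  # sd(1,0,0,0) = 0.5, SM = 0.5/sqrt(4) = 0.25 -> only the 1 survives
  expect_equal(sseomFilter(c(1, 0, 0, 0)), c(TRUE, FALSE, FALSE, FALSE))
  # scale equivariance
  v <- c(0.9, 0.02, 0.4, 0.15, 0.6)
  expect_identical(sseomFilter(v), sseomFilter(5 * v))
  expect_identical(sseomFilter(v), sseomFilter(0.01 * v))
  expect_error(sseomFilter(1), "at least 2")
})

test_that("runRDE reduces dimensionality with a monotone history", {
  fm <- smallPlantedFM(seed = 21)
  cfg <- deConfig(popSize = 10, dims = 30, maxGen = 8, seed = 3)
  sel <- runRDE(fm, config = cfg, fitControl = fitnessControl(seed = 4))
  expect_s4_class(sel, "SelectionResult")
  expect_identical(sel@selector, "rde")
  expect_length(fitnessHistory(sel), 9)
  expect_true(all(diff(fitnessHistory(sel)) <= 1e-12))
  expect_lt(length(selectedFeatures(sel)), 30)
  expect_gte(length(selectedFeatures(sel)), 1)

  # reproducible under the config seed
  sel2 <- runRDE(fm, config = cfg, fitControl = fitnessControl(seed = 4))
  expect_identical(selectionMask(sel), selectionMask(sel2))

  # maxGen = 0: the SSEoM-filtered binarized best of the initial population
  cfg0 <- deConfig(popSize = 10, dims = 30, maxGen = 0, seed = 3)
  sel0 <- runRDE(fm, config = cfg0, fitControl = fitnessControl(seed = 4))
  expect_length(fitnessHistory(sel0), 1)
  m <- binarizePosition(sel0@position, 0.5)
  m[m] <- sseomFilter(sel0@position[m])
  expect_equal(unname(selectionMask(sel0)), m)

  expect_error(runRDE(fm, config = deConfig(popSize = 10, dims = 7)),
               "dims")
})

test_that("with no signal the selector cannot invent one", {
  fm <- makeFeatureMatrix(nPerClass = 40, nFeatures = 20,
                          nInformative = 5, classSep = 0, seed = 31)
  sel <- runRDE(fm, config = deConfig(popSize = 8, dims = 20,
                                      maxGen = 5, seed = 1),
                fitControl = fitnessControl(seed = 2))
  err <- wrapperFitness(unname(selectionMask(sel)), fm,
                        control = fitnessControl(lambda = 0, seed = 99))
  expect_lt(abs(err - 2 / 3), 0.25)
})
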