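#' Differential evolution configuration
#'
#' Parameters of the reformed differential-evolution (RDE) wrapper
#' selector: a continuous DE searches \[`boundsMin`, `boundsMax`\]^D,
#' each candidate position is binarized at `binarizeCut` to a feature
#' mask for the wrapper objective, and the converged best vector is
#' post-thresholded by the standard-error-of-mean rule
#' ([sseomFilter()]).
#'
#' @param popSize population size P (>= 4; >= 6 for `rand2`, which
#'   needs five distinct partners).
#' @param dims problem dimensionality D (number of candidate features).
#' @param scaleFactor DE scale factor F in (0, 2].
#' @param crossoverRate binomial crossover rate C in \[0, 1\].
#' @param strategy one of `"rand1"`, `"best1"`, `"randtobest1"`,
#'   `"rand2"`.
#' @param maxGen number of generations Y (>= 0).
#' @param boundsMin,boundsMax search-space bounds, `boundsMin <
#'   boundsMax` (or both 0 for the degenerate all-zero space).
#' @param binarizeCut binarization threshold in (0, 1), default 0.5.
#' @param sseomSource `"position"` (literal rule: threshold the best
#'   position's components) or `"importance"` (threshold per-column
#'   eta-squared importance scores instead).
#' @param seed integer seed.
#' @return list of class `deConfig`.
#' @export
deConfig <- function(popSize = 30L, dims, scaleFactor = 0.5,
                     crossoverRate = 0.9,
                     strategy = c("rand1", "best1", "randtobest1", "rand2"),
                     maxGen = 40L, boundsMin = 0, boundsMax = 1,
                     binarizeCut = 0.5,
                     sseomSource = c("position", "importance"),
                     seed = 1L) {
  strategy <- match.arg(strategy)
  sseomSource <- match.arg(sseomSource)
  popSize <- checkCount(popSize, "popSize", 4L)
  dims <- checkCount(dims, "dims", 1L)
  maxGen <- checkCount(maxGen, "maxGen", 0L)
  if (strategy == "rand2" && popSize < 6L)
    stop("strategy 'rand2' needs popSize >= 6 (five distinct partners)",
         call. = FALSE)
  if (scaleFactor < 0 || scaleFactor > 2)
    stop("'scaleFactor' must lie in [0, 2]", call. = FALSE)
  if (crossoverRate < 0 || crossoverRate > 1)
    stop("'crossoverRate' must lie in [0, 1]", call. = FALSE)
  if (boundsMin > boundsMax ||
      (boundsMin == boundsMax && boundsMin != 0))
    stop("'boundsMin' must be below 'boundsMax'", call. = FALSE)
  if (binarizeCut <= 0 || binarizeCut >= 1)
    stop("'binarizeCut' must lie strictly in (0, 1)", call. = FALSE)
  structure(list(popSize = popSize, dims = dims,
                 scaleFactor = scaleFactor, crossoverRate = crossoverRate,
                 strategy = strategy, maxGen = maxGen,
                 boundsMin = boundsMin, boundsMax = boundsMax,
                 binarizeCut = binarizeCut, sseomSource = sseomSource,
                 seed = as.integer(seed)),
            class = "deConfig")
}

#' Initialize a DE population
#'
#' Each component is drawn as `boundsMin + u * (boundsMax - boundsMin)`
#' with `u ~ Uniform(0, 1)` from the current RNG stream.
#'
#' @param config a [deConfig()] list.
#' @return list with `population` (P x D matrix), `fitness` (NA until
#'   evaluated), `bestIndex`, `generation`.
#' @export
deInit <- function(config) {
  pop <- matrix(config$boundsMin +
                  runif(config$popSize * config$dims) *
                  (config$boundsMax - config$boundsMin),
                config$popSize, config$dims)
  list(population = pop, fitness = rep(NA_real_, config$popSize),
       bestIndex = NA_integer_, generation = 0L)
}

#' DE mutation
#'
#' Builds one mutant per population member using the configured
#' strategy (`rand1`: `z_r1 + F (z_r2 - z_r3)`; `best1`:
#' `z_best + F (z_r1 - z_r2)`; `randtobest1`:
#' `z_j + F (z_best - z_j) + F (z_r1 - z_r2)`; `rand2`:
#' `z_r1 + F (z_r2 - z_r3) + F (z_r4 - z_r5)`). Partner indices are
#' mutually distinct and distinct from the target. Mutants are clipped
#' to the search bounds, so every trial vector is evaluable.
#'
#' @param state a DE state (see [deInit()]); `fitness` must be
#'   evaluated when the strategy references the best member.
#' @param config a [deConfig()] list.
#' @return P x D matrix of mutant vectors.
#' @export
deMutate <- function(state, config) {
  P <- nrow(state$population); D <- ncol(state$population)
  needed <- switch(config$strategy, rand1 = 3L, best1 = 2L,
                   randtobest1 = 2L, rand2 = 5L)
  if (P < needed + 1L)
    stop("population too small for strategy '", config$strategy, "'",
         call. = FALSE)
  F <- config$scaleFactor
  M <- matrix(0, P, D)
  for (j in seq_len(P)) {
    r <- sample(setdiff(seq_len(P), j), needed)
    z <- state$population
    M[j, ] <- switch(config$strategy,
      rand1 = z[r[1], ] + F * (z[r[2], ] - z[r[3], ]),
      best1 = z[state$bestIndex, ] + F * (z[r[1], ] - z[r[2], ]),
      randtobest1 = z[j, ] + F * (z[state$bestIndex, ] - z[j, ]) +
        F * (z[r[1], ] - z[r[2], ]),
      rand2 = z[r[1], ] + F * (z[r[2], ] - z[r[3], ]) +
        F * (z[r[4], ] - z[r[5], ]))
  }
  pmin(pmax(M, config$boundsMin), config$boundsMax)
}

#' Binomial crossover
#'
#' Component i of the trial vector comes from the mutant iff
#' `u_i <= C` or `i == i_rand`, where `i_rand` is one uniformly chosen
#' forced index — so every trial inherits at least one mutant
#' component, for any C.
#'
#' @param target,mutant numeric vectors of equal length.
#' @param crossoverRate C in \[0, 1\].
#' @return numeric trial vector.
#' @export
deCrossover <- function(target, mutant, crossoverRate) {
  stopifnot(length(target) == length(mutant))
  D <- length(target)
  iRand <- sample.int(D, 1L)
  fromMutant <- runif(D) <= crossoverRate
  fromMutant[iRand] <- TRUE
  ifelse(fromMutant, mutant, target)
}

#' Greedy DE survivor selection
#'
#' The trial replaces the target iff its fitness is less than or equal
#' to the target's (ties go to the trial).
#'
#' @param target,trial numeric position vectors.
#' @param targetFitness known fitness of the target (avoids
#'   re-evaluation).
#' @param fitnessFn function(position) -> numeric(1), lower is better.
#' @return list with `position`, `fitness`, `accepted`.
#' @export
deSelect <- function(target, trial, targetFitness, fitnessFn) {
  ft <- fitnessFn(trial)
  if (!is.finite(ft) || !is.finite(targetFitness))
    stop("non-finite fitness in selection", call. = FALSE)
  if (ft <= targetFitness)
    list(position = trial, fitness = ft, accepted = TRUE)
  else
    list(position = target, fitness = targetFitness, accepted = FALSE)
}

#' Binarize a continuous position to a feature mask
#'
#' Bit i is set iff component i is at or above `cut`. If no component
#' reaches the cut, the single largest component is set (argmax
#' rescue), so the mask is never empty.
#'
#' @param position numeric vector.
#' @param cut threshold in (0, 1).
#' @return logical mask of the same length.
#' @export
binarizePosition <- function(position, cut = 0.5) {
  stopifnot(cut > 0, cut < 1)
  mask <- position >= cut
  if (!any(mask)) mask[which.max(position)] <- TRUE
  mask
}

#' Standard-error-of-mean (SSEoM) threshold filter
#'
#' Retains component i iff `position[i] >= SM`, where
#' `SM = sd(position) / sqrt(D)` is the standard error of the mean of
#' the vector's components. If no component reaches the threshold the
#' single largest component is retained. The rule is scale-equivariant:
#' scaling the vector by any positive factor leaves the mask unchanged.
#'
#' @param position numeric vector of length >= 2.
#' @return logical mask of the same length.
#' @examples
#' sseomFilter(c(1, 0, 0, 0))  # SM = 0.5/2 = 0.25 -> TRUE FALSE FALSE FALSE
#' @export
sseomFilter <- function(position) {
  D <- length(position)
  if (D < 2L) stop("SSEoM filter needs at least 2 components",
                   call. = FALSE)
  SM <- sd(position) / sqrt(D)
  mask <- position >= SM
  if (!any(mask)) mask[which.max(position)] <- TRUE
  mask
}

# Per-column eta-squared (between-class / total sum of squares) of the
# columns of X against labels y; used by the fusion probabilities and
# the alternative SSEoM source.
etaSquared <- function(X, y) {
  y <- as.factor(y)
  gm <- colMeans(X)
  ssTot <- colSums(sweep(X, 2, gm)^2)
  ssB <- rep(0, ncol(X))
  for (lv in levels(y)) {
    idx <- y == lv
    cm <- colMeans(X[idx, , drop = FALSE])
    ssB <- ssB + sum(idx) * (cm - gm)^2
  }
  out <- ifelse(ssTot > 0, ssB / ssTot, 0)
  unname(out)
}

#' Run the reformed differential-evolution feature selector
#'
#' Continuous DE over \[0, 1\]^D: initialization, then `maxGen`
#' generations of mutation, binomial crossover and greedy selection
#' against the shared wrapper objective ([wrapperFitness()]) of the
#' binarized position. The converged best vector is binarized at
#' `binarizeCut` and its surviving components are post-filtered by the
#' SSEoM rule. The recorded best-fitness history is non-increasing.
#'
#' @param X a [FeatureMatrix-class], or a sample-by-feature matrix.
#' @param y labels when `X` is a plain matrix.
#' @param config a [deConfig()] list; `dims` must equal the feature
#'   count.
#' @param fitControl a [fitnessControl()] list.
#' @return A [SelectionResult-class] with `selector = "rde"`.
#' @export
runRDE <- function(X, y = NULL, config, fitControl = fitnessControl()) {
  if (is(X, "FeatureMatrix")) {
    ids <- featureIds(X); y <- sampleLabels(X); Xv <- featureValues(X)
  } else {
    Xv <- as.matrix(X)
    ids <- colnames(Xv)
    if (is.null(ids)) ids <- sprintf("f%04d", seq_len(ncol(Xv)))
  }
  if (nrow(Xv) < 10L) stop("need at least 10 samples", call. = FALSE)
  if (ncol(Xv) < 2L) stop("need at least 2 features", call. = FALSE)
  if (config$dims != ncol(Xv))
    stop("config$dims (", config$dims, ") must equal ncol(X) (",
         ncol(Xv), ")", call. = FALSE)

  fitnessFn <- function(v)
    wrapperFitness(binarizePosition(v, config$binarizeCut), Xv, y,
                   fitControl)

  withSeed(config$seed, {
    state <- deInit(config)
    state$fitness <- apply(state$population, 1, fitnessFn)
    state$bestIndex <- which.min(state$fitness)
    history <- min(state$fitness)
    for (gen in seq_len(config$maxGen)) {
      M <- deMutate(state, config)
      for (j in seq_len(config$popSize)) {
        trial <- deCrossover(state$population[j, ], M[j, ],
                             config$crossoverRate)
        res <- deSelect(state$population[j, ], trial,
                        state$fitness[j], fitnessFn)
        state$population[j, ] <- res$position
        state$fitness[j] <- res$fitness
      }
      state$bestIndex <- which.min(state$fitness)
      state$generation <- gen
      history <- c(history, min(state$fitness))
    }
    best <- state$population[state$bestIndex, ]
    mask <- binarizePosition(best, config$binarizeCut)
    surviving <- which(mask)
    if (length(surviving) >= 2L) {
      sub <- switch(config$sseomSource,
        position = best[surviving],
        importance = etaSquared(Xv[, surviving, drop = FALSE], y))
      mask[surviving] <- sseomFilter(sub)
    }
    new("SelectionResult", mask = mask, featureIds = ids,
        fitnessHistory = history, fitness = min(state$fitness),
        position = best, selector = "rde")
  })
}
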