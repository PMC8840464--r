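#' Grey-wolf optimizer configuration
#'
#' Parameters of the reformed binary grey-wolf (RBGW) wrapper selector:
#' a pack of bit-vector wolves guided by the three best solutions found
#' so far (alpha, beta, delta). Per dimension each leader proposes a
#' candidate bit through a steep sigmoid transfer, a Bernoulli binary
#' step and an OR-type leader move; the wolf's new bit is a stochastic
#' one-of-three crossover of the candidates.
#'
#' @param packSize number of wolves g (>= 3: alpha, beta and delta must
#'   exist).
#' @param iterations number of optimization iterations Gth (>= 1).
#' @param dims problem dimensionality D.
#' @param transferOffset offset subtracted inside the sigmoid transfer
#'   argument (default 0.5).
#' @param seed integer seed.
#' @return list of class `gwoConfig`.
#' @export
gwoConfig <- function(packSize = 20L, iterations = 40L, dims,
                      transferOffset = 0.5, seed = 1L) {
  packSize <- checkCount(packSize, "packSize", 3L)
  iterations <- checkCount(iterations, "iterations", 1L)
  dims <- checkCount(dims, "dims", 1L)
  structure(list(packSize = packSize, iterations = iterations,
                 dims = dims, transferOffset = transferOffset,
                 seed = as.integer(seed)),
            class = "gwoConfig")
}

#' Steep sigmoid transfer function
#'
#' `1 / (1 + exp(-10 * (arg - offset)))`: maps a continuous step size
#' to a bit-flip probability in (0, 1). Strictly increasing, with value
#' 1/2 at `arg = offset`.
#'
#' @param arg finite numeric (vectorized).
#' @param offset midpoint (default 0.5).
#' @return numeric in (0, 1).
#' @examples
#' sigmoidTransfer(0.5)  # 0.5
#' sigmoidTransfer(0)    # 1 / (1 + e^5)
#' @export
sigmoidTransfer <- function(arg, offset = 0.5) {
  if (any(!is.finite(arg))) stop("'arg' must be finite", call. = FALSE)
  1 / (1 + exp(-10 * (arg - offset)))
}

#' Bernoulli binary step
#'
#' Returns 1 iff the continuous step value is at or above a fresh
#' uniform draw, so the expected bit equals `costep`.
#'
#' @param costep numeric in \[0, 1\] (vectorized).
#' @return integer bits (0/1) of the same length.
#' @export
binaryStep <- function(costep) {
  stopifnot(all(costep >= 0 & costep <= 1))
  as.integer(costep >= runif(length(costep)))
}

#' Leader move: OR of leader bit and binary step
#'
#' The candidate bit is 1 iff `leaderBit + bistep >= 1`, i.e. the
#' logical OR of the two bits.
#'
#' @param leaderBit,bistep 0/1 bits (vectorized).
#' @return integer bits.
#' @export
leaderMove <- function(leaderBit, bistep) {
  stopifnot(all(leaderBit %in% 0:1), all(bistep %in% 0:1))
  as.integer((leaderBit + bistep) >= 1)
}

#' Stochastic one-of-three crossover
#'
#' Per dimension, picks the first candidate with probability 1/3, the
#' second with probability 1/3, the third otherwise.
#'
#' @param u,v,w 0/1 bit vectors of equal length.
#' @return integer bit vector; each output bit equals one of the three
#'   inputs.
#' @export
stochasticCrossover <- function(u, v, w) {
  stopifnot(length(u) == length(v), length(v) == length(w))
  r <- runif(length(u))
  as.integer(ifelse(r < 1 / 3, u, ifelse(r < 2 / 3, v, w)))
}

#' One grey-wolf position update
#'
#' For every dimension and each leader (alpha, beta, delta): the
#' coefficient `A = 2 a r1 - a` and `C = 2 r2` are drawn (`a` decreases
#' linearly from 2 to 0 over iterations), the leader distance is
#' `D = |C * leader - position|`, the continuous step is the sigmoid
#' transfer of `A * D`, the binary step is its Bernoulli realization,
#' and the candidate bit is the OR-type leader move. The new bit is the
#' stochastic crossover of the three candidates. Per-wolf draw order:
#' for each leader `r1` (D draws), `r2` (D), the binary-step uniforms
#' (D); then the crossover uniforms (D).
#'
#' @param position current 0/1 position vector.
#' @param leaders list of three 0/1 vectors (alpha, beta, delta).
#' @param aCoef current value of the decreasing coefficient `a` in
#'   \[0, 2\].
#' @param transferOffset sigmoid offset (default 0.5).
#' @return integer 0/1 vector of the same length.
#' @export
wolfUpdate <- function(position, leaders, aCoef, transferOffset = 0.5) {
  stopifnot(length(leaders) == 3L, aCoef >= 0, aCoef <= 2)
  D <- length(position)
  cand <- vector("list", 3L)
  for (k in 1:3) {
    r1 <- runif(D); r2 <- runif(D)
    A <- 2 * aCoef * r1 - aCoef
    C <- 2 * r2
    dist <- abs(C * leaders[[k]] - position)
    costep <- sigmoidTransfer(A * dist, transferOffset)
    bistep <- binaryStep(costep)
    cand[[k]] <- leaderMove(leaders[[k]], bistep)
  }
  stochasticCrossover(cand[[1]], cand[[2]], cand[[3]])
}

#' Run the reformed binary grey-wolf feature selector
#'
#' Initializes a pack of random bit positions, then for `iterations`
#' rounds updates every wolf with [wolfUpdate()], evaluates the shared
#' wrapper objective ([wrapperFitness()]), and refreshes the three
#' leaders (replaced only by strictly better solutions, so the alpha
#' fitness history is non-increasing). Returns the alpha's mask.
#'
#' @param X a [FeatureMatrix-class], or a sample-by-feature matrix.
#' @param y labels when `X` is a plain matrix.
#' @param config a [gwoConfig()] list; `dims` must equal the feature
#'   count.
#' @param fitControl a [fitnessControl()] list.
#' @return A [SelectionResult-class] with `selector = "rbgw"`.
#' @export
runRBGW <- function(X, y = NULL, config, fitControl = fitnessControl()) {
  if (is(X, "FeatureMatrix")) {
    ids <- featureIds(X); y <- sampleLabels(X); Xv <- featureValues(X)
  } else {
    Xv <- as.matrix(X)
    ids <- colnames(Xv)
    if (is.null(ids)) ids <- sprintf("f%04d", seq_len(ncol(Xv)))
  }
  if (ncol(Xv) < 2L) stop("need at least 2 features", call. = FALSE)
  if (config$dims != ncol(Xv))
    stop("config$dims (", config$dims, ") must equal ncol(X) (",
         ncol(Xv), ")", call. = FALSE)
  g <- config$packSize; D <- config$dims

  fitnessFn <- function(bits) wrapperFitness(bits == 1L, Xv, y, fitControl)

  withSeed(config$seed, {
    pack <- matrix(as.integer(runif(g * D) < 0.5), g, D)
    # a wolf must always select something: rescue with one random bit
    for (j in seq_len(g))
      if (!any(pack[j, ] == 1L)) pack[j, sample.int(D, 1L)] <- 1L
    fit <- apply(pack, 1, fitnessFn)
    ord <- order(fit)
    leaders <- list(pack[ord[1], ], pack[ord[2], ], pack[ord[3], ])
    leaderFit <- fit[ord[1:3]]
    history <- leaderFit[1]

    for (it in seq_len(config$iterations)) {
      aCoef <- 2 - (it - 1) * 2 / config$iterations
      for (j in seq_len(g)) {
        newPos <- wolfUpdate(pack[j, ], leaders, aCoef,
                             config$transferOffset)
        if (!any(newPos == 1L)) newPos[sample.int(D, 1L)] <- 1L
        pack[j, ] <- newPos
        fit[j] <- fitnessFn(newPos)
        # promote into the leader hierarchy when strictly better
        if (fit[j] < leaderFit[1]) {
          leaders <- list(newPos, leaders[[1]], leaders[[2]])
          leaderFit <- c(fit[j], leaderFit[1], leaderFit[2])
        } else if (fit[j] < leaderFit[2]) {
          leaders[[3]] <- leaders[[2]]; leaders[[2]] <- newPos
          leaderFit[3] <- leaderFit[2]; leaderFit[2] <- fit[j]
        } else if (fit[j] < leaderFit[3]) {
          leaders[[3]] <- newPos; leaderFit[3] <- fit[j]
        }
      }
      history <- c(history, leaderFit[1])
    }
    new("SelectionResult", mask = leaders[[1]] == 1L, featureIds = ids,
        fitnessHistory = history, fitness = leaderFit[1],
        position = as.numeric(leaders[[1]]), selector = "rbgw")
  })
}
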