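# Run `expr` under `seed` and restore the caller's RNG stream afterwards,
# so seeded helpers never perturb an enclosing optimizer loop.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Stratified sample of training indices: round(frac * n_k) per class.
stratifiedTrainIdx <- function(y, frac) {
  y <- as.factor(y)
  idx <- integer(0)
  for (lv in levels(y)) {
    k <- which(y == lv)
    nTrain <- round(frac * length(k))
    nTrain <- max(1L, min(length(k) - 1L, nTrain))
    idx <- c(idx, sample(k, nTrain))
  }
  sort(idx)
}

checkCount <- function(x, name, min = 0L) {
  if (length(x) != 1L || is.na(x) || x != as.integer(x) || x < min)
    stop("'", name, "' must be a single integer >= ", min, call. = FALSE)
  as.integer(x)
}
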