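# Weighted summary statistics on discrete atoms. Weights are treated as
# probability masses (normalized internally); they never need to sum to 1 on
# input.

normalize_weights <- function(w) {
  if (any(!is.finite(w)) || any(w < 0)) {
    stop_validation("weights must be finite and nonnegative")
  }
  tot <- sum(w)
  if (tot <= 0) stop_contract("weights must have a positive total")
  w / tot
}

weighted_mean <- function(x, w) {
  sum(normalize_weights(w) * x)
}

# Smallest value s such that the cumulative probability at s is >= 0.5
# (lower / no-interpolation convention; deterministic on discrete atoms).
weighted_median <- function(x, w) {
  p <- normalize_weights(w)
  o <- order(x)
  cum <- cumsum(p[o])
  x[o][which(cum >= 0.5 - 1e-12)[1L]]
}

# Probability-weighted central moments; g1 = m3 / m2^(3/2).
weighted_skewness <- function(x, w) {
  p <- normalize_weights(w)
  mu <- sum(p * x)
  m2 <- sum(p * (x - mu)^2)
  if (m2 <= 0) return(NA_real_)
  m3 <- sum(p * (x - mu)^3)
  m3 / m2^1.5
}

weighted_var <- function(x, w) {
  p <- normalize_weights(w)
  mu <- sum(p * x)
  sum(p * (x - mu)^2)
}

# Weighted Pearson correlation with probability weights; NA (never 0) when
# either column has zero weighted variance.
weighted_pearson <- function(x, y, w) {
  p <- normalize_weights(w)
  mx <- sum(p * x); my <- sum(p * y)
  vx <- sum(p * (x - mx)^2); vy <- sum(p * (y - my)^2)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  sum(p * (x - mx) * (y - my)) / sqrt(vx * vy)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_validation("seed must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
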