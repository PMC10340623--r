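#' Inverse-logit
#'
#' @param x numeric vector on the logit scale.
#' @return probabilities in \[0, 1\].
#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Derive a stage seed from a master seed
#'
#' All randomness in the package flows from one master seed.  Each stage
#' (fold construction, parameter draws, bootstrap replicate, ...) derives
#' its own seed from the master seed, a stage label and an index, so that
#' stages can be re-run independently and in any order while remaining
#' bit-reproducible.  The derivation is a fixed affine hash modulo a
#' Mersenne prime, kept below 2^31 so it is always a valid R seed.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @param index non-negative integer replicate/fold index.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  code <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 99991
  x <- (abs(as.numeric(master)) %% 2147483647) * 1103 +
    code * 7919 + as.numeric(index) * 104729
  as.integer(x %% 2147483629)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Percentile bootstrap interval
#'
#' Empirical percentile bounds (type-7, linearly interpolated quantiles)
#' of a vector of replicate statistics.
#'
#' @param x numeric vector of replicates.
#' @param level coverage level in (0, 1), default 0.95.
#' @return named numeric vector with elements `lower` and `upper`.
#' @export
percentile_ci <- function(x, level = 0.95) {
  stopifnot(is.numeric(x), length(x) >= 2L, level > 0, level < 1)
  alpha <- (1 - level) / 2
  q <- stats::quantile(x, c(alpha, 1 - alpha), type = 7, names = FALSE)
  c(lower = q[1], upper = q[2])
}

# Sample standard deviation (n - 1 denominator); 0 for length-1 input.
sample_sd <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

# Dispersion of a partial-dependence curve: sample sd for continuous
# grids, (max - min) / 4 for categorical grids.
pd_dispersion <- function(values, categorical) {
  if (categorical) (max(values) - min(values)) / 4 else sample_sd(values)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Column-wise centring/scaling via recycling (much faster than scale()
# for the wide matrices used in stacked PDP evaluation).
scale_columns <- function(X, center, scale) {
  n <- nrow(X)
  X <- X - rep(center, each = n)
  X / rep(scale, each = n)
}

iso_time <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
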