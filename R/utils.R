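# Internal helpers: seeding, local RNG scope, numeric utilities.

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministically maps a master seed plus one or more integer indices
#' (subject, run, region, ...) to a new seed below 2^31, so that every
#' simulated unit gets an independent, reproducible random substream.
#'
#' @param master_seed Integer master seed.
#' @param ... Integer indices identifying the substream.
#' @return A single integer seed in `[1, 2^31 - 1]`.
#' @export
#' @examples
#' derive_seed(1, 3, 2)
derive_seed <- function(master_seed, ...) {
  idx <- c(...)
  x <- as.double(master_seed) %% 2147483647
  for (i in idx) {
    # 64-bit-safe multiplicative mixing kept under 2^31 via modulus
    x <- (x * 48271 + as.double(i) * 16807 + 1) %% 2147483647
  }
  as.integer(x + 1)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

# Clip values into [lo, hi].
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# log-sum-exp, numerically stable
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# First difference x_{t+1} - x_t aligned to trial t (last element NA),
# the "current trial to the next" convention used by the coupling analyses.
delta_next <- function(x) c(diff(x), NA_real_)

# First difference x_t - x_{t-1} aligned to trial t (first element NA),
# the "current trial minus previous" convention for entropy-change regressors.
delta_prev <- function(x) c(NA_real_, diff(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
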