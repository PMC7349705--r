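#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == floor(x)

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x <= 1

#' Moments of a truncated normal distribution
#'
#' Mean and variance of N(mu, sd^2) truncated to \[lo, hi\].  Used to anchor
#' the cohort generator's intercepts and to derive its variance components
#' analytically, so configured population means are hit exactly.
#'
#' @param mu,sd mean and SD of the parent normal.
#' @param lo,hi truncation bounds.
#' @return list with elements `mean` and `var`.
#' @keywords internal
trunc_norm_moments <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  fa <- stats::dnorm(a)
  fb <- stats::dnorm(b)
  m <- mu + sd * (fa - fb) / z
  v <- sd^2 * (1 + (a * fa - b * fb) / z - ((fa - fb) / z)^2)
  list(mean = m, var = v)
}

## Draw from a truncated normal by inverse-CDF so results are a pure function
## of the RNG stream (no rejection loop of data-dependent length).
rtruncnorm <- function(n, mu, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mu, sd), stats::pnorm(hi, mu, sd))
  stats::qnorm(u, mu, sd)
}

## Derive a per-stage 31-bit seed from a master seed without disturbing the
## caller's RNG state more than once.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
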