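#' Root-mean-square of a signal
#'
#' @param x numeric vector.
#' @return A single non-negative number, `sqrt(mean(x^2))`.
#' @export
rms <- function(x) sqrt(mean(x^2))

#' Derive a reproducible child seed from a master seed
#'
#' Streams of randomness (per dataset, per grid cell, per permutation block)
#' are derived from one master seed by folding integer counters through a
#' Lehmer-style multiplicative congruence, so that any cell of a study can be
#' re-run in isolation and reproduce its draws exactly.  The result always
#' lies in `[1, 2^31 - 2]`.
#'
#' @param ... integer counters, e.g. `derive_seed(master, dataset, cell)`.
#' @return A single integer seed.
#' @export
derive_seed <- function(...) {
  ids <- c(...)
  stopifnot(length(ids) >= 1, all(is.finite(ids)))
  m <- 2147483647
  s <- 0
  for (k in ids) {
    s <- (s * 48271 + (abs(k) %% m) + 1) %% m
  }
  as.integer(s %% (m - 1) + 1)
}

# Evaluate `code` under `seed` if non-NULL, leaving the caller's RNG state
# untouched; otherwise use the current RNG stream.
with_seed_or_current <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Map angles into (-pi, pi]; Arg() returns [-pi, pi], so only the lower
# boundary needs wrapping.
wrap_phase <- function(theta) {
  theta <- ((theta + pi) %% (2 * pi)) - pi
  theta[theta == -pi] <- pi
  theta
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}
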