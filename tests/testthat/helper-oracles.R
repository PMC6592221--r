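# Naive reference implementations: direct loops over the defining formulas,
# kept deliberately independent of the package's vectorized code paths.

naive_hilbert <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  for (k in seq_len(n)) {
    idx <- k - 1
    if (idx == 0) h[k] <- 1
    else if (n %% 2 == 0 && idx == n / 2) h[k] <- 1
    else if (idx < n / 2) h[k] <- 2
    else h[k] <- 0
  }
  fft(X * h, inverse = TRUE) / n
}

naive_plv <- function(phase, amp) {
  theta_u <- Arg(naive_hilbert(amp))
  acc <- 0 + 0i
  for (t in seq_along(phase)) {
    acc <- acc + exp(1i * (phase[t] - theta_u[t]))
  }
  Mod(acc / length(phase))
}

naive_mvl <- function(phase, amp) {
  acc <- 0 + 0i
  for (t in seq_along(phase)) {
    acc <- acc + amp[t] * exp(1i * phase[t])
  }
  Mod(acc / length(phase))
}

naive_direct_mvl <- function(phase, amp) {
  num <- 0 + 0i
  den <- 0
  for (t in seq_along(phase)) {
    num <- num + amp[t] * exp(1i * phase[t])
    den <- den + amp[t]^2
  }
  Mod(num) / sqrt(length(phase) * den)
}

naive_mi <- function(phase, amp, n_bins = 18) {
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  abar <- numeric(n_bins)
  for (j in seq_len(n_bins)) {
    if (j < n_bins) {
      sel <- phase >= edges[j] & phase < edges[j + 1]
    } else {
      sel <- phase >= edges[j] & phase <= edges[j + 1]
    }
    abar[j] <- mean(amp[sel])
  }
  p <- abar / sum(abar)
  h <- 0
  for (j in seq_len(n_bins)) {
    if (p[j] > 0) h <- h - p[j] * log(p[j])
  }
  (log(n_bins) - h) / log(n_bins)
}

# Small random phase/amplitude series with all bins populated.
random_phase_amp <- function(n, seed) {
  withr::with_seed(seed, {
    list(phase = runif(n, -pi, pi) |> (\(x) { x[x == -pi] <- pi; x })(),
         amplitude = abs(rnorm(n)) + 0.05)
  })
}

toy_trials <- function(phase, amplitude, trial = NULL, fs = 1000) {
  as_pac_trials(
    data.frame(phase = phase, amplitude = amplitude,
               trial = trial %||% rep(1L, length(phase))),
    fs = fs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
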