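# Small shared numeric helpers.

# Quartiles by the ideal-fourths (Hoaglin) estimator; returns c(q1, q3).
ideal_fourths <- function(x) {
  x <- sort(x)
  n <- length(x)
  j <- floor(n / 4 + 5 / 12)
  g <- n / 4 + 5 / 12 - j
  q1 <- (1 - g) * x[j] + g * x[j + 1]
  k <- n - j + 1
  q3 <- (1 - g) * x[k] + g * x[k - 1]
  c(q1, q3)
}

# Run body with a locally-seeded RNG when seed is non-NULL.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Time axis in seconds: half-open [window[1], window[2]), t = 0 on the grid.
epoch_time_axis <- function(window, sampling_rate) {
  n_pre <- round(-window[1] * sampling_rate)
  n_post <- round(window[2] * sampling_rate)
  seq.int(-n_pre, n_post - 1L) / sampling_rate
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a single finite number.", name))
  }
}
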