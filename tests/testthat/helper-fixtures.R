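# Shared fixtures built in code; nothing is read from disk.

# A small, fast simulation configuration for structural tests.
small_config <- function(...) {
  defaults <- list(n_per_group = 5, n_epochs_per_session = 6,
                   sampling_rate = 250, artifact_rate = 0)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# Single-channel recording carrying a sum of sinusoids (amplitudes in uV).
sine_recording <- function(freqs, amps, fs = 500, dur = 8, channel = "Cz",
                           dc = 0) {
  t <- seq_len(fs * dur) / fs
  x <- rep(dc, length(t))
  for (i in seq_along(freqs)) x <- x + amps[i] * sin(2 * pi * freqs[i] * t)
  eeg_recording(matrix(x, nrow = 1), channel, fs)
}

rms <- function(x) sqrt(mean(x^2))

# Amplitude of a single frequency component via the DFT bin (dur must make
# freq an exact bin).
component_amplitude <- function(x, freq, fs) {
  n <- length(x)
  k <- round(freq * n / fs)
  2 * Mod(stats::fft(x))[k + 1] / n
}

# Epochs with specified constant dB power per channel (for index tests):
# builds an alpha_power_map-like object directly.
constant_power_map <- function(values_by_channel, fs = 500,
                               window = c(-1, 1)) {
  time <- seq(window[1], window[2] - 1 / fs, by = 1 / fs)
  channels <- names(values_by_channel)
  power <- matrix(unlist(values_by_channel), nrow = length(channels),
                  ncol = length(time))
  structure(
    list(power = power, time = time, valid = rep(TRUE, length(time)),
         channels = channels, freq_band = c(8, 12), n_epochs_used = 60,
         subject_id = "SX", session = "pre"),
    class = "alpha_power_map"
  )
}

full_montage_map <- function(temporal_db = 0, cf_db = 0, other_db = 0) {
  ch <- montage_channels_32()
  vals <- stats::setNames(rep(other_db, length(ch)), ch)
  vals[region_definition("temporal")$channels] <- temporal_db
  vals[region_definition("central_frontal")$channels] <- cf_db
  constant_power_map(as.list(vals))
}

# Independent exhaustive MCD oracle (plain loops, no shared code paths).
oracle_mcd <- function(points, h) {
  combs <- utils::combn(nrow(points), h)
  best <- Inf; best_idx <- NULL
  for (j in seq_len(ncol(combs))) {
    s <- stats::cov(points[combs[, j], , drop = FALSE])
    dt <- s[1, 1] * s[2, 2] - s[1, 2]^2
    if (dt < best) {
      best <- dt
      best_idx <- combs[, j]
    }
  }
  list(subset = sort(best_idx), det = best)
}

# Long change-score table with planted per-cell correlations for battery
# structure tests.
toy_changes <- function(n = 12, groups = c("PMC", "M1", "Sham"), seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    for (g in groups) {
      ids <- sprintf("%s%02d", g, seq_len(n))
      for (m in c("temporal_alpha", "central_frontal_alpha", "alpha_ratio",
                  clinical_outcomes())) {
        rows[[paste(g, m)]] <- tibble::tibble(
          subject_id = ids, group = g, metric = m, delta = stats::rnorm(n)
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}
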