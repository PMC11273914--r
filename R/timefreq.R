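#' Morlet-wavelet power of response-locked epochs
#'
#' Frequency-domain Morlet decomposition: each epoch is zero-padded to
#' `pad_ratio` times its length, FFT-transformed once per channel, and
#' multiplied by a Gaussian frequency response centred on each analysis
#' frequency, confined to positive frequencies. The spectral width is held
#' constant across the band at `centre / cycles` (the Fourier pair of a
#' Morlet wavelet with `cycles` cycles at the band centre), so white noise
#' produces the same expected power at every analysis frequency while a
#' sinusoid at any centre frequency still recovers its amplitude exactly.
#' The complex amplitudes are doubled (one-sided spectrum convention, so a
#' cosine of amplitude A recovers amplitude A), squared into power, and
#' averaged across artifact-free epochs. Samples within one wavelet
#' half-width (3 temporal SDs) of either epoch edge are marked invalid and
#' excluded from every downstream window.
#'
#' @param epochs An [eeg_epochs()] with at least one clean epoch.
#' @param freqs Analysis frequencies in Hz, all below Nyquist.
#' @param cycles Wavelet cycles at the band centre; the common spectral SD
#'   is `mean(range(freqs)) / cycles`.
#' @param pad_ratio Zero-padding factor for each analysis segment.
#' @return List with `power` (`channels x freqs x time`, epoch-averaged
#'   microvolts squared), `freqs`, `time`, `valid` (logical per sample),
#'   `channels`, `n_epochs_used`.
#' @examples
#' cfg <- simulation_config(n_epochs_per_session = 2)
#' ep <- simulate_subject_epochs(cfg, seed = 1)
#' wp <- wavelet_power(ep, freqs = 10)
#' dim(wp$power)
#' @export
wavelet_power <- function(epochs, freqs = 8:12, cycles = 5, pad_ratio = 4) {
  fs <- epochs$sampling_rate
  if (any(freqs <= 0) || any(freqs >= fs / 2)) {
    rlang::abort("`freqs` must lie strictly between 0 and Nyquist.",
                 class = "alphagate_parameter_error")
  }
  keep <- which(!epochs$artifact_flags)
  if (length(keep) == 0L) {
    rlang::abort("no clean epochs to decompose.",
                 class = "alphagate_parameter_error")
  }
  d <- dim(epochs$data)
  n_s <- d[3]
  L <- as.integer(pad_ratio * n_s)
  fgrid <- fft_freqs(L, fs)

  # Gaussian response per frequency with a common spectral width, zero at
  # non-positive frequencies.
  sf <- mean(range(freqs)) / cycles
  W <- vapply(freqs, function(f0) {
    w <- exp(-(fgrid - f0)^2 / (2 * sf^2))
    w[fgrid <= 0] <- 0
    w
  }, numeric(L))

  power <- array(0, dim = c(d[2], length(freqs), n_s))
  pad <- matrix(0, nrow = L, ncol = d[2])
  for (e in keep) {
    pad[] <- 0
    pad[seq_len(n_s), ] <- t(matrix(epochs$data[e, , ], nrow = d[2]))
    X <- stats::mvfft(pad)
    for (fi in seq_along(freqs)) {
      Y <- stats::mvfft(X * W[, fi], inverse = TRUE) / L
      amp2 <- 4 * Mod(Y[seq_len(n_s), , drop = FALSE])^2
      power[, fi, ] <- power[, fi, ] + t(amp2)
    }
  }
  power <- power / length(keep)

  half_width <- ceiling(3 / (2 * pi * sf) * fs)
  valid <- rep(TRUE, n_s)
  if (half_width >= 1) {
    valid[seq_len(min(half_width, n_s))] <- FALSE
    valid[seq.int(max(1L, n_s - half_width + 1L), n_s)] <- FALSE
  }
  list(power = power, freqs = as.numeric(freqs), time = epochs$time,
       valid = valid, channels = epochs$channels,
       n_epochs_used = length(keep))
}

#' Participant-level median-scaled log (dB) transform
#'
#' Converts absolute power to decibels relative to the participant-session
#' median: for every channel x frequency, `10 * log10(power / m)` where `m`
#' is the median of that channel-frequency power over all valid time
#' samples. No pre-stimulus baseline is involved, and the transform is
#' invariant to any overall gain applied to the raw signal. Non-positive
#' power values (possible only in degenerate inputs) are floored to the
#' smallest positive value present, with a warning stating the count.
#'
#' @param power `channels x freqs x time` array of power.
#' @param valid Logical vector over time samples used for the median
#'   (default all).
#' @return Array of the same shape, in dB.
#' @export
median_log_scale <- function(power, valid = rep(TRUE, dim(power)[3])) {
  nonpos <- power <= 0
  if (any(nonpos)) {
    pos <- power[!nonpos]
    floor_val <- if (length(pos)) min(pos) else .Machine$double.xmin
    rlang::warn(sprintf("%d non-positive power value(s) floored before log.",
                        sum(nonpos)))
    power[nonpos] <- floor_val
  }
  d <- dim(power)
  out <- power
  for (ci in seq_len(d[1])) {
    for (fi in seq_len(d[2])) {
      m <- stats::median(power[ci, fi, valid])
      out[ci, fi, ] <- 10 * log10(power[ci, fi, ] / m)
    }
  }
  out
}

#' Average power over a closed frequency band
#'
#' @param power `channels x freqs x time` array.
#' @param freqs Frequencies (Hz) of the second dimension.
#' @param band Closed band limits in Hz.
#' @return `channels x time` matrix, the unweighted mean over in-band
#'   frequencies.
#' @export
band_average <- function(power, freqs, band = c(8, 12)) {
  sel <- which(freqs >= band[1] & freqs <= band[2])
  if (length(sel) == 0L) {
    rlang::abort("no computed frequencies inside the requested band.",
                 class = "alphagate_parameter_error")
  }
  apply(power[, sel, , drop = FALSE], c(1, 3), mean)
}

#' Alpha-power map of one subject-session
#'
#' Full power stage: Morlet decomposition, participant-level median-scaled
#' dB transform per channel and frequency, then the unweighted mean over the
#' alpha band. Returns an `alpha_power_map` object holding the
#' `channels x time` dB matrix.
#'
#' @param epochs An [eeg_epochs()] of clean epochs.
#' @param freqs Analysis frequencies, Hz.
#' @param band Alpha band limits, Hz.
#' @param cycles,pad_ratio Wavelet parameters, see [wavelet_power()].
#' @return An `alpha_power_map`: list with `power` (channels x time, dB),
#'   `time`, `valid`, `channels`, `freq_band`, `n_epochs_used`,
#'   `subject_id`, `session`.
#' @export
alpha_power_map <- function(epochs, freqs = 8:12, band = c(8, 12),
                            cycles = 5, pad_ratio = 4) {
  wp <- wavelet_power(epochs, freqs = freqs, cycles = cycles,
                      pad_ratio = pad_ratio)
  dB <- median_log_scale(wp$power, wp$valid)
  alpha <- band_average(dB, wp$freqs, band)
  structure(
    list(power = alpha, time = wp$time, valid = wp$valid,
         channels = wp$channels, freq_band = band,
         n_epochs_used = wp$n_epochs_used,
         subject_id = epochs$subject_id, session = epochs$session),
    class = "alpha_power_map"
  )
}

#' @export
print.alpha_power_map <- function(x, ...) {
  cat(sprintf(
    "<alpha_power_map> %s/%s: %d channels x %d samples, %g-%g Hz, %d epochs\n",
    x$subject_id, x$session, nrow(x$power), ncol(x$power),
    x$freq_band[1], x$freq_band[2], x$n_epochs_used))
  invisible(x)
}

#' Tidy an alpha-power map into a long tibble
#'
#' @param x An `alpha_power_map`.
#' @param ... Unused.
#' @return Tibble with columns `channel`, `time`, `power_db`, `valid`.
#' @export
tidy.alpha_power_map <- function(x, ...) {
  tibble::tibble(
    channel = rep(x$channels, times = ncol(x$power)),
    time = rep(x$time, each = nrow(x$power)),
    power_db = as.vector(x$power),
    valid = rep(x$valid, each = nrow(x$power))
  )
}
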