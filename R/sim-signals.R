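# Elementary signal generators for the forward model. All amplitudes in
# microvolts, all durations in samples.

# 1/f^exponent background noise via spectral synthesis, scaled to target RMS.
pink_noise <- function(n, exponent = 1, rms = 1) {
  nf <- floor(n / 2)
  freqs <- seq_len(nf)
  amp <- freqs^(-exponent / 2)
  phases <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phases)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  # conjugate symmetry for a real signal
  full[n:(n - nf + 2)] <- Conj(spec[seq_len(nf - 1)])
  x <- Re(stats::fft(full, inverse = TRUE))
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x * (rms / s)
}

# Band-limited gaussian noise with raised-cosine band edges (in Hz).
narrowband_noise <- function(n, sampling_rate, band, transition = 0.5, rms = 1) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- fft_freqs(n, sampling_rate)
  H <- raised_cosine_band(abs(f), band[1], band[2], transition, transition)
  y <- Re(stats::fft(X * H, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(numeric(n))
  (y - mean(y)) * (rms / s)
}

# Slowly varying positive amplitude envelope with mean-square one, so that
# multiplying a unit-RMS carrier keeps unit RMS on average.
burst_envelope <- function(n, sampling_rate, cutoff = 1.5) {
  e <- narrowband_noise(n, sampling_rate, c(0.05, cutoff), transition = 0.05, rms = 1)
  env <- pmax(0, 1 + 0.6 * e)
  env / sqrt(mean(env^2))
}

# Amplitude-modulated alpha-band noise: the oscillatory component of one
# channel. Realistic trial-to-trial power variance comes from the envelope.
alpha_burst_signal <- function(n, sampling_rate, band, rms) {
  carrier <- narrowband_noise(n, sampling_rate, band, rms = 1)
  env <- burst_envelope(n, sampling_rate)
  y <- carrier * env
  y * (rms / sqrt(mean(y^2)))
}

# FFT bin frequencies (signed, Hz).
fft_freqs <- function(n, sampling_rate) {
  k <- seq_len(n) - 1L
  k[k > n / 2] <- k[k > n / 2] - n
  k * sampling_rate / n
}

# Real, zero-phase band response: unity in [f1, f2], raised-cosine rolloff of
# width wl below f1 and wh above f2, zero beyond.
raised_cosine_band <- function(f, f1, f2, wl, wh) {
  H <- numeric(length(f))
  H[f >= f1 & f <= f2] <- 1
  lo <- f < f1 & f > f1 - wl
  H[lo] <- 0.5 * (1 + cos(pi * (f1 - f[lo]) / wl))
  hi <- f > f2 & f < f2 + wh
  H[hi] <- 0.5 * (1 + cos(pi * (f[hi] - f2) / wh))
  H
}

# Stereotyped blink transient: positive bump of ~300 ms (gaussian), peak
# `amplitude` microvolts, returned as a length-n vector centred at sample k.
blink_waveform <- function(n, sampling_rate, center, amplitude = 250,
                           width_s = 0.08) {
  t <- (seq_len(n) - center) / sampling_rate
  amplitude * exp(-t^2 / (2 * width_s^2))
}

# Frontal-dominant spatial pattern of a blink over the given channel names.
blink_topography <- function(channels) {
  w <- rep(0.05, length(channels))
  names(w) <- channels
  w[channels %in% c("Fp1", "Fp2")] <- 1
  w[channels %in% c("F7", "F3", "Fz", "F4", "F8")] <- 0.45
  w[channels %in% c("FC5", "FC1", "FC2", "FC6")] <- 0.2
  w[channels %in% c("VEOG")] <- 1.6
  w[channels %in% c("HEOG")] <- 0.35
  w
}
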