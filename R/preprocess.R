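#' Zero-phase band-pass filter of a continuous recording
#'
#' Applies a real, zero-phase frequency response to every channel: unity in
#' the passband, raised-cosine transitions, zero beyond. The low-edge
#' transition occupies `[low/2, low]` and the high-edge transition
#' `[high, high + high/2]`, so attenuation at `low/2` and at `2*high` is
#' complete while mid-band gain is exactly 1. The recording is
#' reflection-padded before the FFT to suppress circular wrap-around.
#'
#' @param raw An [eeg_recording()].
#' @param low,high Band edges in Hz; `0 < low < high < sampling_rate/2`.
#' @return The filtered [eeg_recording()].
#' @examples
#' fs <- 250
#' x <- matrix(sin(2 * pi * 10 * seq_len(fs * 4) / fs), nrow = 1)
#' rec <- eeg_recording(x, "Cz", fs)
#' filt <- bandpass_filter(rec, 0.5, 40)
#' sd(filt$data) / sd(rec$data)  # ~1: 10 Hz is mid-band
#' @export
bandpass_filter <- function(raw, low = 0.5, high = 40) {
  fs <- raw$sampling_rate
  if (!(low > 0 && low < high && high < fs / 2)) {
    rlang::abort("band must satisfy 0 < low < high < sampling_rate/2.",
                 class = "alphagate_parameter_error")
  }
  n <- ncol(raw$data)
  npad <- min(n - 1L, ceiling(2 * fs / low))
  ntot <- n + 2L * npad
  f <- abs(fft_freqs(ntot, fs))
  H <- raised_cosine_band(f, low, high, wl = low / 2, wh = high / 2)
  out <- raw
  for (ci in seq_len(nrow(raw$data))) {
    x <- raw$data[ci, ]
    xp <- c(rev(x[seq_len(npad) + 1L]), x, rev(x[(n - npad):(n - 1L)]))
    y <- Re(stats::fft(stats::fft(xp) * H, inverse = TRUE)) / ntot
    out$data[ci, ] <- y[(npad + 1L):(npad + n)]
  }
  out
}

#' Remove power-line noise by sliding-window sinusoid regression
#'
#' Within overlapping windows, the line-frequency component is estimated by
#' least squares on a sine/cosine pair and the Hann-weighted estimates are
#' overlap-added into a continuous line-noise signal which is subtracted.
#' Because the estimate is confined to the exact line frequency, spectral
#' neighbours are essentially untouched, unlike a fixed notch.
#'
#' @param raw An [eeg_recording()].
#' @param line_freq Line frequency in Hz (50 or 60).
#' @param window_s Analysis window length in seconds (50% overlap).
#' @return The cleaned [eeg_recording()].
#' @export
remove_line_noise <- function(raw, line_freq = 60, window_s = 4) {
  if (!line_freq %in% c(50, 60)) {
    rlang::abort("`line_freq` must be 50 or 60 Hz.",
                 class = "alphagate_parameter_error")
  }
  fs <- raw$sampling_rate
  n <- ncol(raw$data)
  wl <- min(n, round(window_s * fs))
  hop <- max(1L, wl %/% 2L)
  starts <- seq.int(1L, max(1L, n - wl + 1L), by = hop)
  if (utils::tail(starts, 1L) + wl - 1L < n) starts <- c(starts, n - wl + 1L)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(wl) - 1L) / wl)  # periodic Hann
  tt <- seq_len(wl) / fs
  B <- cbind(cos(2 * pi * line_freq * tt), sin(2 * pi * line_freq * tt))
  BtBinv <- solve(crossprod(B))
  out <- raw
  for (ci in seq_len(nrow(raw$data))) {
    x <- raw$data[ci, ]
    est <- numeric(n)
    wsum <- numeric(n)
    for (s in starts) {
      idx <- s:(s + wl - 1L)
      coef <- BtBinv %*% crossprod(B, x[idx])
      est[idx] <- est[idx] + win * drop(B %*% coef)
      wsum[idx] <- wsum[idx] + win
    }
    ok <- wsum > 1e-8
    est[ok] <- est[ok] / wsum[ok]
    out$data[ci, ] <- x - est
  }
  out
}

#' Cut response-locked epochs for contralesional responses
#'
#' Selects events whose `response_hand` matches the hand contralateral to
#' the lesioned hemisphere (see [contralesional_hand()]) and slices epochs
#' on the half-open window `[window[1], window[2])` around each event
#' sample. Events too close to the recording edges are dropped with a
#' warning. Slicing never alters sample values.
#'
#' @param raw An [eeg_recording()] whose events carry `response_hand`.
#' @param lesion_side `"left"` or `"right"`; defaults to the recording's.
#' @param window Epoch limits in seconds relative to the event.
#' @return An [eeg_epochs()] object, epochs in event-time order.
#' @export
extract_epochs <- function(raw, lesion_side = raw$lesion_side,
                           window = c(-1, 1)) {
  hand <- contralesional_hand(lesion_side)
  ev <- raw$events
  ev <- ev[!is.na(ev$response_hand) & ev$response_hand == hand, , drop = FALSE]
  if (nrow(ev) == 0L) {
    rlang::abort("no qualifying contralesional response events.",
                 class = "alphagate_empty_epochs_error")
  }
  ev <- ev[order(ev$sample), , drop = FALSE]
  fs <- raw$sampling_rate
  time <- epoch_time_axis(window, fs)
  n_pre <- round(-window[1] * fs)
  n_post <- round(window[2] * fs)
  n <- ncol(raw$data)
  ok <- ev$sample - n_pre >= 1L & ev$sample + n_post - 1L <= n
  if (any(!ok)) {
    rlang::warn(sprintf("%d event(s) too close to the recording edge dropped.",
                        sum(!ok)))
    ev <- ev[ok, , drop = FALSE]
  }
  if (nrow(ev) == 0L) {
    rlang::abort("no qualifying events fit inside the recording.",
                 class = "alphagate_empty_epochs_error")
  }
  data <- array(0, dim = c(nrow(ev), nrow(raw$data), length(time)))
  for (e in seq_len(nrow(ev))) {
    idx <- (ev$sample[e] - n_pre):(ev$sample[e] + n_post - 1L)
    data[e, , ] <- raw$data[, idx]
  }
  eeg_epochs(data, raw$channels, fs, time,
             subject_id = raw$subject_id, session = raw$session,
             lesion_side = lesion_side, reference_state = raw$reference_state)
}

#' Re-reference epochs to linked mastoids
#'
#' Subtracts the mean of the two mastoid channels from every channel at each
#' sample and updates the reference state. With silent mastoids this is the
#' identity, and the operation is idempotent once the mastoids are zeroed.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param mastoids Two mastoid channel labels.
#' @return The re-referenced [eeg_epochs()].
#' @export
rereference_linked_mastoids <- function(epochs, mastoids = mastoid_channels()) {
  idx <- match(mastoids, epochs$channels)
  if (anyNA(idx)) {
    rlang::abort(paste0("mastoid channel(s) not found: ",
                        paste(mastoids[is.na(idx)], collapse = ", ")),
                 class = "alphagate_config_error")
  }
  ref <- (epochs$data[, idx[1], , drop = FALSE] +
            epochs$data[, idx[2], , drop = FALSE]) / 2
  epochs$data <- epochs$data - ref[, rep(1, dim(epochs$data)[2]), , drop = FALSE]
  epochs$reference_state <- "linked-mastoids"
  epochs
}

#' Remove ocular artifacts via a pluggable linear decomposition
#'
#' Decomposes the scalp channels with an injectable linear unmixing (default:
#' principal components of the channel covariance, which capture
#' high-variance stereotyped blink activity), removes every component whose
#' time course correlates with any EOG channel beyond `threshold` in
#' absolute value, and reconstructs. If the decomposition fails, or
#' `backend = "regression"`, each scalp channel is instead cleaned by
#' subtracting its least-squares fit on the EOG channels.
#'
#' @param epochs An [eeg_epochs()] object containing the EOG channels.
#' @param eog EOG channel labels (>= 1 present).
#' @param threshold Absolute correlation above which a component is removed.
#' @param backend `"pca"`, `"regression"`, or a function taking the
#'   centred `samples x channels` scalp matrix and returning
#'   `list(sources, mixing)` with `X ~ sources %*% mixing`.
#' @return List with `epochs` (cleaned), `n_components_removed`, and
#'   `method` actually used.
#' @export
remove_ocular_artifacts <- function(epochs, eog = eog_channels(),
                                    threshold = 0.7, backend = "pca") {
  eog <- intersect(eog, epochs$channels)
  if (length(eog) < 1L) {
    rlang::abort("at least one EOG channel is required.",
                 class = "alphagate_config_error")
  }
  d <- dim(epochs$data)
  scalp <- setdiff(epochs$channels, eog)
  si <- match(scalp, epochs$channels)
  ei <- match(eog, epochs$channels)

  # samples*epochs x channels matrices (epochs concatenated in time)
  flatten <- function(idx) {
    m <- aperm(epochs$data[, idx, , drop = FALSE], c(3, 1, 2))
    dim(m) <- c(d[3] * d[1], length(idx))
    m
  }
  X <- flatten(si)
  E <- flatten(ei)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)

  decomposition <- NULL
  method <- if (is.function(backend)) "custom" else backend
  if (method != "regression") {
    fn <- if (is.function(backend)) backend else pca_backend
    decomposition <- tryCatch(fn(Xc), error = function(e) {
      rlang::warn(paste0("decomposition failed (", conditionMessage(e),
                         "); falling back to EOG regression."))
      NULL
    })
    if (!is.null(decomposition)) {
      check <- c("sources", "mixing") %in% names(decomposition)
      if (!all(check)) {
        rlang::warn("backend did not return sources/mixing; falling back to EOG regression.")
        decomposition <- NULL
      }
    }
  }

  if (!is.null(decomposition)) {
    S <- decomposition$sources
    A <- decomposition$mixing
    cors <- suppressWarnings(abs(stats::cor(S, E)))
    cors[is.na(cors)] <- 0
    bad <- which(apply(cors, 1, max) > threshold)
    n_removed <- length(bad)
    if (n_removed > 0) {
      Xc <- Xc - S[, bad, drop = FALSE] %*% A[bad, , drop = FALSE]
    }
    used <- if (method == "custom") "custom" else "pca"
  } else {
    # regression on EOG: remove the EOG-predicted part of each scalp channel
    Ec <- sweep(E, 2, colMeans(E))
    beta <- solve(crossprod(Ec), crossprod(Ec, Xc))
    Xc <- Xc - Ec %*% beta
    n_removed <- ncol(Ec)
    used <- "regression"
  }

  Xclean <- sweep(Xc, 2, mu, `+`)
  dim(Xclean) <- c(d[3], d[1], length(si))
  epochs$data[, si, ] <- aperm(Xclean, c(2, 3, 1))
  list(epochs = epochs, n_components_removed = n_removed, method = used)
}

# Principal-component backend: orthonormal rotation of the centred scalp
# matrix. mixing rows are component topographies.
pca_backend <- function(Xc) {
  V <- eigen(crossprod(Xc) / (nrow(Xc) - 1), symmetric = TRUE)$vectors
  list(sources = Xc %*% V, mixing = t(V))
}

#' Flag artifact epochs by peak-to-peak amplitude
#'
#' Marks an epoch as an artifact when its peak-to-peak amplitude on any
#' scalp channel exceeds `ptp_limit` (default 150 microvolts, a conventional
#' epoch-rejection bound). Flags are OR-ed with any existing flags.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param ptp_limit Peak-to-peak limit in microvolts.
#' @param exclude Channels ignored by the criterion (default the EOG pair).
#' @return The [eeg_epochs()] with updated `artifact_flags`.
#' @export
flag_artifact_epochs <- function(epochs, ptp_limit = 150,
                                 exclude = eog_channels()) {
  keep <- which(!epochs$channels %in% exclude)
  d <- dim(epochs$data)
  ptp <- vapply(seq_len(d[1]), function(e) {
    m <- matrix(epochs$data[e, keep, , drop = FALSE], nrow = length(keep))
    max(apply(m, 1, function(z) diff(range(z))))
  }, numeric(1))
  epochs$artifact_flags <- epochs$artifact_flags | (ptp > ptp_limit)
  epochs
}

#' Keep artifact-free epochs and enforce the minimum-epoch rule
#'
#' Drops flagged epochs and refuses the subject-session when fewer than
#' `minimum` clean epochs survive (the qualification rule for entering the
#' power analysis). The error carries the surviving count.
#'
#' @param epochs An [eeg_epochs()] with populated `artifact_flags`.
#' @param minimum Minimum number of clean epochs (inclusive).
#' @return The [eeg_epochs()] restricted to clean epochs.
#' @export
enforce_min_epochs <- function(epochs, minimum = 50) {
  keep <- which(!epochs$artifact_flags)
  if (length(keep) < minimum) {
    rlang::abort(
      sprintf("subject %s/%s excluded: %d clean epochs < minimum %d.",
              epochs$subject_id, epochs$session, length(keep), minimum),
      class = "alphagate_exclusion_error",
      n_clean = length(keep), minimum = minimum
    )
  }
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$artifact_flags <- epochs$artifact_flags[keep]
  epochs
}

#' Run the full preprocessing chain on a continuous recording
#'
#' Fixed stage order: band-pass filter, line-noise removal, epoch extraction
#' (contralesional responses), linked-mastoid re-referencing, ocular-artifact
#' removal, peak-to-peak flagging, minimum-epoch gate.
#'
#' @param raw An [eeg_recording()].
#' @param band Band-pass edges, Hz.
#' @param line_freq Line frequency, Hz.
#' @param window Epoch window, seconds.
#' @param minimum_epochs Minimum clean epochs; the gate raises an exclusion
#'   error below it.
#' @param ptp_limit Artifact peak-to-peak limit, microvolts.
#' @param eog EOG channel labels.
#' @param backend Ocular-removal backend, see [remove_ocular_artifacts()].
#' @return List with `epochs` (clean, gated) and `log` (tibble of per-stage
#'   counts).
#' @export
preprocess_recording <- function(raw, band = c(0.5, 40), line_freq = 60,
                                 window = c(-1, 1), minimum_epochs = 50,
                                 ptp_limit = 150, eog = eog_channels(),
                                 backend = "pca") {
  filtered <- bandpass_filter(raw, band[1], band[2])
  cleaned <- remove_line_noise(filtered, line_freq)
  epochs <- extract_epochs(cleaned, window = window)
  n_extracted <- dim(epochs$data)[1]
  epochs <- rereference_linked_mastoids(epochs)
  oc <- remove_ocular_artifacts(epochs, eog = eog, backend = backend)
  epochs <- flag_artifact_epochs(oc$epochs, ptp_limit = ptp_limit)
  n_flagged <- sum(epochs$artifact_flags)
  epochs <- enforce_min_epochs(epochs, minimum = minimum_epochs)
  log <- tibble::tibble(
    subject_id = raw$subject_id, session = raw$session,
    n_events = nrow(raw$events), n_epochs_extracted = n_extracted,
    n_components_removed = oc$n_components_removed,
    ocular_method = oc$method,
    n_flagged = n_flagged, n_clean = dim(epochs$data)[1]
  )
  list(epochs = epochs, log = log)
}
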