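# Forward model of one response-locked trial: 1/f background on every
# channel, amplitude-modulated alpha-band noise on scalp channels, temporal
# alpha multiplied by g_surge inside the surge window, central-frontal alpha
# multiplied by g_cf after onset. Returns channels x samples (microvolts).
sim_trial_matrix <- function(config, g_surge, g_cf, chans, time,
                             include_background = TRUE) {
  fs <- config$sampling_rate
  n_s <- length(time)
  temporal <- region_definition("temporal")$channels
  cf <- region_definition("central_frontal")$channels
  surge_win <- config$temporal_surge_window / 1000
  in_surge <- time >= surge_win[1] & time <= surge_win[2]
  post_onset <- time >= 0

  out <- matrix(0, nrow = length(chans), ncol = n_s)
  for (ci in seq_along(chans)) {
    ch <- chans[ci]
    bg <- if (include_background) {
      pink_noise(n_s, config$background_exponent, config$background_rms)
    } else 0
    if (ch %in% config$channels) {
      a <- alpha_burst_signal(n_s, fs, config$alpha_band, config$alpha_rms)
      g <- rep(1, n_s)
      if (ch %in% temporal) g[in_surge] <- g_surge
      if (ch %in% cf) g[post_onset] <- g_cf
      out[ci, ] <- bg + g * a
    } else {
      out[ci, ] <- out[ci, ] + bg
    }
  }
  out
}

effective_gains <- function(config, subject_effect, cf_effect) {
  list(
    surge = max(config$surge_gain * subject_effect, 1e-3),
    cf = min(max(config$cf_suppression_gain * cf_effect, 0.05), 1.5)
  )
}

#' Simulate one subject-session of response-locked epochs
#'
#' Forward model of the gating-by-inhibition pattern: every scalp channel
#' carries 1/f background noise plus amplitude-modulated alpha-band noise;
#' temporal-region channels have their alpha amplitude multiplied by the
#' surge gain inside the surge window around response onset, and
#' central-frontal channels have theirs multiplied by the suppression gain
#' after onset. EOG channels carry background only (blinks are added by
#' [inject_artifacts()]). With both gains at 1 the model is null: no
#' region-by-window contrast exists.
#'
#' @param config A [simulation_config()].
#' @param subject_effect Multiplier on this subject-session's modulation
#'   depth: the effective temporal surge gain is
#'   `surge_gain * subject_effect` (floored at 1e-3).
#' @param cf_effect Multiplier on the central-frontal suppression gain
#'   (clamped to \[0.05, 1.5\]).
#' @param session `"pre"` or `"post"`.
#' @param subject_id,lesion_side Identifiers stored in the result.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An [eeg_epochs()] object with EOG channels appended after the
#'   scalp channels and the event sample at t = 0.
#' @examples
#' cfg <- simulation_config(n_epochs_per_session = 4)
#' ep <- simulate_subject_epochs(cfg, seed = 1)
#' dim(ep$data)
#' @export
simulate_subject_epochs <- function(config, subject_effect = 1, cf_effect = 1,
                                    session = "pre", subject_id = "S01",
                                    lesion_side = "left", seed = NULL) {
  validate_simulation_config(config)
  with_seed_if(seed, {
    time <- epoch_time_axis(config$epoch_window, config$sampling_rate)
    chans <- c(config$channels, eog_channels())
    g <- effective_gains(config, subject_effect, cf_effect)
    n_ep <- config$n_epochs_per_session
    data <- array(0, dim = c(n_ep, length(chans), length(time)))
    for (e in seq_len(n_ep)) {
      data[e, , ] <- sim_trial_matrix(config, g$surge, g$cf, chans, time)
    }
    eeg_epochs(data, chans, config$sampling_rate, time,
               subject_id = subject_id, session = session,
               lesion_side = lesion_side)
  })
}

#' Simulate a continuous recording with response events
#'
#' Builds a continuous multichannel recording by placing response-locked
#' trials (same forward model as [simulate_subject_epochs()]) on a timeline
#' separated by background-only gaps, recording a response event at each
#' trial's t = 0 sample. A fraction of events is given the ipsilateral hand
#' so that epoch extraction has something to reject, and blinks are added
#' near responses at the configured artifact rate.
#'
#' @inheritParams simulate_subject_epochs
#' @param prop_ipsilateral Fraction of additional ipsilateral-hand events.
#' @param gap_s Background-only gap between consecutive trials, seconds.
#' @return List with `recording` (an [eeg_recording()]) and
#'   `blink_trials` (indices of contralesional trials that received a blink).
#' @export
simulate_subject_recording <- function(config, subject_effect = 1,
                                       cf_effect = 1, session = "pre",
                                       subject_id = "S01",
                                       lesion_side = "left",
                                       prop_ipsilateral = 0.2,
                                       gap_s = 0.3, seed = NULL) {
  validate_simulation_config(config)
  with_seed_if(seed, {
    fs <- config$sampling_rate
    time <- epoch_time_axis(config$epoch_window, fs)
    n_s <- length(time)
    onset_offset <- which.min(abs(time))  # sample index of t = 0 within a trial
    chans <- c(config$channels, eog_channels())
    g <- effective_gains(config, subject_effect, cf_effect)

    n_contra <- config$n_epochs_per_session
    n_ipsi <- round(prop_ipsilateral * n_contra)
    n_trials <- n_contra + n_ipsi
    hands_contra <- contralesional_hand(lesion_side)
    hands_other <- setdiff(c("left", "right"), hands_contra)
    hand_seq <- sample(c(rep(hands_contra, n_contra), rep(hands_other, n_ipsi)))

    gap <- round(gap_s * fs)
    step <- n_s + gap
    total <- n_trials * step + gap
    data <- matrix(0, nrow = length(chans), ncol = total)
    for (ci in seq_along(chans)) {
      data[ci, ] <- pink_noise(total, config$background_exponent,
                               config$background_rms)
    }
    events <- vector("list", n_trials)
    blink_trials <- integer(0)
    contra_counter <- 0L
    topo <- blink_topography(chans)
    for (k in seq_len(n_trials)) {
      start <- (k - 1L) * step + gap + 1L
      idx <- start:(start + n_s - 1L)
      data[, idx] <- data[, idx] +
        sim_trial_matrix(config, g$surge, g$cf, chans, time,
                         include_background = FALSE)
      onset <- start + onset_offset - 1L
      is_contra <- hand_seq[k] == hands_contra
      if (is_contra) contra_counter <- contra_counter + 1L
      if (stats::runif(1) < config$artifact_rate) {
        center <- onset + sample.int(round(0.4 * fs), 1) - round(0.2 * fs)
        wf <- blink_waveform(total, fs, center, amplitude = 250)
        data <- data + outer(topo, wf)
        if (is_contra) blink_trials <- c(blink_trials, contra_counter)
      }
      events[[k]] <- tibble::tibble(
        sample = onset, label = "response", response_hand = hand_seq[k]
      )
    }
    rec <- eeg_recording(data, chans, fs,
                         events = dplyr::bind_rows(events),
                         subject_id = subject_id, session = session,
                         lesion_side = lesion_side)
    list(recording = rec, blink_trials = blink_trials)
  })
}

#' Inject stereotyped blink artifacts into an epoch set
#'
#' Adds low-frequency, high-amplitude, frontal-dominant transients to a
#' random subset of epochs (each epoch contaminated independently with
#' probability `rate`), with coherent deflections on the EOG channels. The
#' injected epoch indices are returned so downstream artifact handling can be
#' scored against ground truth.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param rate Per-epoch contamination probability in \[0, 1\].
#' @param amplitude Peak blink amplitude at Fp sites, microvolts.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return List with `epochs` (contaminated copy) and `injected` (integer
#'   indices of contaminated epochs).
#' @export
inject_artifacts <- function(epochs, rate, amplitude = 250, seed = NULL) {
  if (rate < 0 || rate > 1) rlang::abort("`rate` must lie in [0, 1].")
  if (rate == 0) return(list(epochs = epochs, injected = integer(0)))
  with_seed_if(seed, {
    d <- dim(epochs$data)
    hit <- which(stats::runif(d[1]) < rate)
    topo <- blink_topography(epochs$channels)
    n_s <- d[3]
    for (e in hit) {
      center <- sample.int(n_s, 1)
      wf <- blink_waveform(n_s, epochs$sampling_rate, center, amplitude)
      epochs$data[e, , ] <- epochs$data[e, , ] + outer(topo, wf)
    }
    list(epochs = epochs, injected = hit)
  })
}

#' Hand contralateral to a lesioned hemisphere
#'
#' Single named constant implementing the epoch-selection convention:
#' "contralesional responses" are key presses by the hand contralateral to
#' the lesioned hemisphere (the paretic hand's controlling side). Flippable
#' here and nowhere else.
#'
#' @param lesion_side `"left"` or `"right"`.
#' @return `"right"` for a left-hemisphere lesion, `"left"` otherwise.
#' @export
contralesional_hand <- function(lesion_side = c("left", "right")) {
  lesion_side <- rlang::arg_match(lesion_side)
  if (lesion_side == "left") "right" else "left"
}
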