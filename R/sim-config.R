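#' Configuration for the synthetic EEG + clinical cohort generator
#'
#' Bundles every knob of the forward model in one validated object. The
#' defaults describe the study conditions the package is designed around:
#' three intervention groups (premotor tDCS, primary-motor tDCS, sham) of 12
#' subjects each, 32-channel 10-20 EEG sampled at 500 Hz, response-locked
#' epochs from -1 to +1 s, an alpha (8-12 Hz) surge over bilateral temporal
#' sites inside a window spanning response onset, alpha suppression over
#' central-frontal sites after onset, and subject-level coupling between the
#' change in the temporal alpha index and the change in each clinical outcome
#' at planted correlation strengths.
#'
#' @param n_per_group Subjects per group (>= 4; the minimum-covariance
#'   determinant stage is undefined below that).
#' @param groups Group labels.
#' @param sampling_rate Sampling rate in Hz.
#' @param channels Scalp channel labels (10-20 names); must contain every
#'   channel of both index regions and both mastoids.
#' @param epoch_window Epoch limits in seconds relative to response onset;
#'   must span 0. Samples follow the half-open convention
#'   `[lower, upper)` with a sample at exactly t = 0.
#' @param n_epochs_per_session Response-locked epochs simulated per
#'   subject-session.
#' @param alpha_band Alpha band in Hz.
#' @param temporal_surge_window Window (ms, relative to onset) in which
#'   temporal-region alpha amplitude is multiplied by `surge_gain`.
#' @param surge_gain Amplitude multiplier (>= 1) for temporal-region alpha
#'   inside `temporal_surge_window`.
#' @param cf_suppression_gain Amplitude multiplier in (0, 1] for
#'   central-frontal alpha after response onset.
#' @param background_rms Broadband 1/f background RMS in microvolts.
#' @param background_exponent Spectral exponent of the 1/f background.
#' @param alpha_rms RMS (microvolts) of the unmodulated alpha component on
#'   each scalp channel.
#' @param planted_rho Named list, one element per group, each a named numeric
#'   vector over outcomes (`sis_adl`, `fim`, `neadl`, `wmft_time`,
#'   `wmft_strength`) giving the correlation planted between the subject's
#'   temporal-alpha index change and that outcome's change score. Scalars
#'   recycle across outcomes.
#' @param outlier_fraction Fraction of subjects per group whose
#'   (index change, outcome change) pair is replaced by a point displaced
#'   along the minor axis of the planted bivariate distribution (>= 4 robust
#'   SDs), in [0, 0.5).
#' @param artifact_rate Per-epoch probability of an injected blink.
#' @param seed Base integer seed for the generator.
#' @return A validated `simulation_config` list.
#' @examples
#' cfg <- simulation_config(n_per_group = 6, n_epochs_per_session = 10)
#' cfg$surge_gain
#' @export
simulation_config <- function(n_per_group = 12,
                              groups = c("PMC", "M1", "Sham"),
                              sampling_rate = 500,
                              channels = montage_channels_32(),
                              epoch_window = c(-1, 1),
                              n_epochs_per_session = 60,
                              alpha_band = c(8, 12),
                              temporal_surge_window = c(-65, 127),
                              surge_gain = 2,
                              cf_suppression_gain = 0.7,
                              background_rms = 10,
                              background_exponent = 1,
                              alpha_rms = 9,
                              planted_rho = default_planted_rho(groups),
                              outlier_fraction = 0,
                              artifact_rate = 0.1,
                              seed = 1L) {
  cfg <- list(
    n_per_group = as.integer(n_per_group), groups = as.character(groups),
    sampling_rate = sampling_rate, channels = as.character(channels),
    epoch_window = as.numeric(epoch_window),
    n_epochs_per_session = as.integer(n_epochs_per_session),
    alpha_band = as.numeric(alpha_band),
    temporal_surge_window = as.numeric(temporal_surge_window),
    surge_gain = surge_gain, cf_suppression_gain = cf_suppression_gain,
    background_rms = background_rms, background_exponent = background_exponent,
    alpha_rms = alpha_rms,
    planted_rho = normalize_planted_rho(planted_rho, groups),
    outlier_fraction = outlier_fraction, artifact_rate = artifact_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
}

#' Default planted correlation structure
#'
#' One positive coupling (0.6) between temporal-alpha change and the
#' stroke-impact ADL change score in the premotor group, zero everywhere
#' else: the minimal structure in which exactly one cell of the correlation
#' battery carries signal.
#'
#' @param groups Group labels.
#' @return Named list of named numeric vectors.
#' @export
default_planted_rho <- function(groups = c("PMC", "M1", "Sham")) {
  out <- stats::setNames(
    rep(list(stats::setNames(rep(0, 5), clinical_outcomes())), length(groups)),
    groups
  )
  if ("PMC" %in% groups) out$PMC["sis_adl"] <- 0.6
  out
}

#' Names of the clinical outcome columns
#' @return Character vector of the five outcome column names.
#' @export
clinical_outcomes <- function() {
  c("sis_adl", "fim", "neadl", "wmft_time", "wmft_strength")
}

normalize_planted_rho <- function(planted_rho, groups) {
  outs <- clinical_outcomes()
  if (is.numeric(planted_rho) && length(planted_rho) == 1L) {
    planted_rho <- stats::setNames(rep(list(planted_rho), length(groups)), groups)
  }
  if (!is.list(planted_rho) || !all(groups %in% names(planted_rho))) {
    rlang::abort("`planted_rho` must be a named list with one element per group.")
  }
  purrr::map(planted_rho[groups], function(v) {
    if (length(v) == 1L && is.null(names(v))) v <- stats::setNames(rep(v, 5), outs)
    if (is.null(names(v))) rlang::abort("per-group `planted_rho` vectors must be named by outcome.")
    full <- stats::setNames(rep(0, 5), outs)
    bad <- setdiff(names(v), outs)
    if (length(bad)) rlang::abort(paste0("unknown outcome in planted_rho: ", bad[1]))
    full[names(v)] <- v
    full
  })
}

validate_simulation_config <- function(cfg) {
  abort_cfg <- function(msg) rlang::abort(msg, class = "alphagate_config_error")
  if (cfg$n_per_group < 4L) abort_cfg("`n_per_group` must be >= 4 (MCD undefined below).")
  if (cfg$sampling_rate <= 0) abort_cfg("`sampling_rate` must be positive.")
  if (!(cfg$epoch_window[1] < 0 && cfg$epoch_window[2] > 0)) {
    abort_cfg("`epoch_window` must span response onset (lower < 0 < upper).")
  }
  if (anyDuplicated(cfg$channels)) abort_cfg("channel names must be unique.")
  needed <- unique(c(
    region_definition("temporal")$channels,
    region_definition("central_frontal")$channels,
    mastoid_channels()
  ))
  missing <- setdiff(needed, cfg$channels)
  if (length(missing)) {
    abort_cfg(paste0("montage is missing required channels: ",
                     paste(missing, collapse = ", ")))
  }
  rhos <- unlist(cfg$planted_rho)
  if (any(abs(rhos) > 1)) abort_cfg("planted correlations must lie in [-1, 1].")
  if (cfg$outlier_fraction < 0 || cfg$outlier_fraction >= 0.5) {
    abort_cfg("`outlier_fraction` must lie in [0, 0.5).")
  }
  if (cfg$artifact_rate < 0) abort_cfg("`artifact_rate` must be >= 0.")
  if (cfg$surge_gain < 1) abort_cfg("`surge_gain` must be >= 1.")
  if (cfg$cf_suppression_gain <= 0 || cfg$cf_suppression_gain > 1) {
    abort_cfg("`cf_suppression_gain` must lie in (0, 1].")
  }
  if (cfg$alpha_band[1] >= cfg$alpha_band[2] ||
      cfg$alpha_band[2] >= cfg$sampling_rate / 2) {
    abort_cfg("`alpha_band` must be increasing and below Nyquist.")
  }
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  %d groups (%s) x %d subjects, %d epochs/session\n",
              length(x$groups), paste(x$groups, collapse = ", "),
              x$n_per_group, x$n_epochs_per_session))
  cat(sprintf("  %d channels @ %g Hz, epochs [%g, %g) s\n",
              length(x$channels), x$sampling_rate,
              x$epoch_window[1], x$epoch_window[2]))
  cat(sprintf("  surge gain %g in [%g, %g] ms; central-frontal gain %g post-onset\n",
              x$surge_gain, x$temporal_surge_window[1],
              x$temporal_surge_window[2], x$cf_suppression_gain))
  invisible(x)
}
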