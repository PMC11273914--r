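#' Continuous multichannel EEG recording
#'
#' @param data Numeric matrix `n_channels x n_samples`, microvolts.
#' @param channels Channel labels.
#' @param sampling_rate Sampling rate, Hz.
#' @param events Tibble with columns `sample` (1-based sample index),
#'   `label`, and `response_hand` (`"left"`/`"right"`, may be `NA` for
#'   non-response markers).
#' @param subject_id,session,lesion_side Identifiers.
#' @param reference_state Label describing the current reference.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, channels, sampling_rate,
                          events = tibble::tibble(sample = integer(),
                                                  label = character(),
                                                  response_hand = character()),
                          subject_id = "S01", session = "pre",
                          lesion_side = "left",
                          reference_state = "as-recorded") {
  if (!is.matrix(data)) rlang::abort("`data` must be a channels x samples matrix.")
  if (nrow(data) != length(channels)) {
    rlang::abort("channel labels must match the number of rows.")
  }
  if (anyDuplicated(channels)) rlang::abort("channel names must be unique.")
  if (sampling_rate <= 0) rlang::abort("`sampling_rate` must be positive.")
  if (nrow(events) && (any(events$sample < 1) || any(events$sample > ncol(data)))) {
    rlang::abort("event sample indices must lie within the recording.")
  }
  structure(
    list(data = data, channels = as.character(channels),
         sampling_rate = sampling_rate, events = events,
         subject_id = subject_id, session = session,
         lesion_side = lesion_side, reference_state = reference_state),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %s/%s: %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
    x$subject_id, x$session, nrow(x$data), ncol(x$data), x$sampling_rate,
    ncol(x$data) / x$sampling_rate, nrow(x$events)))
  invisible(x)
}
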