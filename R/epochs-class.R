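#' Response-locked epoch container
#'
#' Holds one subject-session's response-locked EEG epochs as an
#' `n_epochs x n_channels x n_samples` array in microvolts, together with the
#' time axis (seconds relative to response onset, half-open
#' `[lower, upper)` with a sample at exactly t = 0), channel labels,
#' per-epoch artifact flags and the referencing state.
#'
#' @param data Numeric array `n_epochs x n_channels x n_samples`.
#' @param channels Channel labels (length = dim 2).
#' @param sampling_rate Sampling rate, Hz.
#' @param time Time axis in seconds (length = dim 3), strictly increasing and
#'   containing 0.
#' @param subject_id,session,lesion_side Identifiers; `session` is `"pre"` or
#'   `"post"`, `lesion_side` `"left"` or `"right"`.
#' @param artifact_flags Logical per epoch; `TRUE` marks a contaminated epoch.
#' @param reference_state Label describing the current reference.
#' @return An `eeg_epochs` object.
#' @export
eeg_epochs <- function(data, channels, sampling_rate, time,
                       subject_id = "S01", session = "pre",
                       lesion_side = "left",
                       artifact_flags = rep(FALSE, dim(data)[1]),
                       reference_state = "as-recorded") {
  stopifnot(length(dim(data)) == 3L)
  if (dim(data)[2] != length(channels)) {
    rlang::abort("channel labels must match the second array dimension.")
  }
  if (dim(data)[3] != length(time)) {
    rlang::abort("time axis must match the third array dimension.")
  }
  if (anyDuplicated(channels)) rlang::abort("channel names must be unique.")
  if (is.unsorted(time, strictly = TRUE)) {
    rlang::abort("time axis must be strictly increasing.")
  }
  if (!any(abs(time) < 1e-9)) rlang::abort("time axis must contain t = 0.")
  structure(
    list(
      data = data, channels = as.character(channels),
      sampling_rate = sampling_rate, time = as.numeric(time),
      subject_id = subject_id, session = session, lesion_side = lesion_side,
      artifact_flags = as.logical(artifact_flags),
      reference_state = reference_state
    ),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_epochs> %s/%s: %d epochs x %d channels x %d samples @ %g Hz\n",
    x$subject_id, x$session, d[1], d[2], d[3], x$sampling_rate))
  cat(sprintf("  time [%g, %g] s, reference: %s, %d epoch(s) flagged\n",
              min(x$time), max(x$time), x$reference_state,
              sum(x$artifact_flags)))
  invisible(x)
}

#' Number of artifact-free epochs
#' @param epochs An [eeg_epochs()] object.
#' @return Integer count of epochs not flagged as artifacts.
#' @export
n_clean_epochs <- function(epochs) {
  sum(!epochs$artifact_flags)
}

#' Tidy an epoch set into a long tibble
#'
#' @param x An [eeg_epochs()] object.
#' @param channels Optional subset of channels to keep.
#' @param ... Unused.
#' @return Tibble with columns `epoch`, `channel`, `time`, `amplitude`.
#' @export
tidy.eeg_epochs <- function(x, channels = NULL, ...) {
  keep <- channels %||% x$channels
  idx <- match(keep, x$channels)
  if (anyNA(idx)) rlang::abort("unknown channel requested in tidy().")
  d <- dim(x$data)
  tibble::tibble(
    epoch = rep(seq_len(d[1]), times = length(idx) * d[3]),
    channel = rep(rep(keep, each = d[1]), times = d[3]),
    time = rep(x$time, each = d[1] * length(idx)),
    amplitude = as.vector(x$data[, idx, , drop = FALSE])
  )
}
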