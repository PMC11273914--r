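#' Read and write clinical score tables
#'
#' The interchange CSV has one row per subject x timepoint with columns
#' `subject_id`, `group` (PMC/M1/Sham), `timepoint` (pre/post) and the five
#' outcome columns `sis_adl`, `fim`, `neadl`, `wmft_time`, `wmft_strength`.
#'
#' @param data Clinical tibble in the interchange layout.
#' @param path File path.
#' @return `read_clinical_csv()` returns the tibble; the writer returns
#'   `path` invisibly.
#' @export
write_clinical_csv <- function(data, path) {
  needed <- c("subject_id", "group", "timepoint", clinical_outcomes())
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    rlang::abort(paste0("clinical table is missing columns: ",
                        paste(missing, collapse = ", ")))
  }
  readr::write_csv(data[, needed], path)
  invisible(path)
}

#' @rdname write_clinical_csv
#' @export
read_clinical_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("subject_id", "group", "timepoint", clinical_outcomes())
  missing <- setdiff(needed, names(out))
  if (length(missing)) {
    rlang::abort(paste0("clinical CSV is missing columns: ",
                        paste(missing, collapse = ", ")))
  }
  out
}

#' Write / read a recording as a raw numeric array with a JSON sidecar
#'
#' The container is a flat little-endian float64 file (channels x samples,
#' channel-major per sample, i.e. multiplexed) plus a `.json` sidecar
#' holding channel names, sampling rate, identifiers and the event table.
#'
#' @param rec An [eeg_recording()].
#' @param prefix Path prefix; writes `<prefix>.dat` and `<prefix>.json`.
#' @return The writer returns `prefix` invisibly; the reader an
#'   [eeg_recording()].
#' @export
write_eeg_array <- function(rec, prefix) {
  dat <- paste0(prefix, ".dat")
  side <- paste0(prefix, ".json")
  con <- file(dat, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  meta <- list(
    channels = rec$channels, sampling_rate = rec$sampling_rate,
    n_samples = ncol(rec$data), subject_id = rec$subject_id,
    session = rec$session, lesion_side = rec$lesion_side,
    reference_state = rec$reference_state,
    events = rec$events, dtype = "float64", order = "channel-major"
  )
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_eeg_array
#' @export
read_eeg_array <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n_ch <- length(meta$channels)
  con <- file(paste0(prefix, ".dat"), "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, "double", n = n_ch * meta$n_samples, size = 8,
                  endian = "little")
  events <- if (length(meta$events)) {
    tibble::as_tibble(meta$events)
  } else {
    tibble::tibble(sample = integer(), label = character(),
                   response_hand = character())
  }
  eeg_recording(matrix(vals, nrow = n_ch), meta$channels, meta$sampling_rate,
                events = events, subject_id = meta$subject_id,
                session = meta$session %||% "pre",
                lesion_side = meta$lesion_side %||% "left",
                reference_state = meta$reference_state %||% "as-recorded")
}

#' Write a recording as a BrainVision triplet
#'
#' Writes `<prefix>.vhdr` (header), `<prefix>.vmrk` (markers) and
#' `<prefix>.eeg` (binary IEEE float32, multiplexed). Response events are
#' stored as `Response` markers whose description is the response hand.
#'
#' @param rec An [eeg_recording()].
#' @param prefix Path prefix (without extension).
#' @return `prefix`, invisibly.
#' @export
write_brainvision <- function(rec, prefix) {
  base <- basename(prefix)
  vhdr <- paste0(prefix, ".vhdr")
  vmrk <- paste0(prefix, ".vmrk")
  eegf <- paste0(prefix, ".eeg")
  interval_us <- 1e6 / rec$sampling_rate
  hdr <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    paste0("SamplingInterval=", format(interval_us, scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(rec$data)), rec$channels)
  )
  writeLines(hdr, vhdr, useBytes = TRUE)
  mk <- c(
    "BrainVision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0"
  )
  if (nrow(rec$events)) {
    mk <- c(mk, sprintf(
      "Mk%d=Response,%s,%d,1,0",
      seq_len(nrow(rec$events)) + 1L,
      ifelse(is.na(rec$events$response_hand), rec$events$label,
             rec$events$response_hand),
      rec$events$sample
    ))
  }
  writeLines(mk, vmrk, useBytes = TRUE)
  con <- file(eegf, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(rec$data), con, size = 4, endian = "little")
  invisible(prefix)
}

#' Read a BrainVision triplet
#'
#' Parses the `.vhdr` header (channel names, resolutions, sampling
#' interval, binary format), the `.vmrk` markers and the binary `.eeg`
#' payload (multiplexed IEEE float32 or int16 with per-channel resolution).
#' Marker descriptions are mapped to response hands through `hand_map`.
#'
#' @param prefix Path prefix without extension (a `.vhdr` path is also
#'   accepted).
#' @param hand_map Named character vector mapping marker descriptions to
#'   `"left"`/`"right"`; unmapped descriptions give `NA` hands.
#' @param subject_id,session,lesion_side Identifiers for the returned
#'   recording.
#' @return An [eeg_recording()].
#' @export
read_brainvision <- function(prefix,
                             hand_map = c(left = "left", right = "right"),
                             subject_id = basename(prefix),
                             session = "pre", lesion_side = "left") {
  prefix <- sub("\\.vhdr$", "", prefix)
  hdr <- readLines(paste0(prefix, ".vhdr"), warn = FALSE, encoding = "UTF-8")
  get_val <- function(key) {
    ln <- grep(paste0("^", key, "="), hdr, value = TRUE)
    if (!length(ln)) return(NA_character_)
    sub(paste0("^", key, "="), "", ln[1])
  }
  n_ch <- as.integer(get_val("NumberOfChannels"))
  interval <- as.numeric(get_val("SamplingInterval"))
  fmt <- get_val("BinaryFormat")
  orient <- get_val("DataOrientation")
  if (!is.na(orient) && toupper(orient) != "MULTIPLEXED") {
    rlang::abort("only MULTIPLEXED BrainVision data is supported.")
  }
  ch_lines <- grep("^Ch[0-9]+=", hdr, value = TRUE)
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  channels <- vapply(parts, `[`, character(1), 1)
  resolution <- vapply(parts, function(p) {
    r <- suppressWarnings(as.numeric(p[3]))
    if (is.na(r) || r == 0) 1 else r
  }, numeric(1))

  eegf <- paste0(prefix, ".eeg")
  sz <- file.info(eegf)$size
  con <- file(eegf, "rb")
  on.exit(close(con), add = TRUE)
  if (toupper(fmt) == "IEEE_FLOAT_32") {
    vals <- readBin(con, "double", n = sz / 4, size = 4, endian = "little")
    data <- matrix(vals, nrow = n_ch)
  } else if (toupper(fmt) == "INT_16") {
    vals <- readBin(con, "integer", n = sz / 2, size = 2, signed = TRUE,
                    endian = "little")
    data <- matrix(vals, nrow = n_ch) * resolution
  } else {
    rlang::abort(paste0("unsupported BinaryFormat: ", fmt))
  }

  mrk <- readLines(paste0(prefix, ".vmrk"), warn = FALSE, encoding = "UTF-8")
  mk_lines <- grep("^Mk[0-9]+=", mrk, value = TRUE)
  ev <- purrr::map_dfr(mk_lines, function(ln) {
    f <- strsplit(sub("^Mk[0-9]+=", "", ln), ",")[[1]]
    tibble::tibble(type = f[1], description = f[2],
                   sample = as.integer(f[3]))
  })
  ev <- ev[ev$type %in% c("Response", "Stimulus"), , drop = FALSE]
  events <- tibble::tibble(
    sample = ev$sample, label = ev$type,
    response_hand = unname(hand_map[ev$description])
  )
  eeg_recording(data, channels, 1e6 / interval, events = events,
                subject_id = subject_id, session = session,
                lesion_side = lesion_side)
}
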