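#' Standard 32-channel 10-20 montage used throughout the package
#'
#' Channel labels of a 32-electrode actiCAP-style layout placed per the
#' international 10-20 system, the default montage for both the synthetic
#' generator and the preprocessing stage. Electro-oculogram (EOG) channels are
#' carried separately and appended after the scalp channels.
#'
#' @return Character vector of 32 scalp channel labels.
#' @export
montage_channels_32 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8",
    "PO9", "O1", "Oz", "O2", "PO10")
}

#' Default EOG channel labels
#' @return Character vector: vertical then horizontal EOG.
#' @export
eog_channels <- function() c("VEOG", "HEOG")

#' Default mastoid channel labels for linked-mastoid re-referencing
#' @return Character vector of length 2.
#' @export
mastoid_channels <- function() c("TP9", "TP10")

#' Region definitions for the gating-by-inhibition alpha indexes
#'
#' Two fixed bilateral scalp regions drive the indexes: the temporal region
#' (T7, F7, CP5, T8, F8, CP6), where an alpha surge before the response is
#' read as inhibition of non-motor interference, and the central-frontal
#' region (frontal F3, Fz, F4 plus central C3, CP1, C4, CP2), where reduced
#' alpha after response onset is read as a release of motor cortex from
#' inhibition. These definitions are the single source of truth: every
#' region-level computation takes a region name or an explicit channel set
#' from here, never a hard-coded duplicate.
#'
#' @param name `"temporal"` or `"central_frontal"`.
#' @return A list with elements `name` and `channels`.
#' @examples
#' region_definition("temporal")$channels
#' @export
region_definition <- function(name = c("temporal", "central_frontal")) {
  name <- rlang::arg_match(name)
  channels <- switch(name,
    temporal = c("T7", "F7", "CP5", "T8", "F8", "CP6"),
    central_frontal = c("F3", "Fz", "F4", "C3", "CP1", "C4", "CP2")
  )
  structure(list(name = name, channels = channels), class = "region_definition")
}

#' All region definitions as a named list
#' @return Named list of [region_definition()] objects.
#' @export
region_definitions <- function() {
  list(
    temporal = region_definition("temporal"),
    central_frontal = region_definition("central_frontal")
  )
}
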