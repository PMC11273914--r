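#' Electrode current density
#'
#' Current density of a surface electrode: stimulation intensity divided by
#' electrode area. At the standard protocol of 2 mA through a 35 cm^2
#' sponge electrode this is 0.057 mA/cm^2, well inside accepted safety
#' limits.
#'
#' @param current_ma Stimulation intensity, mA.
#' @param area_cm2 Electrode area, cm^2.
#' @return Current density in mA/cm^2.
#' @examples
#' current_density(2, 35)
#' @export
current_density <- function(current_ma = 2, area_cm2 = 35) {
  stopifnot_scalar_number(current_ma, "current_ma")
  stopifnot_scalar_number(area_cm2, "area_cm2")
  if (area_cm2 <= 0) rlang::abort("`area_cm2` must be positive.")
  current_ma / area_cm2
}
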