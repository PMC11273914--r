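#' Mean dB power over a region and time window
#'
#' Unweighted mean of the alpha-power map over the region's channels and
#' every valid sample inside the closed window. The window must lie inside
#' the edge-valid part of the map.
#'
#' @param map An `alpha_power_map` (see [alpha_power_map()]).
#' @param region A [region_definition()] or region name.
#' @param window Closed window in milliseconds relative to response onset.
#' @return Scalar dB value.
#' @examples
#' cfg <- simulation_config(n_epochs_per_session = 3)
#' ep <- simulate_subject_epochs(cfg, seed = 2)
#' m <- alpha_power_map(ep)
#' region_window_mean(m, "temporal", c(-65, 0))
#' @export
region_window_mean <- function(map, region, window) {
  if (is.character(region)) region <- region_definition(region)
  idx <- match(region$channels, map$channels)
  if (anyNA(idx)) {
    rlang::abort(paste0("region channel(s) missing from the power map: ",
                        paste(region$channels[is.na(idx)], collapse = ", ")),
                 class = "alphagate_config_error")
  }
  win_s <- window / 1000
  in_win <- map$time >= win_s[1] - 1e-9 & map$time <= win_s[2] + 1e-9
  usable <- in_win & map$valid
  if (!any(usable)) {
    rlang::abort("window contains no valid samples.",
                 class = "alphagate_parameter_error")
  }
  if (any(in_win & !map$valid)) {
    rlang::warn("window overlaps edge-invalid samples; they are excluded.")
  }
  mean(map$power[idx, usable])
}

#' Temporal / central-frontal alpha ratio
#'
#' The composite gating index: temporal-window alpha divided by
#' central-frontal-window alpha, both on the median-scaled dB scale the
#' indexes are defined on. Higher values are read as better psychomotor
#' efficiency. dB values near zero make the ratio unstable, so when the
#' denominator's magnitude falls below `eps` the ratio is computed against
#' `eps` (keeping the numerator's sign structure) and flagged with a
#' warning rather than failing.
#'
#' @param temporal Temporal-region alpha, dB.
#' @param central_frontal Central-frontal-region alpha, dB.
#' @param eps Denominator magnitude floor, dB.
#' @return Dimensionless ratio.
#' @export
alpha_ratio <- function(temporal, central_frontal, eps = 0.1) {
  if (abs(central_frontal) < eps) {
    rlang::warn(sprintf(
      "central-frontal alpha %.4f dB below the %.2f dB floor; ratio floored.",
      central_frontal, eps))
    return(sign(temporal) * abs(temporal) / eps)
  }
  temporal / central_frontal
}

#' Alpha indexes of one subject-session
#'
#' Reduces an alpha-power map to the three theory-driven indexes: temporal
#' alpha in the pre-onset window, central-frontal alpha in the post-onset
#' window, and their ratio.
#'
#' @param map An `alpha_power_map`.
#' @param windows Named list with `temporal` and `central_frontal` windows
#'   in ms (default [default_windows()]).
#' @param eps Ratio denominator floor, see [alpha_ratio()].
#' @return One-row tibble: `subject_id`, `session`, `temporal_alpha`,
#'   `central_frontal_alpha`, `alpha_ratio`, plus the window bounds used.
#' @export
compute_alpha_indexes <- function(map, windows = default_windows(),
                                  eps = 0.1) {
  ta <- region_window_mean(map, "temporal", windows$temporal)
  cf <- region_window_mean(map, "central_frontal", windows$central_frontal)
  tibble::tibble(
    subject_id = map$subject_id, session = map$session,
    temporal_alpha = ta, central_frontal_alpha = cf,
    alpha_ratio = alpha_ratio(ta, cf, eps = eps),
    temporal_window_start = windows$temporal[1],
    temporal_window_end = windows$temporal[2],
    cf_window_start = windows$central_frontal[1],
    cf_window_end = windows$central_frontal[2]
  )
}

#' Post-minus-pre change scores
#'
#' Turns a long table of per-subject, per-session measurements into change
#' scores (post - pre) for every metric column. Subjects missing either
#' session for a metric are dropped from that metric with a warning naming
#' them: a change score is defined only when both sessions qualified.
#'
#' @param data Tibble with columns `subject_id`, `session`
#'   (`"pre"`/`"post"`), optional grouping columns, and numeric metric
#'   columns.
#' @param metrics Metric column names; defaults to every numeric column
#'   except identifiers.
#' @param keep Identifier columns carried through (e.g. `group`).
#' @return Tibble with `subject_id`, `keep` columns, `metric`, `delta`.
#' @examples
#' df <- tibble::tibble(
#'   subject_id = rep(c("S1", "S2"), each = 2),
#'   session = rep(c("pre", "post"), 2),
#'   score = c(10, 12, 20, 19)
#' )
#' change_scores(df)
#' @export
change_scores <- function(data, metrics = NULL, keep = intersect("group", names(data))) {
  id_cols <- c("subject_id", "session", keep)
  metrics <- metrics %||%
    setdiff(names(data)[vapply(data, is.numeric, logical(1))], id_cols)
  long <- tidyr::pivot_longer(
    dplyr::select(data, dplyr::all_of(c(id_cols, metrics))),
    cols = dplyr::all_of(metrics), names_to = "metric", values_to = "value"
  )
  wide <- tidyr::pivot_wider(long, names_from = "session",
                             values_from = "value")
  for (s in c("pre", "post")) if (!s %in% names(wide)) wide[[s]] <- NA_real_
  missing <- wide[is.na(wide$pre) | is.na(wide$post), , drop = FALSE]
  if (nrow(missing)) {
    rlang::warn(sprintf(
      "dropping %d subject-metric pair(s) missing a session: %s",
      nrow(missing),
      paste(unique(missing$subject_id), collapse = ", ")))
    wide <- wide[!is.na(wide$pre) & !is.na(wide$post), , drop = FALSE]
  }
  out <- dplyr::mutate(wide, delta = .data$post - .data$pre)
  dplyr::select(out, dplyr::all_of(c("subject_id", keep, "metric")),
                "delta")
}
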