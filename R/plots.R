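#' Plot an alpha-power map as a channel-by-time heat map
#'
#' @param object An `alpha_power_map`.
#' @param channels Optional channel subset (default: both index regions).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.alpha_power_map <- function(object,
                                     channels = c(
                                       region_definition("temporal")$channels,
                                       region_definition("central_frontal")$channels),
                                     ...) {
  df <- tidy(object)
  df <- df[df$valid & df$channel %in% channels, , drop = FALSE]
  df$channel <- factor(df$channel, levels = channels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time * 1000, y = .data$channel,
                                   fill = .data$power_db)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_fill_gradient2(name = "dB") +
    ggplot2::labs(x = "time (ms, response-locked)", y = NULL,
                  title = sprintf("Alpha power, %s/%s",
                                  object$subject_id, object$session)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a skipped correlation
#'
#' Retained pairs with the least-squares line fitted to them; flagged
#' outliers drawn as filled black points, mirroring the standard
#' presentation of robust correlation results.
#'
#' @param object A `skipped_corr` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.skipped_corr <- function(object, ...) {
  df <- tibble::tibble(x = object$x, y = object$y,
                       outlier = seq_along(object$x) %in%
                         match(object$outlier_indices, seq_along(object$x)))
  lab <- sprintf("r = %.2f, t = %.2f%s", object$r, object$t,
                 if (!is.na(object$ci[1])) {
                   sprintf(", CI [%.2f, %.2f]", object$ci[1], object$ci[2])
                 } else "")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_smooth(data = df[!df$outlier, ], method = "lm",
                         formula = y ~ x, se = FALSE,
                         linetype = "dotted", colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(fill = .data$outlier),
                        shape = 21, size = 2.5, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white", `TRUE` = "black")) +
    ggplot2::labs(subtitle = lab, x = "index change", y = "outcome change") +
    ggplot2::theme_classic()
}

#' Plot the pointwise t trace of a cluster permutation test
#'
#' @param object A `cluster_test` object.
#' @param alpha Significance level for shading surviving clusters.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_test <- function(object, alpha = 0.05, ...) {
  df <- tibble::tibble(time = object$time, t = object$t)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$t)) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$cluster_forming_threshold,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line()
  cl <- object$clusters[object$clusters$p_value < alpha, , drop = FALSE]
  if (nrow(cl)) {
    p <- p + ggplot2::annotate("rect", xmin = cl$start, xmax = cl$end,
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "steelblue")
  }
  p + ggplot2::labs(x = "time", y = "t statistic") + ggplot2::theme_minimal()
}

#' Tile plot of a correlation battery
#'
#' One tile per (group, index, outcome) cell coloured by the skipped r,
#' with significant cells (bootstrap CI excluding 0) outlined.
#'
#' @param battery Result tibble of [correlation_battery()].
#' @return A ggplot object.
#' @export
plot_correlation_battery <- function(battery) {
  df <- battery[battery$estimable, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(.data$outcome, .data$index,
                                   fill = .data$r)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_tile(data = df[isTRUE_vec(df$significant), , drop = FALSE],
                       fill = NA, colour = "black", linewidth = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

isTRUE_vec <- function(x) !is.na(x) & x
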