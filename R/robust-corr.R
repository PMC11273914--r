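#' Minimum covariance determinant location and scatter (bivariate)
#'
#' Finds the h-point subset whose covariance matrix has minimal determinant
#' and returns that subset's mean and covariance. For n <= 15 every subset
#' is enumerated, so the estimate is exact; beyond that, concentration
#' steps (C-steps) from many random starts are used, each iterated to
#' convergence. Collinear data yield a degenerate-scatter flag so callers
#' can fall back to univariate outlier screening.
#'
#' @param points Numeric `n x 2` matrix (n >= 4).
#' @param h Subset size, in `[floor((n+3)/2), n]`. Default
#'   `floor((n + 3) / 2)` (maximal breakdown for two variables).
#' @param n_starts Random starts for the iterative path (n > 15).
#' @param seed Seed for the iterative path.
#' @return List with `center` (length 2), `scatter` (2 x 2), `subset`
#'   (indices of the optimal h-subset), `det`, and `degenerate` flag.
#' @examples
#' set.seed(1)
#' pts <- cbind(rnorm(12), rnorm(12))
#' pts[1, ] <- c(10, -10)
#' mcd_estimate(pts)$subset
#' @export
mcd_estimate <- function(points, h = NULL, n_starts = 500, seed = 1L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 4 || ncol(points) != 2) {
    rlang::abort("`points` must be an n x 2 matrix with n >= 4.",
                 class = "alphagate_parameter_error")
  }
  h <- h %||% floor((n + 3) / 2)
  if (h < floor((n + 3) / 2) || h > n) {
    rlang::abort("`h` must lie in [floor((n+3)/2), n].",
                 class = "alphagate_parameter_error")
  }
  if (h == n) {
    ctr <- colMeans(points)
    sc <- stats::cov(points)
    return(finish_mcd(points, seq_len(n), ctr, sc))
  }
  if (n <= 15) {
    subsets <- utils::combn(n, h)
    moments <- mcd_subset_moments(points, subsets, h)
    best <- which.min(moments$det)
    idx <- subsets[, best]
  } else {
    idx <- mcd_csteps(points, h, n_starts = n_starts, seed = seed)
  }
  sub <- points[idx, , drop = FALSE]
  finish_mcd(points, idx, colMeans(sub), stats::cov(sub))
}

# Vectorized determinant of the covariance of every candidate subset.
mcd_subset_moments <- function(points, subsets, h) {
  n <- nrow(points)
  x <- points[, 1]; y <- points[, 2]
  Z <- matrix(0, nrow = ncol(subsets), ncol = n)
  Z[cbind(rep(seq_len(ncol(subsets)), each = h), as.vector(subsets))] <- 1
  M <- Z %*% cbind(x, y, x^2, y^2, x * y)
  mx <- M[, 1] / h; my <- M[, 2] / h
  cxx <- (M[, 3] - h * mx^2) / (h - 1)
  cyy <- (M[, 4] - h * my^2) / (h - 1)
  cxy <- (M[, 5] - h * mx * my) / (h - 1)
  list(det = cxx * cyy - cxy^2)
}

# C-step refinement (FAST-MCD style) for larger n.
mcd_csteps <- function(points, h, n_starts = 500, seed = 1L) {
  n <- nrow(points)
  with_seed_if(seed, {
    best_idx <- NULL
    best_det <- Inf
    for (s in seq_len(n_starts)) {
      idx <- sample.int(n, max(3L, min(h, 3L)))
      sub <- points[idx, , drop = FALSE]
      repeat {
        ctr <- colMeans(sub)
        sc <- stats::cov(sub)
        if (nrow(sub) < 3 || !is.finite(det(sc)) || det(sc) < 1e-300) {
          d2 <- rowSums(sweep(points, 2, ctr)^2)
        } else {
          d2 <- stats::mahalanobis(points, ctr, sc)
        }
        new_idx <- order(d2)[seq_len(h)]
        if (setequal(new_idx, idx) && length(idx) == h) break
        idx <- new_idx
        sub <- points[idx, , drop = FALSE]
      }
      dt <- det(stats::cov(points[idx, , drop = FALSE]))
      if (dt < best_det) {
        best_det <- dt
        best_idx <- sort(idx)
      }
    }
    best_idx
  })
}

finish_mcd <- function(points, idx, ctr, sc) {
  scale2 <- prod(apply(points, 2, stats::var))
  degenerate <- !is.finite(det(sc)) ||
    det(sc) <= max(1e-12 * scale2, 1e-300)
  list(center = ctr, scatter = sc, subset = sort(idx),
       det = det(sc), degenerate = degenerate)
}

#' Box-plot rule on robust distances
#'
#' Flags bivariate outliers from their robust (Mahalanobis) distances to the
#' MCD centre under the MCD scatter: point i is flagged when
#' `d_i > q3 + k (q3 - q1)`, with quartiles of the distances by the
#' ideal-fourths estimator and `k = 1.5` by default. With a degenerate
#' scatter the rule falls back to univariate box-plot screening on each
#' coordinate.
#'
#' @param points Numeric `n x 2` matrix.
#' @param center,scatter Robust location and scatter (e.g. from
#'   [mcd_estimate()]).
#' @param k Box-plot whisker multiplier.
#' @param degenerate Set `TRUE` to force the univariate fallback.
#' @return Integer indices of flagged points (possibly empty).
#' @export
flag_outliers_boxplot <- function(points, center, scatter, k = 1.5,
                                  degenerate = FALSE) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (degenerate) {
    flag1 <- univariate_boxplot_flags(points[, 1], k)
    flag2 <- univariate_boxplot_flags(points[, 2], k)
    return(sort(union(flag1, flag2)))
  }
  d <- sqrt(pmax(stats::mahalanobis(points, center, scatter), 0))
  if (all(d < 1e-12)) return(integer(0))
  q <- ideal_fourths(d)
  which(d > q[2] + k * (q[2] - q[1]))
}

univariate_boxplot_flags <- function(x, k = 1.5) {
  if (stats::sd(x) < 1e-12) return(integer(0))
  q <- ideal_fourths(x)
  which(x > q[2] + k * (q[2] - q[1]) | x < q[1] - k * (q[2] - q[1]))
}

#' Skipped correlation with percentile-bootstrap confidence interval
#'
#' Robust correlation between two vectors: the bivariate scatter's location
#' and shape are estimated by the minimum covariance determinant, outliers
#' are rejected by the box-plot rule on robust distances, Pearson's r is
#' computed on the retained pairs with its t statistic
#' `t = r sqrt(n_ret - 2) / sqrt(1 - r^2)`, and a percentile bootstrap
#' (resampling retained pairs with replacement, outlier flags frozen)
#' provides the 95% confidence interval at the 2.5 and 97.5 percentiles.
#' The null hypothesis of no association is rejected exactly when 0 lies
#' outside the interval.
#'
#' @param x,y Numeric vectors of equal length (n >= 5 after removing
#'   incomplete pairs).
#' @param n_bootstrap Bootstrap resamples (0 skips the interval).
#' @param seed Seed for the bootstrap draw.
#' @param k Box-plot whisker multiplier.
#' @param h MCD subset size (default maximal breakdown).
#' @param ci_level Confidence level of the percentile interval.
#' @return A `skipped_corr` object: list with `r`, `t`, `ci`,
#'   `outlier_indices`, `n`, `n_retained`, `n_bootstrap`, `seed`,
#'   `significant`.
#' @examples
#' set.seed(7)
#' x <- rnorm(12); y <- 0.6 * x + rnorm(12, sd = 0.8)
#' res <- skipped_correlation(x, y, n_bootstrap = 200, seed = 1)
#' res$r
#' @export
skipped_correlation <- function(x, y, n_bootstrap = 1000, seed = 1L,
                                k = 1.5, h = NULL, ci_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) {
    rlang::abort("at least 5 complete pairs are required.",
                 class = "alphagate_parameter_error")
  }
  pts <- cbind(x, y)
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    rlang::abort("zero variance in x or y; correlation not estimable.",
                 class = "alphagate_degenerate_error")
  }
  mcd <- mcd_estimate(pts, h = h)
  out_idx <- flag_outliers_boxplot(pts, mcd$center, mcd$scatter, k = k,
                                   degenerate = mcd$degenerate)
  keep <- setdiff(seq_len(n), out_idx)
  n_ret <- length(keep)
  if (n_ret < 4) {
    rlang::abort(sprintf("only %d retained pairs; inference refused.", n_ret),
                 class = "alphagate_parameter_error")
  }
  xr <- x[keep]; yr <- y[keep]
  if (stats::sd(xr) < 1e-12 || stats::sd(yr) < 1e-12) {
    rlang::abort("retained pairs have zero variance; correlation not estimable.",
                 class = "alphagate_degenerate_error")
  }
  r <- stats::cor(xr, yr)
  t_stat <- if (abs(r) >= 1 - 1e-12) {
    rlang::warn("perfect correlation among retained pairs; t is infinite.")
    sign(r) * Inf
  } else {
    r * sqrt(n_ret - 2) / sqrt(1 - r^2)
  }

  ci <- c(NA_real_, NA_real_)
  significant <- NA
  if (n_bootstrap > 0) {
    boot_r <- with_seed_if(seed, {
      vapply(seq_len(n_bootstrap), function(b) {
        i <- sample.int(n_ret, n_ret, replace = TRUE)
        if (stats::sd(xr[i]) < 1e-12 || stats::sd(yr[i]) < 1e-12) {
          return(NA_real_)
        }
        stats::cor(xr[i], yr[i])
      }, numeric(1))
    })
    alpha <- 1 - ci_level
    ci <- unname(stats::quantile(boot_r, c(alpha / 2, 1 - alpha / 2),
                                 na.rm = TRUE))
    significant <- ci[1] > 0 || ci[2] < 0
  }
  structure(
    list(r = r, t = t_stat, ci = ci, outlier_indices = which(ok)[out_idx],
         n = n, n_retained = n_ret, n_bootstrap = n_bootstrap, seed = seed,
         significant = significant, ci_level = ci_level,
         x = x, y = y, retained = which(ok)[keep]),
    class = "skipped_corr"
  )
}

#' @export
print.skipped_corr <- function(x, ...) {
  cat(sprintf(
    "<skipped_corr> r = %.3f, t = %.3f, n = %d (%d retained, %d outliers)\n",
    x$r, x$t, x$n, x$n_retained, length(x$outlier_indices)))
  if (!is.na(x$ci[1])) {
    cat(sprintf("  %d%% bootstrap CI [%.3f, %.3f] -> %s\n",
                round(100 * x$ci_level), x$ci[1], x$ci[2],
                if (isTRUE(x$significant)) "significant" else "not significant"))
  }
  invisible(x)
}

#' Tidy a skipped correlation
#' @param x A `skipped_corr` object.
#' @param ... Unused.
#' @return One-row tibble with estimate, statistic, CI, counts and flag.
#' @export
tidy.skipped_corr <- function(x, ...) {
  tibble::tibble(
    estimate = x$r, statistic = x$t,
    ci_low = x$ci[1], ci_high = x$ci[2],
    n = x$n, n_retained = x$n_retained,
    n_outliers = length(x$outlier_indices),
    significant = x$significant
  )
}

#' Summarize a skipped correlation
#' @param x A `skipped_corr` object.
#' @param ... Unused.
#' @return One-row tibble with bootstrap settings and retained fraction.
#' @export
glance.skipped_corr <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_retained = x$n_retained, n_bootstrap = x$n_bootstrap,
    ci_level = x$ci_level, seed = x$seed,
    retained_fraction = x$n_retained / x$n
  )
}

#' Skipped-correlation battery over groups, indexes and outcomes
#'
#' Runs one skipped correlation per (group, EEG index, clinical outcome)
#' cell on a long change-score table, mirroring the panel structure of the
#' neural-behavioral analysis: 3 groups x 3 indexes x 5 outcomes = 45 cells
#' under the default design. No multiplicity correction is applied; an
#' optional false-discovery-rate column can be switched on.
#'
#' @param changes Long change-score tibble with columns `subject_id`,
#'   `group`, `metric`, `delta` containing both the index metrics and the
#'   outcome metrics (see [change_scores()]).
#' @param groups,index_names,outcome_names Cell structure of the battery.
#' @param n_bootstrap,k Passed to [skipped_correlation()].
#' @param seed Base seed; each cell uses `seed + cell_number`.
#' @param fdr Add a Benjamini-Hochberg-adjusted two-sided p column
#'   (computed from the t statistics; off by default).
#' @return Tibble with one row per cell: `group`, `index`, `outcome`, `n`,
#'   `n_retained`, `r`, `t`, `ci_low`, `ci_high`, `n_outliers`,
#'   `outliers` (comma-separated subject ids), `significant`, `estimable`.
#' @export
correlation_battery <- function(changes,
                                groups = c("PMC", "M1", "Sham"),
                                index_names = c("temporal_alpha",
                                                "central_frontal_alpha",
                                                "alpha_ratio"),
                                outcome_names = clinical_outcomes(),
                                n_bootstrap = 1000, k = 1.5,
                                seed = 1L, fdr = FALSE) {
  cells <- tidyr::expand_grid(group = groups, index = index_names,
                              outcome = outcome_names)
  res <- purrr::pmap(cells, function(group, index, outcome) {
    gi <- changes[changes$group == group & changes$metric == index,
                  c("subject_id", "delta")]
    go <- changes[changes$group == group & changes$metric == outcome,
                  c("subject_id", "delta")]
    m <- dplyr::inner_join(gi, go, by = "subject_id",
                           suffix = c("_index", "_outcome"))
    cell_seed <- seed + which(cells$group == group &
                                cells$index == index &
                                cells$outcome == outcome)[1]
    base <- tibble::tibble(
      group = group, index = index, outcome = outcome,
      n = nrow(m), n_retained = NA_integer_, r = NA_real_, t = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, n_outliers = NA_integer_,
      outliers = NA_character_, significant = NA, estimable = FALSE
    )
    if (nrow(m) < 5) return(base)
    sc <- tryCatch(
      skipped_correlation(m$delta_index, m$delta_outcome,
                          n_bootstrap = n_bootstrap, seed = cell_seed, k = k),
      alphagate_degenerate_error = function(e) NULL,
      alphagate_parameter_error = function(e) NULL
    )
    if (is.null(sc)) return(base)
    dplyr::mutate(base,
      n_retained = sc$n_retained, r = sc$r, t = sc$t,
      ci_low = sc$ci[1], ci_high = sc$ci[2],
      n_outliers = length(sc$outlier_indices),
      outliers = paste(m$subject_id[sc$outlier_indices], collapse = ","),
      significant = sc$significant, estimable = TRUE
    )
  })
  out <- dplyr::bind_rows(res)
  if (fdr) {
    p_two <- 2 * stats::pt(-abs(out$t), df = out$n_retained - 2)
    out$p_fdr <- stats::p.adjust(p_two, method = "BH")
  }
  out
}
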