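#' Normality and variance-homogeneity screening
#'
#' Kolmogorov-Smirnov test of each group against a normal with the sample
#' mean and SD (the commonly run, estimated-parameter form; a Lilliefors
#' correction is available), plus Levene's test on absolute deviations from
#' the group means. A routing flag recommends the nonparametric track when
#' any group's normality p falls below `alpha` or when a group is
#' degenerate (zero variance).
#'
#' @param data Tibble with a numeric `value` column and a `group` column.
#' @param value,group Column names.
#' @param alpha Routing threshold.
#' @param lilliefors Use a Lilliefors-corrected p (Monte-Carlo, 2000 draws)
#'   instead of the plain KS p.
#' @return List with `normality` (tibble group/p), `levene_p`, and
#'   `route` (`"parametric"`/`"nonparametric"`).
#' @export
check_assumptions <- function(data, value = "value", group = "group",
                              alpha = 0.05, lilliefors = FALSE) {
  v <- data[[value]]; g <- factor(data[[group]])
  norm <- purrr::map_dfr(levels(g), function(lv) {
    x <- v[g == lv]
    if (length(x) < 3 || stats::sd(x) < 1e-12) {
      return(tibble::tibble(group = lv, n = length(x), p = NA_real_))
    }
    p <- if (lilliefors) lilliefors_p(x) else {
      suppressWarnings(
        stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
    }
    tibble::tibble(group = lv, n = length(x), p = p)
  })
  lev <- tryCatch(
    car::leveneTest(v ~ g, center = mean)[1, "Pr(>F)"],
    error = function(e) NA_real_
  )
  route <- if (any(is.na(norm$p)) || any(norm$p < alpha)) {
    "nonparametric"
  } else {
    "parametric"
  }
  list(normality = norm, levene_p = unname(lev), route = route)
}

lilliefors_p <- function(x, n_sim = 2000) {
  n <- length(x)
  stat <- function(z) {
    suppressWarnings(
      stats::ks.test(z, "pnorm", mean(z), stats::sd(z))$statistic)
  }
  d_obs <- stat(x)
  d_null <- vapply(seq_len(n_sim), function(i) stat(stats::rnorm(n)),
                   numeric(1))
  mean(d_null >= d_obs)
}

#' Two-way mixed ANOVA (one between-subject, one within-subject factor)
#'
#' Classical sums-of-squares decomposition for a design with one
#' between-subject factor (e.g. three intervention groups) and one
#' within-subject factor with two levels (pre/post): between-group SS with
#' subjects-within-groups as its error, and time, group x time and their
#' time-by-subjects-within-groups error. With 3 groups of 12 subjects the
#' denominator df is 33 for every effect and the numerator df are 2
#' (Group), 1 (Time), and 2 (interaction). Subjects missing a cell are
#' dropped listwise with a warning. With only two within-levels sphericity
#' is not at issue and no correction is applied.
#'
#' @param data Tibble with columns `subject_id`, `group`, `session`
#'   (within-factor levels) and a numeric `value` column.
#' @param value Name of the response column.
#' @return A `mixed_anova` object: list with `effects` tibble (effect, SS,
#'   df_num, df_den, F, p), `ss_total`, `design`, `balanced`.
#' @examples
#' df <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:9),
#'                          session = c("pre", "post"))
#' df$group <- rep(rep(c("A", "B", "C"), each = 3), each = 2)[1:18]
#' df$value <- rnorm(18)
#' mixed_anova(df)
#' @export
mixed_anova <- function(data, value = "value") {
  d <- tibble::tibble(
    subject = as.character(data$subject_id),
    group = as.character(data$group),
    time = as.character(data$session),
    y = data[[value]]
  )
  counts <- dplyr::count(d, .data$subject)
  t_levels <- sort(unique(d$time))
  n_t <- length(t_levels)
  incomplete <- counts$subject[counts$n < n_t]
  if (length(incomplete)) {
    rlang::warn(sprintf("dropping %d subject(s) with missing cells: %s",
                        length(incomplete),
                        paste(incomplete, collapse = ", ")))
    d <- d[!d$subject %in% incomplete, , drop = FALSE]
  }
  subjects <- unique(d$subject)
  groups <- sort(unique(d$group))
  a <- length(groups)
  if (a < 2 || n_t < 2) {
    rlang::abort("need at least 2 groups and 2 within-levels.",
                 class = "alphagate_parameter_error")
  }
  grand <- mean(d$y)
  ss_total <- sum((d$y - grand)^2)

  subj_mean <- tapply(d$y, d$subject, mean)
  subj_group <- tapply(d$group, d$subject, `[`, 1)
  grp_mean <- tapply(d$y, d$group, mean)
  time_mean <- tapply(d$y, d$time, mean)
  cell_mean <- tapply(d$y, list(d$group, d$time), mean)
  n_g <- table(subj_group)[groups]

  ss_between_subj <- n_t * sum((subj_mean - grand)^2)
  ss_group <- n_t * sum(n_g * (grp_mean[groups] - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_time <- sum(vapply(t_levels, function(tl) {
    sum(n_g) * (time_mean[tl] - grand)^2
  }, numeric(1)))
  ss_cells <- 0
  for (gi in groups) for (tl in t_levels) {
    ss_cells <- ss_cells + n_g[[gi]] *
      (cell_mean[gi, tl] - grp_mean[[gi]] - time_mean[[tl]] + grand)^2
  }
  ss_gxt <- ss_cells
  ss_err_within <- ss_total - ss_group - ss_subj_within - ss_time - ss_gxt

  n_subj <- length(subjects)
  df_group <- a - 1
  df_subj <- n_subj - a
  df_time <- n_t - 1
  df_gxt <- (a - 1) * (n_t - 1)
  df_err <- (n_subj - a) * (n_t - 1)

  f_group <- (ss_group / df_group) / (ss_subj_within / df_subj)
  f_time <- (ss_time / df_time) / (ss_err_within / df_err)
  f_gxt <- (ss_gxt / df_gxt) / (ss_err_within / df_err)

  effects <- tibble::tibble(
    effect = c("Group", "Time", "Group:Time"),
    ss = c(ss_group, ss_time, ss_gxt),
    df_num = c(df_group, df_time, df_gxt),
    df_den = c(df_subj, df_err, df_err),
    statistic = c(f_group, f_time, f_gxt),
    p_value = stats::pf(c(f_group, f_time, f_gxt),
                        c(df_group, df_time, df_gxt),
                        c(df_subj, df_err, df_err), lower.tail = FALSE)
  )
  structure(
    list(effects = effects,
         ss = tibble::tibble(
           component = c("Group", "Subjects(Group)", "Time", "Group:Time",
                         "Time:Subjects(Group)"),
           ss = c(ss_group, ss_subj_within, ss_time, ss_gxt, ss_err_within)),
         ss_total = ss_total,
         design = list(n_groups = a, n_levels = n_t,
                       n_per_group = as.integer(n_g)),
         balanced = length(unique(n_g)) == 1L),
    class = "mixed_anova"
  )
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf("<mixed_anova> %d groups x %d within-levels%s\n",
              x$design$n_groups, x$design$n_levels,
              if (x$balanced) " (balanced)" else ""))
  print(x$effects)
  invisible(x)
}

#' Tidy a mixed ANOVA
#' @param x A `mixed_anova` object.
#' @param ... Unused.
#' @return Tibble of effects with SS, df, F and p.
#' @export
tidy.mixed_anova <- function(x, ...) x$effects

#' Summarize a mixed ANOVA
#' @param x A `mixed_anova` object.
#' @param ... Unused.
#' @return One-row tibble with design counts and total SS.
#' @export
glance.mixed_anova <- function(x, ...) {
  tibble::tibble(
    n_groups = x$design$n_groups, n_levels = x$design$n_levels,
    n_subjects = sum(x$design$n_per_group), balanced = x$balanced,
    ss_total = x$ss_total
  )
}

#' Nonparametric fallbacks: Kruskal-Wallis and Friedman
#'
#' Rank-based alternatives used when the normality screen fails: the
#' Kruskal-Wallis test for between-group comparison of one measurement, and
#' the Friedman test for the within-subject comparison across sessions.
#' Both use the tie-corrected statistics and asymptotic chi-squared p of
#' the standard implementations.
#'
#' @param data For `kruskal_between()`: tibble with `value` and `group`
#'   columns. For `friedman_within()`: tibble with `subject_id`, `session`
#'   and `value` columns.
#' @param value,group Column names.
#' @return One-row tibble with `statistic`, `df`, `p_value`, `method`.
#' @export
kruskal_between <- function(data, value = "value", group = "group") {
  g <- factor(data[[group]])
  if (nlevels(g) < 3) {
    rlang::abort("Kruskal-Wallis routing requires at least 3 groups.",
                 class = "alphagate_parameter_error")
  }
  v <- data[[value]]
  if (stats::sd(v) < 1e-300) {
    # complete ties carry no evidence against equality of the groups
    return(tibble::tibble(statistic = 0, df = nlevels(g) - 1,
                          p_value = 1, method = "kruskal-wallis"))
  }
  k <- stats::kruskal.test(v, g)
  tibble::tibble(statistic = unname(k$statistic),
                 df = unname(k$parameter),
                 p_value = k$p.value, method = "kruskal-wallis")
}

#' @rdname kruskal_between
#' @export
friedman_within <- function(data, value = "value") {
  sessions <- unique(data$session)
  if (length(sessions) < 2) {
    rlang::abort("Friedman routing requires at least 2 within-levels.",
                 class = "alphagate_parameter_error")
  }
  f <- stats::friedman.test(
    y = data[[value]],
    groups = factor(data$session),
    blocks = factor(data$subject_id)
  )
  tibble::tibble(statistic = unname(f$statistic),
                 df = unname(f$parameter),
                 p_value = f$p.value, method = "friedman")
}

#' Bonferroni-corrected paired post-hoc comparisons
#'
#' Paired t test of post versus pre within each group, with p multiplied by
#' the number of comparisons (capped at 1). Used as the follow-up when the
#' interaction or a main effect survives the mixed ANOVA.
#'
#' @param data Tibble with `subject_id`, `group`, `session`, and a numeric
#'   `value` column.
#' @param value Response column name.
#' @param m Number of comparisons (default: number of groups).
#' @return Tibble with one row per group: `t`, `df`, `p_raw`,
#'   `p_corrected`.
#' @export
bonferroni_posthoc <- function(data, value = "value", m = NULL) {
  groups <- sort(unique(data$group))
  m <- m %||% length(groups)
  purrr::map_dfr(groups, function(gname) {
    dsub <- data[data$group == gname, , drop = FALSE]
    wide <- tidyr::pivot_wider(
      dsub[, c("subject_id", "session", value)],
      names_from = "session", values_from = dplyr::all_of(value)
    )
    wide <- wide[stats::complete.cases(wide), , drop = FALSE]
    if (nrow(wide) < 2) {
      rlang::abort(sprintf("group %s has fewer than 2 complete pairs.", gname),
                   class = "alphagate_parameter_error")
    }
    delta <- wide$post - wide$pre
    if (stats::sd(delta) < 1e-300) {
      tt <- list(statistic = 0, parameter = nrow(wide) - 1, p.value = 1)
    } else {
      tt <- stats::t.test(delta)
    }
    tibble::tibble(
      group = gname, t = unname(tt$statistic), df = unname(tt$parameter),
      p_raw = tt$p.value, p_corrected = min(1, tt$p.value * m)
    )
  })
}
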