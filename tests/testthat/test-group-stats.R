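test_that("assumption screening routes parametric and nonparametric data", {
  set.seed(1)
  dfn <- tibble::tibble(value = rnorm(180),
                        group = rep(c("A", "B", "C"), each = 60))
  chk <- check_assumptions(dfn)
  expect_true(all(chk$normality$p > 0.05))
  expect_equal(chk$route, "parametric")
  expect_gt(chk$levene_p, 0.05)

  dfe <- dfn
  dfe$value[dfe$group == "A"] <- rexp(60)
  # exponential tails should trip the normality screen at n = 60
  set.seed(2)
  dfe2 <- tibble::tibble(value = c(rexp(200), rnorm(200), rnorm(200)),
                         group = rep(c("A", "B", "C"), each = 200))
  chk2 <- check_assumptions(dfe2)
  expect_lt(chk2$normality$p[chk2$normality$group == "A"], 0.05)
  expect_equal(chk2$route, "nonparametric")

  dfc <- tibble::tibble(value = rep(1, 30),
                        group = rep(c("A", "B", "C"), each = 10))
  expect_equal(check_assumptions(dfc)$route, "nonparametric")
})

test_that("mixed ANOVA reproduces the design df and the all-equal null", {
  df <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:36),
                           session = c("pre", "post"))
  df$group <- rep(rep(c("PMC", "M1", "Sham"), each = 12), each = 2)
  df$value <- 5
  fit0 <- mixed_anova(df)
  expect_true(all(fit0$effects$statistic == 0 | is.nan(fit0$effects$statistic)))

  set.seed(3)
  df$value <- rnorm(72)
  fit <- mixed_anova(df)
  expect_equal(fit$effects$df_num, c(2, 1, 2))
  expect_equal(fit$effects$df_den, c(33, 33, 33))
  expect_true(fit$balanced)
})

test_that("mixed ANOVA agrees with the aov error-stratum oracle", {
  run_check <- function(df) {
    fit <- mixed_anova(df)
    oracle <- summary(stats::aov(
      value ~ group * session + Error(subject_id / session), data = df))
    bs <- oracle[["Error: subject_id"]][[1]]
    ws <- oracle[["Error: subject_id:session"]][[1]]
    expect_equal(fit$effects$ss[fit$effects$effect == "Group"],
                 bs["group", "Sum Sq"], tolerance = 1e-8)
    expect_equal(fit$effects$ss[fit$effects$effect == "Time"],
                 ws["session", "Sum Sq"], tolerance = 1e-8)
    expect_equal(fit$effects$ss[fit$effects$effect == "Group:Time"],
                 ws["group:session", "Sum Sq"], tolerance = 1e-8)
    expect_equal(fit$effects$statistic,
                 c(bs["group", "F value"], ws["session", "F value"],
                   ws["group:session", "F value"]), tolerance = 1e-8)
    expect_equal(fit$effects$p_value,
                 c(bs["group", "Pr(>F)"], ws["session", "Pr(>F)"],
                   ws["group:session", "Pr(>F)"]), tolerance = 1e-8)
  }
  set.seed(4)
  df <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:18),
                           session = c("pre", "post"))
  df$group <- rep(rep(c("A", "B", "C"), each = 6), each = 2)
  df$value <- rnorm(36) + rep(rnorm(18), each = 2)
  run_check(df)
  # near-balanced design (5, 6, 6 subjects)
  run_check(df[!df$subject_id %in% "S01", ])
})

test_that("the SS decomposition is exhaustive", {
  set.seed(5)
  df <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:15),
                           session = c("pre", "post"))
  df$group <- rep(rep(c("A", "B", "C"), each = 5), each = 2)
  df$value <- rnorm(30)
  fit <- mixed_anova(df)
  expect_equal(sum(fit$ss$ss), fit$ss_total, tolerance = 1e-10)
})

test_that("a pure time effect loads on Time, not Group or the interaction", {
  set.seed(6)
  df <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:30),
                           session = c("pre", "post"))
  df$group <- rep(rep(c("A", "B", "C"), each = 10), each = 2)
  df$value <- rnorm(60, sd = 0.3) + ifelse(df$session == "post", 2, 0)
  fit <- mixed_anova(df)
  f <- fit$effects$statistic
  expect_gt(f[2], 50)
  expect_lt(f[1], 5)
  expect_lt(f[3], 5)
})

test_that("subjects with missing cells are dropped listwise", {
  df <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:9),
                           session = c("pre", "post"))
  df$group <- rep(rep(c("A", "B", "C"), each = 3), each = 2)
  set.seed(7)
  df$value <- rnorm(18)
  df <- df[-1, ]  # S01 loses its pre session
  expect_warning(fit <- mixed_anova(df), "S01")
  expect_equal(sum(fit$design$n_per_group), 8)
})

test_that("nonparametric fallbacks behave on null and degenerate input", {
  set.seed(8)
  dfn <- tibble::tibble(value = rnorm(60),
                        group = rep(c("A", "B", "C"), each = 20))
  kw <- kruskal_between(dfn)
  expect_gt(kw$p_value, 0.001)
  expect_equal(kw$df, 2)

  same <- tibble::tibble(value = rep(2, 30),
                         group = rep(c("A", "B", "C"), each = 10))
  kw0 <- kruskal_between(same)
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_value, 1)

  expect_error(kruskal_between(dfn[dfn$group != "C", ]),
               class = "alphagate_parameter_error")
})

test_that("two-condition Friedman equals its closed sign form without ties", {
  set.seed(9)
  n <- 14
  df <- tibble::tibble(
    subject_id = rep(sprintf("S%02d", 1:n), each = 2),
    session = rep(c("pre", "post"), n),
    value = rnorm(2 * n)
  )
  fr <- friedman_within(df)
  wide <- tidyr::pivot_wider(df, names_from = session, values_from = value)
  s <- sum(sign(wide$post - wide$pre))
  expect_equal(fr$statistic, s^2 / n, tolerance = 1e-10)
  expect_equal(fr$df, 1)
})

test_that("Bonferroni post-hoc multiplies and caps the paired-t p", {
  df <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:36),
                           session = c("pre", "post"))
  df$group <- rep(rep(c("PMC", "M1", "Sham"), each = 12), each = 2)
  set.seed(10)
  df$value <- rnorm(72) + ifelse(df$session == "post" & df$group == "M1",
                                 1.5, 0)
  ph <- bonferroni_posthoc(df)
  expect_equal(ph$df, rep(11, 3))
  expect_equal(ph$p_corrected, pmin(1, ph$p_raw * 3))
  expect_lt(ph$p_corrected[ph$group == "M1"], 0.05)

  dfz <- df
  dfz$value <- rep(rnorm(36), each = 2)  # post == pre within subject
  phz <- bonferroni_posthoc(dfz)
  expect_true(all(phz$t == 0))
  expect_true(all(phz$p_corrected == 1))
})
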