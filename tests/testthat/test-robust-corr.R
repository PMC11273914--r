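test_that("MCD with h = n is the ordinary mean and covariance", {
  set.seed(1)
  pts <- cbind(rnorm(10), rnorm(10))
  m <- mcd_estimate(pts, h = 10)
  expect_equal(m$center, colMeans(pts))
  expect_equal(m$scatter, cov(pts))
})

test_that("a gross outlier is excluded from every optimal subset and flagged", {
  set.seed(2)
  pts <- cbind(rnorm(12, sd = 0.5), rnorm(12, sd = 0.5))
  pts[4, ] <- c(8, -8)
  m <- mcd_estimate(pts, h = 8)
  expect_false(4 %in% m$subset)
  expect_lt(sqrt(sum(m$center^2)), 1)
  fl <- flag_outliers_boxplot(pts, m$center, m$scatter)
  expect_true(4 %in% fl)
})

test_that("exhaustive enumeration oracle matches the estimator for n <= 15", {
  for (i in 1:8) {
    set.seed(100 + i)
    n <- sample(8:13, 1)
    pts <- cbind(rnorm(n), rnorm(n) + rt(n, df = 3))
    h <- floor((n + 3) / 2)
    m <- mcd_estimate(pts)
    o <- oracle_mcd(pts, h)
    expect_equal(m$subset, o$subset)
    expect_equal(m$det, o$det, tolerance = 1e-12)
  }
})

test_that("C-step refinement attains the exhaustive optimum at desk scale", {
  for (i in 1:4) {
    set.seed(200 + i)
    n <- 12
    pts <- cbind(rnorm(n), rnorm(n))
    pts[1:2, ] <- pts[1:2, ] + 6
    h <- floor((n + 3) / 2)
    idx <- alphagate:::mcd_csteps(pts, h, n_starts = 200, seed = i)
    o <- oracle_mcd(pts, h)
    det_cstep <- det(cov(pts[idx, , drop = FALSE]))
    expect_equal(det_cstep, o$det, tolerance = 1e-9)
  }
})

test_that("MCD is affine equivariant", {
  set.seed(3)
  pts <- cbind(rnorm(12), rnorm(12))
  pts[7, ] <- c(6, 6)
  A <- matrix(c(2, 0.5, -1, 1.5), 2)
  b <- c(3, -2)
  m1 <- mcd_estimate(pts)
  m2 <- mcd_estimate(t(A %*% t(pts) + b))
  expect_equal(m2$subset, m1$subset)
  expect_equal(m2$center, drop(A %*% m1$center + b), tolerance = 1e-10)
})

test_that("box-plot flags are rare without contamination and absent for ties", {
  set.seed(4)
  flags <- vapply(1:40, function(i) {
    pts <- cbind(rnorm(12), rnorm(12))
    m <- mcd_estimate(pts)
    length(flag_outliers_boxplot(pts, m$center, m$scatter,
                                 degenerate = m$degenerate))
  }, numeric(1))
  expect_lt(mean(flags), 1)

  same <- matrix(1, nrow = 8, ncol = 2)
  expect_length(flag_outliers_boxplot(same, c(1, 1), diag(2),
                                      degenerate = TRUE), 0L)
})

test_that("collinear data fall back to univariate screening", {
  x <- c(1:11, 40)
  pts <- cbind(x, 2 * x + 1)
  m <- mcd_estimate(pts)
  expect_true(m$degenerate)
  fl <- flag_outliers_boxplot(pts, m$center, m$scatter,
                              degenerate = m$degenerate)
  expect_true(12 %in% fl)
})

test_that("skipped r equals plain Pearson whenever nothing is flagged", {
  hits <- 0
  for (i in 1:20) {
    set.seed(300 + i)
    x <- rnorm(12)
    y <- 0.4 * x + rnorm(12)
    sc <- skipped_correlation(x, y, n_bootstrap = 0)
    if (length(sc$outlier_indices) == 0) {
      hits <- hits + 1
      expect_identical(sc$r, cor(x, y))
    }
  }
  expect_gt(hits, 5)
})

test_that("the t statistic satisfies its defining identity exactly", {
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(12)
    y <- 0.5 * x + rnorm(12)
    sc <- skipped_correlation(x, y, n_bootstrap = 0)
    n <- sc$n_retained
    expect_equal(sc$t, sc$r * sqrt(n - 2) / sqrt(1 - sc$r^2),
                 tolerance = 1e-12)
  }
  # printed-pair arithmetic: r = 0.56 on 12 retained pairs gives t ~ 2.15
  expect_lt(abs(0.56 * sqrt(10) / sqrt(1 - 0.56^2) - 2.15), 0.03)
})

test_that("one gross outlier barely moves skipped r but breaks Pearson", {
  set.seed(6)
  x <- rnorm(12)
  y <- 0.8 * x + rnorm(12, sd = 0.45)
  r_clean <- cor(x, y)
  x2 <- c(x[1:11], 4.5)
  y2 <- c(y[1:11], -4.5)
  r_naive <- cor(x2, y2)
  sc <- skipped_correlation(x2, y2, n_bootstrap = 0)
  expect_gt(abs(r_naive - r_clean), 0.2)
  expect_lt(abs(sc$r - r_clean), 0.1)
})

test_that("degenerate inputs are guarded", {
  x <- rnorm(12)
  expect_warning(sc <- skipped_correlation(x, x, n_bootstrap = 0),
                 "perfect correlation")
  expect_equal(sc$r, 1)
  expect_true(is.infinite(sc$t))

  expect_error(skipped_correlation(1:4, 4:1),
               class = "alphagate_parameter_error")
  expect_error(skipped_correlation(rep(1, 8), rnorm(8)),
               class = "alphagate_degenerate_error")
})

test_that("the bootstrap interval is seeded and deterministic", {
  set.seed(7)
  x <- rnorm(12); y <- 0.5 * x + rnorm(12)
  a <- skipped_correlation(x, y, n_bootstrap = 400, seed = 77)
  b <- skipped_correlation(x, y, n_bootstrap = 400, seed = 77)
  expect_identical(a$ci, b$ci)
  expect_true(a$ci[1] <= a$ci[2])
  expect_identical(a$significant, a$ci[1] > 0 || a$ci[2] < 0)
})

test_that("the battery covers every design cell and flags the inestimable", {
  ch <- toy_changes()
  bat <- correlation_battery(ch, n_bootstrap = 0)
  expect_equal(nrow(bat), 45L)
  expect_true(all(bat$estimable))
  expect_equal(nrow(dplyr::distinct(bat, group, index, outcome)), 45L)

  ch2 <- ch
  ch2$delta[ch2$metric == "fim"] <- 3  # constant outcome: zero variance
  bat2 <- correlation_battery(ch2, n_bootstrap = 0)
  expect_true(all(!bat2$estimable[bat2$outcome == "fim"]))
  expect_true(all(bat2$estimable[bat2$outcome != "fim"]))

  # under-filled cells are marked, not fatal
  ch3 <- ch[!(ch$group == "M1" & ch$subject_id %in%
                sprintf("M1%02d", 1:8)), ]
  bat3 <- correlation_battery(ch3, n_bootstrap = 0)
  expect_true(all(!bat3$estimable[bat3$group == "M1"]))
})

test_that("tidy and glance return broom-shaped summaries", {
  set.seed(8)
  x <- rnorm(12); y <- 0.6 * x + rnorm(12)
  sc <- skipped_correlation(x, y, n_bootstrap = 200, seed = 1)
  td <- tidy(sc)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("estimate", "statistic", "ci_low", "ci_high", "n",
                     "n_retained", "n_outliers", "significant"))
  gl <- glance(sc)
  expect_equal(gl$n_bootstrap, 200)
})
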