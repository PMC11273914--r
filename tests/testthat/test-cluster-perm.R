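test_that("identical paired conditions yield no clusters and zero t", {
  set.seed(1)
  a <- matrix(rnorm(6 * 30), 6)
  expect_warning(
    ct <- cluster_permutation_test(a, a, n_perm = 100, seed = 1),
    "degenerate variance"
  )
  expect_true(all(ct$t == 0))
  expect_equal(nrow(ct$clusters), 0L)
})

test_that("a planted difference is detected in the planted window", {
  set.seed(2)
  n_t <- 100
  time <- seq(-200, 198, by = 4)  # ms grid
  win <- time >= -64 & time <= 128
  a <- matrix(rnorm(12 * n_t), 12)
  a[, win] <- a[, win] + 1.6
  b <- matrix(rnorm(12 * n_t), 12)
  ct <- cluster_permutation_test(a, b, time = time, paired = TRUE,
                                 n_perm = 500, seed = 3)
  sig <- ct$clusters[ct$clusters$p_value < 0.05, ]
  expect_gte(nrow(sig), 1L)
  # detected cluster overlaps the planted window
  expect_true(any(sig$start <= 128 & sig$end >= -64))

  w <- windows_from_clusters(ct)
  expect_true(length(w) >= 1)
})

test_that("swapping condition labels flips mass and preserves p", {
  set.seed(4)
  a <- matrix(rnorm(8 * 50), 8) + 0.8
  b <- matrix(rnorm(8 * 50), 8)
  c1 <- cluster_permutation_test(a, b, n_perm = 300, seed = 5)
  c2 <- cluster_permutation_test(b, a, n_perm = 300, seed = 5)
  expect_equal(c1$clusters$mass, -c2$clusters$mass)
  expect_equal(c1$clusters$p_value, c2$clusters$p_value)
})

test_that("Monte-Carlo p matches full sign-flip enumeration at small n", {
  set.seed(6)
  n <- 8
  n_t <- 24
  a <- matrix(rnorm(n * n_t), n)
  a[, 8:14] <- a[, 8:14] + 1.1
  b <- matrix(rnorm(n * n_t), n)
  ct <- cluster_permutation_test(a, b, n_perm = 2000, seed = 7)
  expect_gte(nrow(ct$clusters), 1L)

  # independent oracle: enumerate all 2^8 sign assignments with plain loops
  d <- a - b
  t_crit <- qt(1 - 0.05 / 2, df = n - 1)
  t_stat <- function(m) {
    mu <- colMeans(m)
    se <- apply(m, 2, sd) / sqrt(n)
    ifelse(se == 0, 0, mu / se)
  }
  max_mass <- function(tv) {
    best <- 0
    cur <- 0
    cur_sign <- 0
    for (v in c(tv, 0)) {
      s <- if (abs(v) > t_crit) sign(v) else 0
      if (s != 0 && s == cur_sign) {
        cur <- cur + v
      } else {
        best <- max(best, abs(cur))
        cur <- if (s != 0) v else 0
        cur_sign <- s
      }
    }
    best
  }
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null_max <- apply(signs, 1, function(s) max_mass(t_stat(s * d)))
  obs <- abs(ct$clusters$mass[which.max(abs(ct$clusters$mass))])
  p_exact <- mean(null_max >= obs - 1e-12)
  p_mc <- min(ct$clusters$p_value)
  # Monte-Carlo standard error at p_exact with 2000 draws
  expect_lt(abs(p_mc - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 2000) + 1e-3)
})

test_that("the permutation null is deterministic under a fixed seed", {
  set.seed(8)
  a <- matrix(rnorm(10 * 40), 10) + 0.5
  b <- matrix(rnorm(10 * 40), 10)
  c1 <- cluster_permutation_test(a, b, n_perm = 200, seed = 9)
  c2 <- cluster_permutation_test(a, b, n_perm = 200, seed = 9)
  expect_identical(c1$clusters, c2$clusters)
})

test_that("window selection filters by alpha and falls back to defaults", {
  fake <- structure(
    list(clusters = tibble::tibble(
      start = c(-60, 40), end = c(-10, 90),
      mass = c(30, -12), p_value = c(0.01, 0.20)
    )),
    class = "cluster_test"
  )
  expect_equal(windows_from_clusters(fake), list(c(-60, -10)))
  expect_length(windows_from_clusters(fake, alpha = 1.0), 2L)

  none <- structure(
    list(clusters = tibble::tibble(start = numeric(), end = numeric(),
                                   mass = numeric(), p_value = numeric())),
    class = "cluster_test"
  )
  expect_equal(windows_from_clusters(none), default_windows())
  expect_equal(windows_from_clusters(none, fallback = NULL), list())
})

test_that("the unpaired path accepts unequal group sizes", {
  set.seed(10)
  a <- matrix(rnorm(9 * 30), 9) + 1.2
  b <- matrix(rnorm(7 * 30), 7)
  ct <- cluster_permutation_test(a, b, paired = FALSE, n_perm = 200,
                                 seed = 11)
  expect_true(all(is.finite(ct$t)))
  expect_error(
    cluster_permutation_test(a, b, paired = TRUE, n_perm = 200),
    class = "alphagate_parameter_error"
  )
  expect_error(
    cluster_permutation_test(a, b, paired = FALSE, n_perm = 50),
    class = "alphagate_parameter_error"
  )
})
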