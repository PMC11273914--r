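#' Cluster-based permutation test over time
#'
#' Nonparametric family-wise-error-controlling comparison of two conditions
#' sampled over time. A pointwise t statistic (paired or two-sample) is
#' computed at every sample; adjacent samples whose |t| exceeds the
#' cluster-forming threshold (the two-sided critical t at `threshold_p`) and
#' share a sign are grouped into clusters with mass equal to the summed t.
#' The null distribution of the maximum absolute cluster mass is built from
#' `n_perm` random sign flips (paired) or condition-label shuffles
#' (two-sample), and each observed cluster's p-value is the proportion of
#' null maxima at least as large as its |mass|, with the +1 correction in
#' numerator and denominator so p is never exactly 0.
#'
#' @param condition_a,condition_b `subjects x time` matrices on a shared
#'   time axis; equal row counts when `paired = TRUE`.
#' @param time Time axis (any units; cluster intervals are reported in it).
#'   Defaults to sample indices.
#' @param paired Paired (sign-flip) or independent (label-shuffle) design.
#' @param n_perm Number of random partitions (>= 100).
#' @param threshold_p Two-sided pointwise p forming the cluster threshold.
#' @param seed Integer seed for the permutation draw.
#' @return A `cluster_test` object: tibble `clusters` (`start`, `end`,
#'   `mass`, `p_value`), plus the threshold, pointwise `t`, `time`,
#'   `n_perm`, `seed`.
#' @examples
#' set.seed(1)
#' a <- matrix(rnorm(8 * 40), 8)
#' b <- matrix(rnorm(8 * 40), 8)
#' ct <- cluster_permutation_test(a, b, n_perm = 200, seed = 1)
#' ct$clusters
#' @export
cluster_permutation_test <- function(condition_a, condition_b,
                                     time = seq_len(ncol(condition_a)),
                                     paired = TRUE, n_perm = 1000,
                                     threshold_p = 0.05, seed = 1L) {
  if (ncol(condition_a) != ncol(condition_b)) {
    rlang::abort("conditions must share a time axis.",
                 class = "alphagate_parameter_error")
  }
  if (n_perm < 100) {
    rlang::abort("`n_perm` must be at least 100.",
                 class = "alphagate_parameter_error")
  }
  if (paired && nrow(condition_a) != nrow(condition_b)) {
    rlang::abort("paired design requires equal subject counts.",
                 class = "alphagate_parameter_error")
  }
  n_t <- ncol(condition_a)

  # Pointwise t for every row of a sign matrix (paired) or assignment
  # matrix (unpaired) in one BLAS call each.
  if (paired) {
    d <- condition_a - condition_b
    n <- nrow(d)
    t_crit <- stats::qt(1 - threshold_p / 2, df = n - 1)
    ss <- colSums(d^2)
    t_of_sign_rows <- function(S) {
      M <- (S %*% d) / n
      V <- sweep(-n * M^2, 2, ss, `+`) / (n - 1)
      T <- M / sqrt(V / n)
      T[V <= 1e-300 | !is.finite(T)] <- 0
      T
    }
    t_obs <- drop(t_of_sign_rows(matrix(1, 1, n)))
    if (any((ss - n * colMeans(d)^2) / (n - 1) <= 1e-300)) {
      rlang::warn("degenerate variance at some timepoints; their t set to 0.")
    }
  } else {
    na <- nrow(condition_a); nb <- nrow(condition_b)
    comb <- rbind(condition_a, condition_b)
    nn <- na + nb
    t_crit <- stats::qt(1 - threshold_p / 2, df = nn - 2)
    tot <- colSums(comb)
    tot2 <- colSums(comb^2)
    t_of_assign_rows <- function(G) {
      # G: 0/1 rows selecting condition a
      Sa <- G %*% comb
      Qa <- G %*% comb^2
      Sb <- sweep(-Sa, 2, tot, `+`)
      Qb <- sweep(-Qa, 2, tot2, `+`)
      Ma <- Sa / na; Mb <- Sb / nb
      Va <- (Qa - na * Ma^2) / (na - 1)
      Vb <- (Qb - nb * Mb^2) / (nb - 1)
      Sp <- ((na - 1) * Va + (nb - 1) * Vb) / (nn - 2)
      Se <- sqrt(Sp * (1 / na + 1 / nb))
      T <- (Ma - Mb) / Se
      T[Se <= 1e-150 | !is.finite(T)] <- 0
      T
    }
    g_obs <- matrix(0, 1, nn); g_obs[1, seq_len(na)] <- 1
    t_obs <- drop(t_of_assign_rows(g_obs))
  }

  obs_clusters <- find_clusters(t_obs, t_crit)

  null_max <- with_seed_if(seed, {
    if (paired) {
      S <- matrix(sample(c(-1, 1), n_perm * nrow(condition_a),
                         replace = TRUE), nrow = n_perm)
      Tmat <- t_of_sign_rows(S)
    } else {
      G <- matrix(0, n_perm, nrow(condition_a) + nrow(condition_b))
      for (i in seq_len(n_perm)) {
        G[i, sample.int(ncol(G), nrow(condition_a))] <- 1
      }
      Tmat <- t_of_assign_rows(G)
    }
    vapply(seq_len(n_perm), function(i) {
      max_cluster_mass(Tmat[i, ], t_crit)
    }, numeric(1))
  })

  clusters <- obs_clusters
  if (nrow(clusters)) {
    clusters$p_value <- vapply(clusters$mass, function(m) {
      (1 + sum(null_max >= abs(m))) / (n_perm + 1)
    }, numeric(1))
    clusters$start <- time[clusters$start_idx]
    clusters$end <- time[clusters$end_idx]
    clusters <- clusters[order(clusters$start_idx),
                         c("start", "end", "mass", "p_value")]
  } else {
    clusters <- tibble::tibble(start = numeric(), end = numeric(),
                               mass = numeric(), p_value = numeric())
  }
  structure(
    list(clusters = tibble::as_tibble(clusters),
         cluster_forming_threshold = t_crit, t = t_obs, time = time,
         n_permutations = n_perm, seed = seed, paired = paired),
    class = "cluster_test"
  )
}

# Largest absolute summed-t over contiguous supra-threshold runs (0 if none).
max_cluster_mass <- function(t_vals, t_crit) {
  lab <- sign(t_vals) * (abs(t_vals) > t_crit)
  if (!any(lab != 0)) return(0)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 0)
  max(abs(vapply(keep, function(k) sum(t_vals[starts[k]:ends[k]]),
                 numeric(1))))
}

# Contiguous runs of same-signed supra-threshold t values.
find_clusters <- function(t_vals, t_crit) {
  lab <- sign(t_vals) * (abs(t_vals) > t_crit)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  tibble::tibble(
    start_idx = starts[keep], end_idx = ends[keep],
    mass = vapply(which(keep), function(k) {
      sum(t_vals[starts[k]:ends[k]])
    }, numeric(1))
  )
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %s, %d permutations, |t| > %.2f\n",
              if (x$paired) "paired" else "independent",
              x$n_permutations, x$cluster_forming_threshold))
  print(x$clusters)
  invisible(x)
}

#' Tidy a cluster-test result
#' @param x A `cluster_test` object.
#' @param ... Unused.
#' @return Tibble of clusters with start, end, mass and p-value.
#' @export
tidy.cluster_test <- function(x, ...) x$clusters

#' Significant analysis windows from a cluster test
#'
#' Returns the time intervals of clusters with `p < alpha`, on the sampling
#' grid of the test. When no cluster survives, the fall-back is the
#' configured default windows (pre-onset -65-0 ms and post-onset 0-127 ms),
#' the theory-driven windows the indexes are defined on.
#'
#' @param result A `cluster_test` object.
#' @param alpha Significance level.
#' @param fallback List of default windows used when nothing survives;
#'   `NULL` returns an empty list instead.
#' @return List of numeric `c(start, end)` windows.
#' @export
windows_from_clusters <- function(result, alpha = 0.05,
                                  fallback = default_windows()) {
  cl <- result$clusters[result$clusters$p_value < alpha, , drop = FALSE]
  if (nrow(cl) == 0L) return(fallback %||% list())
  purrr::map(seq_len(nrow(cl)), function(i) c(cl$start[i], cl$end[i]))
}

#' Default analysis windows (ms relative to response onset)
#'
#' The pre-onset temporal-surge window and the post-onset central-frontal
#' suppression window used by the alpha indexes.
#'
#' @return Named list with `temporal` = c(-65, 0) and
#'   `central_frontal` = c(0, 127), in milliseconds.
#' @export
default_windows <- function() {
  list(temporal = c(-65, 0), central_frontal = c(0, 127))
}
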