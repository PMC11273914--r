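#' Anchor values for the synthetic clinical scales
#'
#' Group-level pre-training means/SDs and mean pre-to-post changes used to
#' scale the synthetic clinical scores, together with each instrument's
#' valid range (scores are clipped to it after noise addition: stroke-impact
#' ADL 0-100, functional independence 18-126, extended ADL 0-66, timed
#' motor test non-negative, strength score 0-5). The change-score SD is set
#' to half the pre-training SD, a typical test-retest spread for these
#' instruments.
#'
#' @return Tibble with one row per outcome x group.
#' @export
clinical_anchors <- function() {
  tibble::tribble(
    ~outcome, ~group, ~pre_mean, ~pre_sd, ~delta_mean, ~low, ~high,
    "sis_adl", "PMC", 74.58, 14.88, 1.88, 0, 100,
    "sis_adl", "M1", 71.25, 17.21, -1.53, 0, 100,
    "sis_adl", "Sham", 68.96, 17.24, 3.96, 0, 100,
    "fim", "PMC", 113.58, 9.48, -1.25, 18, 126,
    "fim", "M1", 106.50, 9.47, 0.17, 18, 126,
    "fim", "Sham", 106.50, 10.32, 2.92, 18, 126,
    "neadl", "PMC", 36.92, 15.63, 5.83, 0, 66,
    "neadl", "M1", 33.67, 13.35, 3.66, 0, 66,
    "neadl", "Sham", 34.25, 13.07, -1.42, 0, 66,
    "wmft_time", "PMC", 11.04, 6.48, 1.24, 0, Inf,
    "wmft_time", "M1", 14.25, 5.22, -3.50, 0, Inf,
    "wmft_time", "Sham", 9.72, 5.37, 0.84, 0, Inf,
    "wmft_strength", "PMC", 2.76, 0.67, 0.15, 0, 5,
    "wmft_strength", "M1", 2.51, 0.61, 0.18, 0, 5,
    "wmft_strength", "Sham", 3.06, 0.80, 0.17, 0, 5
  ) |>
    dplyr::mutate(delta_sd = .data$pre_sd / 2)
}

# Session-level scale of the true (latent) EEG indexes, dB.
index_truth_params <- function() {
  list(
    temporal = list(pre_mean = 0.8, pre_sd = 0.8,
                    change_mean = c(PMC = 0.8, M1 = -0.3, Sham = -0.2),
                    change_sd = 1.2),
    central_frontal = list(pre_mean = -0.8, pre_sd = 0.6,
                           change_mean = c(PMC = 0.2, M1 = -0.4, Sham = 0),
                           change_sd = 1.0)
  )
}

#' Simulate a full cohort: EEG recordings, clinical tables, ground truth
#'
#' Generates the complete synthetic study: per-group latent temporal-alpha
#' index changes, clinical change scores drawn from a bivariate model with
#' the configured planted correlation per (group, outcome), optional
#' bivariate outlier contamination (pairs displaced >= 4 robust SDs along
#' the minor axis of the planted distribution), pre/post clinical scores
#' clipped to instrument ranges, and (optionally) a continuous EEG
#' recording per subject-session whose temporal surge gain realizes the
#' subject's planted index change (`post gain = pre gain * 10^(change/20)`).
#' Everything planted is returned as ground truth.
#'
#' @param config A [simulation_config()].
#' @param eeg Generate continuous EEG recordings (slow) or tables only.
#' @param seed Overrides `config$seed` when non-NULL.
#' @return List with:
#' * `clinical`: tibble (subject_id, group, timepoint, five outcome columns),
#' * `truth_changes`: long tibble (subject_id, group, metric, delta) over the
#'   three indexes and five outcomes, ready for [correlation_battery()],
#' * `truth_sessions`: long per-session latent index values,
#' * `outlier_subjects`: ids whose pairs were displaced,
#' * `recordings`: tibble with list-columns `recording` and `blink_trials`
#'   (`NULL` when `eeg = FALSE`).
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_per_group = 6), eeg = FALSE)
#' dplyr::count(cohort$clinical, group, timepoint)
#' @export
simulate_cohort <- function(config, eeg = TRUE, seed = NULL) {
  validate_simulation_config(config)
  seed <- seed %||% config$seed
  with_seed_if(seed, {
    n <- config$n_per_group
    groups <- config$groups
    anchors <- clinical_anchors()
    ipar <- index_truth_params()
    outcomes <- clinical_outcomes()

    subjects <- tibble::tibble(
      subject_id = sprintf("S%02d", seq_len(n * length(groups))),
      group = rep(groups, each = n),
      lesion_side = rep_len(c("left", "right"), n * length(groups))
    )

    truth_rows <- list()
    clin_rows <- list()
    outlier_ids <- character(0)

    for (g in groups) {
      sub_g <- subjects[subjects$group == g, ]
      z <- stats::rnorm(n)
      tp <- ipar$temporal
      cp <- ipar$central_frontal
      d_temporal <- tp$change_mean[[g]] + tp$change_sd * z
      d_cf <- cp$change_mean[[g]] + cp$change_sd * stats::rnorm(n)

      # outcome changes: correlation with the temporal index change is the
      # planted rho for this (group, outcome)
      d_out <- matrix(NA_real_, n, length(outcomes),
                      dimnames = list(NULL, outcomes))
      for (oc in outcomes) {
        rho <- config$planted_rho[[g]][[oc]]
        a <- anchors[anchors$outcome == oc & anchors$group == g, ]
        eps <- stats::rnorm(n)
        d_out[, oc] <- a$delta_mean +
          a$delta_sd * (rho * z + sqrt(max(0, 1 - rho^2)) * eps)
      }

      # bivariate outlier contamination: displace along the minor axis
      n_out <- floor(config$outlier_fraction * n)
      if (n_out > 0) {
        who <- sample.int(n, n_out)
        signs <- sample(c(-1, 1), n_out, replace = TRUE)
        kdisp <- 5
        d_temporal[who] <- d_temporal[who] +
          signs * kdisp * tp$change_sd / sqrt(2)
        for (oc in outcomes) {
          a <- anchors[anchors$outcome == oc & anchors$group == g, ]
          d_out[who, oc] <- d_out[who, oc] -
            signs * kdisp * a$delta_sd / sqrt(2)
        }
        outlier_ids <- c(outlier_ids, sub_g$subject_id[who])
      }

      # latent session values of the indexes
      t_pre <- stats::rnorm(n, tp$pre_mean, tp$pre_sd)
      c_pre <- stats::rnorm(n, cp$pre_mean, cp$pre_sd)
      t_post <- t_pre + d_temporal
      c_post <- c_pre + d_cf
      ratio <- function(ta, cf) {
        vapply(seq_along(ta), function(i) {
          suppressWarnings(alpha_ratio(ta[i], cf[i]))
        }, numeric(1))
      }
      r_pre <- ratio(t_pre, c_pre)
      r_post <- ratio(t_post, c_post)

      truth_rows[[g]] <- tibble::tibble(
        subject_id = rep(sub_g$subject_id, times = 2),
        group = g,
        session = rep(c("pre", "post"), each = n),
        temporal_alpha = c(t_pre, t_post),
        central_frontal_alpha = c(c_pre, c_post),
        alpha_ratio = c(r_pre, r_post)
      )

      # clinical scores: pre draw + planted change, clipped to range
      for (tp_lab in c("pre", "post")) {
        row <- tibble::tibble(subject_id = sub_g$subject_id, group = g,
                              timepoint = tp_lab)
        for (oc in outcomes) {
          a <- anchors[anchors$outcome == oc & anchors$group == g, ]
          if (tp_lab == "pre") {
            v <- stats::rnorm(n, a$pre_mean, a$pre_sd)
            assign(paste0(".pre_", oc, "_", g), v)
          } else {
            v <- get(paste0(".pre_", oc, "_", g)) + d_out[, oc]
          }
          row[[oc]] <- pmin(pmax(v, a$low), a$high)
        }
        clin_rows[[paste(g, tp_lab)]] <- row
      }
    }

    truth_sessions <- dplyr::bind_rows(truth_rows)
    clinical <- dplyr::bind_rows(clin_rows)
    clinical <- clinical[order(match(clinical$subject_id, subjects$subject_id),
                               match(clinical$timepoint, c("pre", "post"))), ]

    idx_changes <- truth_sessions |>
      tidyr::pivot_longer(dplyr::all_of(c("temporal_alpha",
                                          "central_frontal_alpha",
                                          "alpha_ratio")),
                          names_to = "metric", values_to = "value") |>
      tidyr::pivot_wider(names_from = "session", values_from = "value") |>
      dplyr::mutate(delta = .data$post - .data$pre) |>
      dplyr::select("subject_id", "group", "metric", "delta")
    out_changes <- clinical |>
      dplyr::rename(session = "timepoint") |>
      change_scores(metrics = outcomes)
    truth_changes <- dplyr::bind_rows(idx_changes, out_changes)

    recordings <- NULL
    if (eeg) {
      t_chg <- idx_changes[idx_changes$metric == "temporal_alpha", ]
      c_chg <- idx_changes[idx_changes$metric == "central_frontal_alpha", ]
      rec_rows <- list()
      for (i in seq_len(nrow(subjects))) {
        sid <- subjects$subject_id[i]
        dT <- t_chg$delta[t_chg$subject_id == sid]
        dC <- c_chg$delta[c_chg$subject_id == sid]
        for (ses in c("pre", "post")) {
          eff <- if (ses == "pre") 1 else 10^(dT / 20)
          ceff <- if (ses == "pre") 1 else 10^(dC / 20)
          sim <- simulate_subject_recording(
            config, subject_effect = eff, cf_effect = ceff, session = ses,
            subject_id = sid, lesion_side = subjects$lesion_side[i]
          )
          rec_rows[[paste(sid, ses)]] <- tibble::tibble(
            subject_id = sid, group = subjects$group[i], session = ses,
            lesion_side = subjects$lesion_side[i],
            recording = list(sim$recording),
            blink_trials = list(sim$blink_trials)
          )
        }
      }
      recordings <- dplyr::bind_rows(rec_rows)
    }

    list(
      clinical = tibble::as_tibble(clinical),
      truth_changes = truth_changes,
      truth_sessions = truth_sessions,
      outlier_subjects = outlier_ids,
      planted_rho = config$planted_rho,
      recordings = recordings
    )
  })
}
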