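test_that("epoch geometry follows the half-open sampling convention", {
  cfg <- simulation_config(n_epochs_per_session = 2)
  ep <- simulate_subject_epochs(cfg, seed = 1)
  expect_equal(dim(ep$data), c(2L, 34L, 1000L))
  expect_equal(ep$time[1], -1)
  expect_equal(ep$time[length(ep$time)], 1 - 1 / 500)
  expect_true(any(ep$time == 0))
  expect_equal(which(ep$time == 0), 501L)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- small_config()
  a <- simulate_subject_epochs(cfg, seed = 42)
  b <- simulate_subject_epochs(cfg, seed = 42)
  expect_identical(a$data, b$data)

  ca <- simulate_cohort(small_config(outlier_fraction = 0.2), eeg = FALSE)
  cb <- simulate_cohort(small_config(outlier_fraction = 0.2), eeg = FALSE)
  expect_identical(ca$clinical, cb$clinical)
  expect_identical(ca$truth_changes, cb$truth_changes)
  expect_identical(ca$outlier_subjects, cb$outlier_subjects)
})

test_that("invalid configurations are refused", {
  expect_error(simulation_config(n_per_group = 3), class = "alphagate_config_error")
  expect_error(simulation_config(epoch_window = c(0.1, 1)),
               class = "alphagate_config_error")
  expect_error(simulation_config(outlier_fraction = 0.5),
               class = "alphagate_config_error")
  expect_error(simulation_config(surge_gain = 0.5),
               class = "alphagate_config_error")
  expect_error(simulation_config(cf_suppression_gain = 1.4),
               class = "alphagate_config_error")
  expect_error(simulation_config(planted_rho = list(PMC = c(bogus = 0.5),
                                                    M1 = 0, Sham = 0)))
  expect_error(
    simulation_config(channels = setdiff(montage_channels_32(), "T7")),
    class = "alphagate_config_error"
  )
})

test_that("temporal-window alpha power grows monotonically with surge gain", {
  gains <- c(1, 2, 3)
  med <- vapply(gains, function(g) {
    vals <- vapply(1:3, function(i) {
      cfg <- simulation_config(n_epochs_per_session = 12, surge_gain = g,
                               artifact_rate = 0)
      ep <- simulate_subject_epochs(cfg, seed = 300 + i)
      m <- alpha_power_map(ep)
      region_window_mean(m, "temporal", c(-65, 127)) -
        region_window_mean(m, "temporal", c(-650, -400))
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(med[2] > med[1])
  expect_true(med[3] > med[2])
  # with both gains at 1 the forward model is null: contrast near 0
  expect_lt(abs(med[1]), 0.6)
})

test_that("blink injection is additive, frontal-dominant and binomial", {
  cfg <- small_config(n_epochs_per_session = 20)
  ep <- simulate_subject_epochs(cfg, seed = 7)

  none <- inject_artifacts(ep, rate = 0)
  expect_identical(none$epochs$data, ep$data)
  expect_length(none$injected, 0)

  res <- inject_artifacts(ep, rate = 0.5, seed = 11)
  expect_true(length(res$injected) >= 1)
  fp <- match(c("Fp1", "Fp2"), ep$channels)
  for (e in res$injected) {
    before <- max(apply(ep$data[e, fp, ], 1, function(z) diff(range(z))))
    after <- max(apply(res$epochs$data[e, fp, ], 1,
                       function(z) diff(range(z))))
    expect_gt(after, before)
  }
  untouched <- setdiff(seq_len(20), res$injected)
  expect_identical(res$epochs$data[untouched, , ], ep$data[untouched, , ])

  counts <- vapply(1:30, function(i) {
    length(inject_artifacts(ep, rate = 0.3, seed = 100 + i)$injected)
  }, numeric(1))
  # mean count ~ Binomial(20, 0.3): 6 +/- tight Monte-Carlo band
  expect_gt(mean(counts), 4)
  expect_lt(mean(counts), 8)
})

test_that("cohort tables carry the planted design", {
  cfg <- small_config(n_per_group = 6, outlier_fraction = 0.34)
  co <- simulate_cohort(cfg, eeg = FALSE)
  expect_equal(nrow(co$clinical), 6 * 3 * 2)
  expect_setequal(unique(co$clinical$timepoint), c("pre", "post"))
  anchors <- clinical_anchors()
  for (oc in clinical_outcomes()) {
    rng <- anchors[anchors$outcome == oc, c("low", "high")][1, ]
    expect_true(all(co$clinical[[oc]] >= rng$low & co$clinical[[oc]] <= rng$high))
  }
  # floor(0.34 * 6) = 2 displaced subjects per group
  expect_equal(length(co$outlier_subjects), 3 * 2)
  expect_true(all(co$outlier_subjects %in% co$clinical$subject_id))
  # change table covers 3 indexes + 5 outcomes per subject
  expect_equal(nrow(co$truth_changes), 18 * 8)
})

test_that("planted correlation is recovered on average without contamination", {
  rs <- vapply(1:30, function(i) {
    cfg <- simulation_config(seed = 7000 + i)
    co <- simulate_cohort(cfg, eeg = FALSE)
    ch <- co$truth_changes
    x <- ch$delta[ch$group == "PMC" & ch$metric == "temporal_alpha"]
    y <- ch$delta[ch$group == "PMC" & ch$metric == "sis_adl"]
    sc <- skipped_correlation(x, y, n_bootstrap = 0)
    sc$r
  }, numeric(1))
  # mean recovered skipped r close to the planted 0.6 (n = 12 per cohort)
  expect_lt(abs(mean(rs) - 0.6), 3 * stats::sd(rs) / sqrt(length(rs)) + 0.05)
})

test_that("synthetic recordings carry contralesional and ipsilateral events", {
  cfg <- small_config()
  sim <- simulate_subject_recording(cfg, lesion_side = "left", seed = 3)
  rec <- sim$recording
  expect_s3_class(rec, "eeg_recording")
  expect_equal(sum(rec$events$response_hand == "right"), 6)
  expect_gt(sum(rec$events$response_hand == "left"), 0)
  expect_true(all(rec$events$sample > 0 & rec$events$sample <= ncol(rec$data)))
})
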