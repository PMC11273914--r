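test_that("band-pass keeps mid-band, rejects stop-band and DC", {
  rec10 <- sine_recording(10, 20)
  out10 <- bandpass_filter(rec10, 0.5, 40)
  a10 <- component_amplitude(out10$data[1, ], 10, 500)
  expect_lt(abs(a10 - 20) / 20, 0.01)

  rec80 <- sine_recording(80, 20)
  out80 <- bandpass_filter(rec80, 0.5, 40)
  expect_lt(rms(out80$data[1, ]) / rms(rec80$data[1, ]), 10^(-20 / 20))

  recdc <- sine_recording(10, 20, dc = 100)
  outdc <- bandpass_filter(recdc, 0.5, 40)
  expect_lt(abs(mean(outdc$data[1, ])), 1)

  expect_error(bandpass_filter(rec10, 40, 0.5),
               class = "alphagate_parameter_error")
  expect_error(bandpass_filter(rec10, 0.5, 400),
               class = "alphagate_parameter_error")
})

test_that("filtering and re-referencing are linear operators", {
  set.seed(5)
  fs <- 250
  x <- matrix(rnorm(2 * fs * 4), nrow = 2)
  y <- matrix(rnorm(2 * fs * 4), nrow = 2)
  mk <- function(m) eeg_recording(m, c("C3", "C4"), fs)
  f <- function(m) bandpass_filter(mk(m), 1, 30)$data
  expect_equal(f(2 * x + 3 * y), 2 * f(x) + 3 * f(y), tolerance = 1e-9)
})

test_that("line-noise removal targets the line frequency only", {
  mix <- sine_recording(c(10, 60), c(15, 10))
  out <- remove_line_noise(mix, 60)
  a60 <- component_amplitude(out$data[1, ], 60, 500)
  a10 <- component_amplitude(out$data[1, ], 10, 500)
  expect_lt(a60 / 10, 10^(-20 / 20))
  expect_lt(abs(a10 - 15) / 15, 0.05)

  pure <- sine_recording(60, 10)
  outp <- remove_line_noise(pure, 60)
  expect_lt(rms(outp$data[1, ]) / rms(pure$data[1, ]), 0.10)

  clean <- sine_recording(c(7, 23), c(12, 5))
  outc <- remove_line_noise(clean, 60)
  expect_lt(rms(outc$data[1, ] - clean$data[1, ]) / rms(clean$data[1, ]),
            0.01)

  expect_error(remove_line_noise(pure, 55),
               class = "alphagate_parameter_error")
})

test_that("epoch extraction selects contralesional responses and pure-slices", {
  fs <- 100
  set.seed(8)
  data <- matrix(rnorm(2 * fs * 30), nrow = 2)
  events <- tibble::tibble(
    sample = c(300, 700, 1100, 1500, 2950),
    label = "response",
    response_hand = c("left", "right", "right", "left", "right")
  )
  rec <- eeg_recording(data, c("C3", "C4"), fs, events = events,
                       lesion_side = "left")
  # three right-hand (contralesional) events, but the one at sample 2950
  # needs samples up to 3049 > 3000 and is dropped with a warning
  expect_warning(ep <- extract_epochs(rec, window = c(-1, 1)), "dropped")
  expect_equal(dim(ep$data)[1], 2L)
  # pure slicing: values match the raw recording exactly
  expect_identical(ep$data[1, , ], data[, (700 - 100):(700 + 99)])

  # right lesion: the two left-hand events, all inside the recording
  rec2 <- eeg_recording(data, c("C3", "C4"), fs, events = events,
                        lesion_side = "right")
  ep2 <- extract_epochs(rec2, window = c(-1, 1))
  expect_equal(dim(ep2$data)[1], 2L)

  rec3 <- eeg_recording(data, c("C3", "C4"), fs,
                        events = events[events$response_hand == "left", ],
                        lesion_side = "left")
  expect_error(extract_epochs(rec3), class = "alphagate_empty_epochs_error")
})

test_that("linked-mastoid re-referencing shifts by the mastoid mean", {
  time <- seq(-0.5, 0.5 - 1 / 100, by = 1 / 100)
  n_s <- length(time)
  chans <- c("C3", "TP9", "TP10")
  data <- array(0, dim = c(2, 3, n_s))
  data[, 1, ] <- 7

  ep0 <- eeg_epochs(data, chans, 100, time)
  out0 <- rereference_linked_mastoids(ep0)
  expect_equal(out0$data, ep0$data)
  expect_equal(out0$reference_state, "linked-mastoids")

  data5 <- data
  data5[, 2, ] <- 5
  data5[, 3, ] <- 5
  ep5 <- eeg_epochs(data5, chans, 100, time)
  out5 <- rereference_linked_mastoids(ep5)
  expect_equal(out5$data[, 1, ], data5[, 1, ] - 5)
  expect_true(all(abs(out5$data[, 2:3, ]) < 1e-12))
  # idempotent once the mastoids are zeroed
  out5b <- rereference_linked_mastoids(out5)
  expect_equal(out5b$data, out5$data)

  expect_error(rereference_linked_mastoids(ep0, mastoids = c("M1", "M2")),
               class = "alphagate_config_error")
})

test_that("ocular removal cleans blinks and spares posterior alpha", {
  cfg <- simulation_config(n_epochs_per_session = 12, artifact_rate = 0)
  ep <- simulate_subject_epochs(cfg, seed = 21)
  res <- inject_artifacts(ep, rate = 0.4, seed = 22)
  contaminated <- res$epochs

  cleaned <- remove_ocular_artifacts(contaminated)
  expect_gt(cleaned$n_components_removed, 0)
  fp <- match(c("Fp1", "Fp2"), ep$channels)
  post <- match(c("O1", "Oz", "O2"), ep$channels)
  for (e in res$injected) {
    ptp_dirty <- max(apply(contaminated$data[e, fp, ], 1,
                           function(z) diff(range(z))))
    ptp_clean <- max(apply(cleaned$epochs$data[e, fp, ], 1,
                           function(z) diff(range(z))))
    expect_lt(ptp_clean, 0.5 * ptp_dirty)
  }
  rms_before <- rms(contaminated$data[, post, ])
  rms_after <- rms(cleaned$epochs$data[, post, ])
  expect_lt(abs(rms_after - rms_before) / rms_before, 0.10)
})

test_that("ocular removal is the identity when nothing couples to EOG", {
  cfg <- small_config(n_epochs_per_session = 4)
  ep <- simulate_subject_epochs(cfg, seed = 31)
  out <- remove_ocular_artifacts(ep)
  expect_equal(out$n_components_removed, 0)
  expect_equal(out$epochs$data, ep$data, tolerance = 1e-8)

  # unreachable threshold: identity within numerical tolerance
  dirty <- inject_artifacts(ep, rate = 0.5, seed = 32)$epochs
  out2 <- remove_ocular_artifacts(dirty, threshold = 1.01)
  expect_equal(out2$n_components_removed, 0)
  expect_equal(out2$epochs$data, dirty$data, tolerance = 1e-8)
})

test_that("regression fallback engages when the backend fails", {
  cfg <- small_config(n_epochs_per_session = 4)
  ep <- simulate_subject_epochs(cfg, seed = 33)
  bad_backend <- function(Xc) stop("backend exploded")
  expect_warning(
    out <- remove_ocular_artifacts(ep, backend = bad_backend),
    "falling back"
  )
  expect_equal(out$method, "regression")
})

test_that("the minimum-epoch gate keeps clean epochs and refuses thin sets", {
  time <- seq(-1, 1 - 1 / 50, by = 1 / 50)
  data <- array(rnorm(60 * 2 * length(time)), dim = c(60, 2, length(time)))
  ep <- eeg_epochs(data, c("C3", "C4"), 50, time)

  ep$artifact_flags[1:5] <- TRUE
  kept <- enforce_min_epochs(ep, minimum = 50)
  expect_equal(dim(kept$data)[1], 55L)

  ep$artifact_flags <- rep(FALSE, 60)
  ep$artifact_flags[1:15] <- TRUE
  err <- expect_error(enforce_min_epochs(ep, minimum = 50),
                      class = "alphagate_exclusion_error")
  expect_equal(err$n_clean, 45L)

  ep$artifact_flags <- rep(FALSE, 60)
  ep$artifact_flags[1:10] <- TRUE  # exactly 50 clean: boundary passes
  expect_silent(kept50 <- enforce_min_epochs(ep, minimum = 50))
  expect_equal(dim(kept50$data)[1], 50L)
})

test_that("peak-to-peak flagging marks large epochs only", {
  time <- seq(-1, 1 - 1 / 50, by = 1 / 50)
  data <- array(rnorm(10 * 2 * length(time), sd = 5),
                dim = c(10, 2, length(time)))
  data[3, 1, 40] <- 400
  ep <- eeg_epochs(data, c("C3", "C4"), 50, time)
  flagged <- flag_artifact_epochs(ep, ptp_limit = 150)
  expect_true(flagged$artifact_flags[3])
  expect_false(any(flagged$artifact_flags[-3]))
})
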