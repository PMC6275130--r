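test_that("flat components give empty peak lists, not errors", {
  z <- acceleration_trace(numeric(500), 50)
  expect_length(detect_peaks(z, "heartbeat")$peak_times_s, 0L)
  expect_length(detect_peaks(z, "respiration")$peak_times_s, 0L)
})

test_that("a strict impulse train is recovered at exactly its spacing", {
  fs <- 50
  x <- numeric(60 * fs)
  x[seq(25, length(x), by = 50)] <- 1
  p <- detect_peaks(acceleration_trace(x, fs), "heartbeat")
  expect_gt(length(p$peak_times_s), 50L)
  # exactly 50 samples (1.0 s) between consecutive detections
  expect_true(all(diff(round(p$peak_times_s * fs)) == 50L))
  expect_equal(diff(p$peak_times_s), rep(1.0, length(p$peak_times_s) - 1L))
})

test_that("noiseless simulated beats at 60 bpm are found at their true times", {
  dur <- 60
  sim <- sim_trace(duration_s = dur, heart_rate_bpm = 60, noise_sd = 0,
                   rate_jitter_frac = 0)
  b <- separate_bands(sim$trace)
  p <- detect_peaks(b$cardiac, "heartbeat")
  bt <- sim$ground_truth$beat_times_s
  expect_gte(length(p$peak_times_s), 59L)
  expect_lte(length(p$peak_times_s), 61L)
  # each detection within 40 ms of a true beat
  off <- vapply(p$peak_times_s, function(pt) min(abs(pt - bt)), numeric(1))
  expect_lt(max(off), 0.040 + 1e-9)
  # refractory invariant
  expect_true(all(diff(p$peak_times_s) >=
                    p$detection_params$refractory_s - 1e-9))
})

test_that("windowed rates follow the median inter-peak interval", {
  mk_peaks <- function(times) {
    structure(list(peak_times_s = times,
                   peak_amplitudes = rep(1, length(times)),
                   detection_params = list(kind = "heartbeat",
                                           refractory_s = 0.27)),
              class = "peak_list")
  }
  # uniform train: 60 events/min
  rs <- rate_from_peaks(mk_peaks(0:59), window_length_s = 60, hop_s = 10,
                        duration_s = 60)
  expect_equal(rs$rate, 60.0)
  # intervals {1, 1, 2}: median 1 s -> 60 events/min
  rs2 <- rate_from_peaks(mk_peaks(c(0, 1, 2, 4)), window_length_s = 60,
                         hop_s = 10, duration_s = 60)
  expect_equal(rs2$rate, 60.0)
  # under 2 peaks -> invalid, carried not dropped
  rs3 <- rate_from_peaks(mk_peaks(c(10)), window_length_s = 60, hop_s = 10,
                         duration_s = 60)
  expect_false(any(rs3$valid))
  expect_identical(nrow(rs3), 1L)
  expect_error(rate_from_peaks(mk_peaks(0:10), window_length_s = -1),
               class = "scg_invalid_config")
})

test_that("session summary reports medians, means and invalid counts", {
  rs <- rate_series(c(30, 40, 50), c(10, 20, 30), kind = "respiration")
  s <- session_summary(rs)
  expect_equal(s$median, 20)
  expect_equal(s$mean, 20)
  expect_identical(s$n_valid, 3L)
  const <- rate_series(1:12 * 10, rep(20, 12), kind = "respiration")
  sc <- session_summary(const)
  expect_equal(sc$median, 20)
  expect_equal(sc$mean, 20)
  none <- rate_series(c(10, 20), c(70, 71), kind = "heartbeat",
                      valid = FALSE)
  expect_error(session_summary(none), class = "scg_no_valid_data")
})

test_that("the rest scenario (76 bpm, 20 brpm) is recovered from a session", {
  est <- recover_rates(76, 20, noise_sd = 0.01, duration_s = 600)
  expect_lt(abs(est["hr"] - 76), 2)
  expect_lt(abs(est["rr"] - 20), 1)
})

test_that("a breath-hold protocol recovers the 5 breaths/min truth", {
  # 60 s hold (no respiratory motion) followed by slow deep breathing
  hold <- sim_trace(duration_s = 60, heart_rate_bpm = 68,
                    resp_amplitude = 0, seed = 21)
  breathing <- sim_trace(duration_s = 540, heart_rate_bpm = 68,
                         resp_rate_brpm = 5, resp_amplitude = 2, seed = 22)
  tr <- acceleration_trace(c(hold$trace$samples, breathing$trace$samples), 50)
  b <- separate_bands(tr)
  rr <- session_summary(rate_from_peaks(
    detect_peaks(b$respiratory, "respiration"),
    duration_s = 600, transient_s = 5))$median
  expect_lt(abs(rr - 5), 1)
})

test_that("recovered heart rate is monotone in the simulated truth", {
  est <- vapply(c(50, 76, 100, 150),
                function(hr) recover_rates(hr, 12)["hr"], numeric(1))
  expect_true(all(diff(est) > 0))
})
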