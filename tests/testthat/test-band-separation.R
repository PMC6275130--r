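test_that("normalized cutoff follows both conventions", {
  expect_identical(normalized_cutoff(0.5, 50, "sampling_rate"), 0.01)
  expect_identical(normalized_cutoff(0.5, 50, "nyquist"), 0.02)
  for (f in c(0.3, 1, 7)) {
    expect_equal(normalized_cutoff(f, 4 * f, "nyquist"), 0.5)
  }
  expect_error(normalized_cutoff(25, 50), class = "scg_invalid_filter")
  expect_error(normalized_cutoff(30, 50), class = "scg_invalid_filter")
})

test_that("designed filters hit the Butterworth -3 dB point exactly", {
  spec <- filter_spec()
  for (fs in c(50, 500)) {
    for (kind in c("lowpass", "highpass")) {
      d <- design_butterworth(spec, kind, fs)
      expect_equal(filter_magnitude(d, 0.5), 1 / sqrt(2), tolerance = 1e-6)
    }
  }
})

test_that("magnitude response matches the warped analytic form at 50 Hz", {
  # oracle: analog Butterworth magnitude evaluated at bilinear-warped
  # frequency ratios tan(pi f / fs) / tan(pi fc / fs)
  spec <- filter_spec()
  fs <- 50
  fc <- 0.5
  lp <- design_butterworth(spec, "lowpass", fs)
  hp <- design_butterworth(spec, "highpass", fs)
  for (f in c(0.05, 0.2, 1, 5)) {
    w <- tan(pi * f / fs) / tan(pi * fc / fs)
    expect_equal(filter_magnitude(lp, f), 1 / sqrt(1 + w^4),
                 tolerance = 1e-8)
    expect_equal(filter_magnitude(hp, f), 1 / sqrt(1 + (1 / w)^4),
                 tolerance = 1e-8)
  }
})

test_that("far below Nyquist the response matches the analog closed form", {
  spec <- filter_spec()
  fs <- 500
  lp <- design_butterworth(spec, "lowpass", fs)
  hp <- design_butterworth(spec, "highpass", fs)
  # f/fc = 10 for the lowpass, 0.1 for the highpass: both ~0.0100
  expect_equal(filter_magnitude(lp, 5), 1 / sqrt(1 + 10^4),
               tolerance = 0.05)
  expect_equal(filter_magnitude(hp, 0.05), 1 / sqrt(1 + 10^4),
               tolerance = 0.05)
})

test_that("an all-zero trace separates into all-zero components", {
  tr <- acceleration_trace(numeric(500), 50)
  b <- separate_bands(tr)
  expect_true(all(b$cardiac$samples == 0))
  expect_true(all(b$respiratory$samples == 0))
  expect_length(b$cardiac$samples, 500L)
  expect_identical(b$cardiac$sampling_rate_hz, 50)
})

test_that("band-extreme tones are routed to exactly one component", {
  fs <- 50
  t <- (0:(60 * fs - 1)) / fs
  slow <- acceleration_trace(sin(2 * pi * 0.05 * t), fs)
  fast <- acceleration_trace(sin(2 * pi * 5 * t), fs)
  bs <- separate_bands(slow)
  bf <- separate_bands(fast)
  expect_gte(mid_amplitude(bs$respiratory$samples, fs), 0.99)
  expect_lte(mid_amplitude(bs$cardiac$samples, fs), 0.001)
  expect_gte(mid_amplitude(bf$cardiac$samples, fs), 0.99)
  expect_lte(mid_amplitude(bf$respiratory$samples, fs), 0.001)
})

test_that("separation is linear", {
  fs <- 50
  t <- (0:(30 * fs - 1)) / fs
  x <- sin(2 * pi * 0.2 * t)
  y <- 0.3 * sin(2 * pi * 3 * t + 1)
  bx <- separate_bands(acceleration_trace(x, fs))
  by <- separate_bands(acceleration_trace(y, fs))
  bxy <- separate_bands(acceleration_trace(x + y, fs))
  expect_equal(bxy$cardiac$samples,
               bx$cardiac$samples + by$cardiac$samples, tolerance = 1e-9)
  expect_equal(bxy$respiratory$samples,
               bx$respiratory$samples + by$respiratory$samples,
               tolerance = 1e-9)
})

test_that("zero-phase mode introduces no lag at mid-band", {
  fs <- 50
  t <- (0:(60 * fs - 1)) / fs
  tone <- sin(2 * pi * 2 * t)
  b <- separate_bands(acceleration_trace(tone, fs))
  keep <- (5 * fs):(55 * fs)
  cc <- stats::ccf(tone[keep], b$cardiac$samples[keep], lag.max = 25,
                   plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf)], 0)
})

test_that("degenerate inputs raise classed errors", {
  expect_error(separate_bands(acceleration_trace(rnorm(5), 50)),
               class = "scg_insufficient_data")
  tr <- acceleration_trace(rnorm(100), 50)
  tr$samples[10] <- NaN
  expect_error(separate_bands(tr), class = "scg_invalid_trace")
  expect_error(design_butterworth(filter_spec(cutoff_hz = 30), "highpass", 50),
               class = "scg_invalid_filter")
})
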