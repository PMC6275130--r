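test_that("distribution shape measures range and modal bin count", {
  # hand-built histogram: rates {70 x5, 71 x10, 72 x5}, bin width 1
  r <- rep(c(70, 71, 72), c(5, 10, 5))
  rs <- rate_series(seq_along(r) * 10, r, kind = "heartbeat")
  shp <- estimate_distribution_shape(rs, bin_width = 1)
  expect_equal(shp$length_L, 2)
  expect_identical(shp$height_h, 10L)
  expect_false(shp$degenerate)
})

test_that("a constant series is degenerate with height n", {
  rs <- rate_series(1:20 * 10, rep(70, 20), kind = "heartbeat")
  shp <- estimate_distribution_shape(rs)
  expect_equal(shp$length_L, 0)
  expect_identical(shp$height_h, 20L)
  expect_true(shp$degenerate)
})

test_that("Gaussian-simulated rates match an independent histogram count", {
  set.seed(123)
  r <- stats::rnorm(360, mean = 76, sd = 3)
  rs <- rate_series(seq_along(r) * 10, r, kind = "heartbeat")
  shp <- estimate_distribution_shape(rs, bin_width = 1)
  expect_gte(shp$length_L, 4 * 3)
  expect_lte(shp$length_L, 8 * 3)
  # oracle: brute-force bin counting
  expect_identical(shp$height_h, as.integer(max(table(floor(r / 1)))))
  expect_identical(shp$n_samples, 360L)
})

test_that("too few valid windows is an error", {
  rs <- rate_series(1:5 * 10, 70:74, kind = "heartbeat")
  expect_error(estimate_distribution_shape(rs),
               class = "scg_insufficient_data")
})

test_that("healthy measure is length over height", {
  expect_equal(healthy_measure(distribution_shape(17, 10))$value, 1.7)
  for (k in c(1, 4, 20)) {
    expect_equal(healthy_measure(distribution_shape(k, k))$value, 1.0)
  }
  expect_equal(healthy_measure(distribution_shape(34, 20))$value, 1.7)
  expect_error(healthy_measure(distribution_shape(5, 0)),
               class = "scg_degenerate_distribution")
})

test_that("widening a distribution never decreases the measure", {
  h <- 12
  vals <- vapply(seq(1, 40, by = 0.5),
                 function(L) healthy_measure(distribution_shape(L, h))$value,
                 numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("classification is a step function with severe-side boundaries", {
  borders <- default_class_borders("heartbeat")
  expect_identical(classify_health(1.7, kind = "heartbeat")$label, "healthy")
  expect_identical(classify_health(9.88, kind = "heartbeat")$label,
                   "dangerous")
  expect_identical(classify_health(5.56, kind = "heartbeat")$label,
                   "emergency")
  # boundary values belong to the more severe class
  expect_identical(classify_health(borders[1], kind = "heartbeat")$label,
                   "emergency")
  expect_identical(classify_health(borders[2], kind = "heartbeat")$label,
                   "dangerous")
  # label changes only at the borders
  m <- seq(0.1, 12, by = 0.01)
  labs <- vapply(m, function(v) classify_health(v, kind = "heartbeat")$label,
                 character(1))
  switches <- m[which(labs[-1] != labs[-length(labs)]) + 1L]
  expect_equal(switches, borders, tolerance = 0.011)
  expect_error(classify_health(1, borders = c(2, 2)),
               class = "scg_invalid_config")
})

test_that("respiration borders separate the three reported class values", {
  expect_identical(classify_health(1.54, kind = "respiration")$label,
                   "healthy")
  expect_identical(classify_health(1.9, kind = "respiration")$label,
                   "emergency")
  expect_identical(classify_health(2.3, kind = "respiration")$label,
                   "dangerous")
})

test_that("the measure is invariant under permutation of the series", {
  set.seed(9)
  r <- stats::rnorm(60, 76, 4)
  m1 <- healthy_measure(estimate_distribution_shape(
    rate_series(1:60 * 10, r, kind = "heartbeat")))$value
  m2 <- healthy_measure(estimate_distribution_shape(
    rate_series(1:60 * 10, sample(r), kind = "heartbeat")))$value
  expect_identical(m1, m2)
})

test_that("the normal-fit variant scales with the sample SD", {
  set.seed(4)
  r <- stats::rnorm(200, 76, 3)
  rs <- rate_series(seq_along(r) * 10, r, kind = "heartbeat")
  shp <- estimate_distribution_shape(rs, method = "normal", z = 2)
  expect_equal(shp$length_L, 4 * stats::sd(r))
  expect_equal(shp$height_h,
               200 * stats::dnorm(0) / stats::sd(r))
})
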