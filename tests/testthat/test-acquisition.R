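# Tare tracking, gain calibration, range filtering and the segmentation
# state machine.

test_that("tare converges to the empty-pan level and resists outliers", {
  cfg <- acquisition_config()

  st <- tare_state()
  for (i in 1:64) st <- update_tare(st, 10, cfg)
  expect_equal(st$tare, 10)
  expect_equal(st$n_updates, 64L)
  expect_length(st$buffer, 64)

  st <- update_tare(tare_state(), 9.8, cfg)
  expect_equal(st$tare, 9.8)

  # one 250 g wind spike among 63 clean readings barely moves the estimate
  set.seed(101)
  st <- tare_state()
  vals <- c(rnorm(63, 10, 0.1), 250)
  for (v in vals) st <- update_tare(st, v, cfg)
  expect_lt(abs(st$tare - 10), 0.2)
  expect_lt(abs(st$tare - median(st$buffer)), 0.2)
})

test_that("tare IRLS agrees with an independent Huber M-estimator", {
  skip_if_not_installed("MASS")
  cfg <- acquisition_config()
  set.seed(202)
  for (rep in 1:20) {
    vals <- c(rnorm(50, 10, 0.5), runif(sample(0:12, 1), 100, 300))
    st <- tare_state()
    for (v in vals) st <- update_tare(st, v, cfg)
    oracle <- MASS::huber(st$buffer, k = cfg$huber_k)$mu
    expect_equal(st$tare, oracle, tolerance = 1e-4)
  }
})

test_that("tare error stays within the contamination bound", {
  cfg <- acquisition_config()
  set.seed(303)
  mu <- 12; sigma <- 0.5; window <- cfg$tare_window
  for (rep in 1:20) {
    n_out <- sample(0:12, 1)  # up to ~20% contamination
    vals <- sample(c(rnorm(window - n_out, mu, sigma), runif(n_out, 100, 300)))
    st <- tare_state()
    for (v in vals) st <- update_tare(st, v, cfg)
    expect_lt(abs(st$tare - mu), 5 * sigma / sqrt(window))
  }
})

test_that("gain calibration recovers linear scale response", {
  g <- fit_gain(c(100, 200), c(100, 200))
  expect_equal(g$gain, 1)
  expect_equal(g$offset, 0)

  g <- fit_gain(c(100, 200), c(99, 199))
  expect_equal(g$gain, 1)
  expect_equal(g$offset, 1)

  set.seed(404)
  raw <- c(50, 100, 150, 200, 250)
  ref <- 1.02 * raw + rnorm(5, 0, 0.05)
  g <- fit_gain(ref, raw)
  expect_lt(abs(g$gain - 1.02) / 1.02, 0.01)
  expect_gte(g$residual_rms, 0)

  expect_error(fit_gain(c(100, 200), c(150, 150)), "distinct")
})

test_that("calibration arithmetic and the range filter behave", {
  expect_equal(apply_calibration(160, 10), 150)
  expect_equal(apply_calibration(160, 10, gain_calibration(1.01, -0.5)), 151.1)
  expect_equal(apply_calibration(10, 10), 0)

  cfg <- acquisition_config()
  expect_true(is_in_range(150, cfg))
  expect_false(is_in_range(400, cfg))
  expect_true(is_in_range(50, cfg))   # boundaries inclusive
  expect_true(is_in_range(300, cfg))
  expect_false(is_in_range(49.99, cfg))
})

test_that("segmentation hand traces hold sample-for-sample", {
  cfg <- acquisition_config()

  # clean visit: 10 empty, 30 on-pan, 6 empty -> one 30-sample pattern
  w <- c(rep(0, 10), rep(150, 30), rep(0, 6))
  res <- segment_vector(w, cfg)
  expect_length(res$patterns, 1)
  expect_equal(nrow(res$patterns[[1]]$samples), 30)
  expect_equal(res$patterns[[1]]$samples$tick, 11:40)
  expect_false(res$patterns[[1]]$truncated)

  # all below threshold: no patterns, one tare update per sample
  w <- rep(10, 46)
  res <- segment_vector(w, cfg)
  expect_length(res$patterns, 0)
  expect_equal(res$summary$tare_updates, 46L)

  # sub-critical dip is retained: 30 + 3-sample 20 g dip -> 33 samples
  w <- c(rep(150, 15), rep(20, 3), rep(150, 15), rep(0, 6))
  res <- segment_vector(w, cfg)
  expect_length(res$patterns, 1)
  expect_equal(nrow(res$patterns[[1]]$samples), 33)
  expect_equal(sum(res$patterns[[1]]$samples$weight_g == 20), 3)
})

test_that("segmentation strips trailing below-threshold samples and flags truncation", {
  cfg <- acquisition_config()

  # 4 below-threshold samples then recovery: dip retained, pattern continues
  w <- c(rep(150, 10), rep(20, 4), rep(150, 10), rep(0, 8))
  res <- segment_vector(w, cfg)
  expect_length(res$patterns, 1)
  expect_equal(nrow(res$patterns[[1]]$samples), 24)

  # 5th consecutive below-threshold sample closes; none of them survive
  w <- c(rep(150, 20), rep(20, 5), rep(150, 20), rep(0, 8))
  res <- segment_vector(w, cfg)
  expect_length(res$patterns, 2)
  expect_equal(nrow(res$patterns[[1]]$samples), 20)
  tail_w <- res$patterns[[1]]$samples$weight_g
  expect_gt(tail_w[length(tail_w)], cfg$start_threshold)

  # stream ending mid-pattern -> truncated
  w <- c(rep(0, 10), rep(150, 20))
  res <- segment_vector(w, cfg)
  expect_length(res$patterns, 1)
  expect_true(res$patterns[[1]]$truncated)
  expect_false(validate_pattern(res$patterns[[1]], cfg))
  expect_true(validate_pattern(res$patterns[[1]], cfg, include_truncated = TRUE))
})

test_that("wind spikes are dropped without opening real patterns", {
  cfg <- acquisition_config()
  w <- c(rep(0, 10), 400, rep(0, 10), rep(150, 30), rep(0, 6))
  res <- segment_vector(w, cfg)
  expect_length(res$patterns, 1)           # the spike pattern is empty
  expect_equal(nrow(res$patterns[[1]]$samples), 30)
  expect_equal(res$summary$outliers_dropped, 1L)

  # spike inside an open pattern: dropped, pattern unbroken
  w <- c(rep(0, 10), rep(150, 15), 400, rep(150, 15), rep(0, 6))
  res <- segment_vector(w, cfg)
  expect_length(res$patterns, 1)
  expect_equal(nrow(res$patterns[[1]]$samples), 30)
  expect_false(any(res$patterns[[1]]$samples$weight_g > cfg$valid_range[2]))
})

test_that("pattern duration and validity boundaries follow the sampling rate", {
  cfg <- acquisition_config()
  p30 <- make_pattern(rep(150, 30))
  p17 <- make_pattern(rep(150, 17))
  p16 <- make_pattern(rep(150, 16))
  expect_true(validate_pattern(p30, cfg))
  expect_true(validate_pattern(p17, cfg))
  expect_false(validate_pattern(p16, cfg))
  expect_equal(p30$duration_s, 30 / 16)
})

test_that("tare updating is suspended while a pattern is open, and no sample is double-used", {
  cfg <- acquisition_config()
  w <- c(rep(0, 12), rep(150, 20), rep(0, 7), rep(150, 18), rep(0, 9))
  res <- segment_vector(w, cfg)
  expect_length(res$patterns, 2)
  # samples: 12 before first + (7 - 5 consumed by the close) + ... ; every
  # empty-pan update happened strictly outside open pattern spans
  spans <- lapply(res$patterns, function(p) p$samples$tick)
  n_in_patterns <- sum(lengths(spans))
  consumed_by_close <- 2 * cfg$end_consecutive_below
  expect_equal(res$summary$tare_updates + n_in_patterns + consumed_by_close,
               length(w))
  expect_equal(res$summary$tare_updates, 12L + 2L + 4L)
})

test_that("segmentation matches the two-pass reference on random toy streams", {
  cfg <- acquisition_config()
  set.seed(505)
  for (i in 1:200) expect_segmentation_matches(random_toy_stream(), cfg)
})
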