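# The dual-path estimator: stable-reading mean, MLP forward pass with the
# published connection weights, dispatch, and the accuracy metric.

test_that("forward pass with the deployed weights matches a hand computation", {
  params <- kestrel_mlp()
  sigma <- function(x) 1 / (1 + exp(-x))
  expected <- 300 * sigma(-0.778603 +
                            2.357087 * sigma(-0.967833) +
                            3.643371 * sigma(-0.247893) +
                            (-4.810658) * sigma(3.395910))
  got <- mlp_forward(rep(0, 9), params)
  expect_lt(abs(got - expected) / expected, 1e-9)
  expect_lt(expected, 15)  # about 0.04 * R
})

test_that("output symmetry and determinism of the forward pass", {
  # zero weights into the output neuron and zero output bias -> R/2
  p <- mlp_parameters(hidden_weights = matrix(rnorm(27), 9, 3),
                      hidden_bias = rnorm(3),
                      output_weights = rep(0, 3), output_bias = 0,
                      resample_factor = 300)
  expect_equal(mlp_forward(runif(9, 0, 200), p), 150)

  params <- kestrel_mlp()
  f <- extract_features(c(150, 151, 150, 152, 149, 150))
  expect_identical(mlp_forward(f, params), mlp_forward(f, params))
  expect_error(mlp_forward(rep(0, 5), params), "input layer")
})

test_that("forward pass is bounded in (0, R) for any finite input", {
  params <- kestrel_mlp()
  set.seed(7)
  X <- matrix(runif(9 * 2000, -1e3, 1e3), ncol = 9)
  y <- mlp_forward(X, params)
  expect_true(all(y > 0 & y < params$resample_factor))
})

test_that("the reversed-sigmoid fidelity switch mirrors the standard one", {
  base <- kestrel_mlp()
  rev <- kestrel_mlp(sigmoid = "as_printed")
  # reversed sigmoid(x) equals standard sigmoid(-x); on the all-zero input
  # the hidden activations flip accordingly
  f0 <- rep(0, 9)
  expect_false(isTRUE(all.equal(mlp_forward(f0, base), mlp_forward(f0, rev))))
  expect_true(mlp_forward(f0, rev) > 0 &&
                mlp_forward(f0, rev) < rev$resample_factor)
})

test_that("stable mean averages only the stable readings", {
  p <- make_pattern(c(150, 151, 162), stable = c(TRUE, TRUE, FALSE))
  e <- stable_mean(p)
  expect_equal(e$grams, 150.5)
  expect_equal(e$method, "stable_mean")
  expect_true(e$stable_tag)

  p1 <- make_pattern(147.3, stable = TRUE)
  expect_equal(stable_mean(p1)$grams, 147.3)

  p100 <- make_pattern(rep(150, 100), stable = rep(TRUE, 100))
  expect_equal(stable_mean(p100)$grams, 150)

  expect_error(stable_mean(make_pattern(c(150, 151))), "no stable")
})

test_that("dispatch follows the stable/unstable tag contract", {
  params <- kestrel_mlp()
  p_mixed <- make_pattern(rep(c(150, 151), 10),
                          stable = rep(c(TRUE, FALSE), 10))
  e <- estimate_weight(p_mixed, params)
  expect_equal(e$method, "stable_mean")
  expect_true(e$stable_tag)

  p_unstable <- make_pattern(sample(148:152, 30, replace = TRUE))
  e <- estimate_weight(p_unstable, params)
  expect_equal(e$method, "mlp")
  expect_false(e$stable_tag)
  expect_gt(e$grams, 0)
  expect_lt(e$grams, params$resample_factor)
  expect_equal(e$tick_range, c(1L, 30L))
})

test_that("accuracy metric reproduces the recapture comparison rows", {
  manual <- c(155, 142, 120, 153, 143)
  estimated <- c(154.471, 144.078, 118.045, 154.716, 144.661)
  expect_equal(accuracy_percent(manual, estimated),
               c(99.66, 98.54, 98.37, 98.88, 98.84))
  expect_equal(accuracy_percent(137.2, 137.2), 100.00)
  expect_equal(accuracy_percent(100, 90), accuracy_percent(100, 110))
  expect_error(accuracy_percent(0, 100), "positive")
  expect_error(accuracy_percent(-5, 100), "positive")
})

test_that("network parameters round-trip through the model file bit-exactly", {
  params <- kestrel_mlp()
  path <- withr::local_tempfile(fileext = ".json")
  write_mlp(params, path)
  back <- read_mlp(path)
  expect_identical(back$hidden_weights, params$hidden_weights)
  expect_identical(back$hidden_bias, params$hidden_bias)
  expect_identical(back$output_weights, params$output_weights)
  expect_identical(back$output_bias, params$output_bias)
  expect_identical(back$resample_factor, params$resample_factor)
  expect_identical(back$sigmoid, params$sigmoid)
})

test_that("the shipped parameter file equals the in-code fixture", {
  path <- system.file("extdata", "kestrel_mlp.json", package = "nestscale")
  expect_true(nzchar(path))
  shipped <- read_mlp(path)
  expect_identical(shipped$hidden_weights, kestrel_mlp()$hidden_weights)
  expect_identical(shipped$output_bias, kestrel_mlp()$output_bias)
})
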