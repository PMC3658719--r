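# Dual-path weight estimation. A pattern with any stable readings is
# estimated as the arithmetic mean of those readings (the scale is unbiased
# when it reports stability); an all-unstable pattern goes through a small
# feed-forward network on the nine pattern summaries. The network output
# lives in (0, 1) and is rescaled to grams by a fixed resample factor.

#' Multilayer perceptron parameters
#'
#' A fully connected 9-H-1 network of sigmoid neurons, plus the input/output
#' scaling needed to map features to the unit interval and the output
#' activation back to grams.
#'
#' @param hidden_weights Numeric matrix, `n_in x H`: column `j` holds the
#'   connection weights into hidden neuron `j`.
#' @param hidden_bias Numeric vector of length `H`.
#' @param output_weights Numeric vector of length `H`: connection weights
#'   into the single output neuron.
#' @param output_bias Scalar bias of the output neuron.
#' @param resample_factor Constant `R` (grams) multiplying the output
#'   neuron's activation; defaults to 300, the upper bound of the valid
#'   weight range, so the output spans it.
#' @param n_max Normalizer for count-valued features (samples); default
#'   2048 = 128 s at 16 samples/s.
#' @param sigmoid `"standard"` for `1/(1+exp(-x))`, or `"as_printed"` for
#'   the reversed form `1/(1+exp(x))` kept for fidelity experiments.
#' @return An object of class `mlp_parameters`.
#' @export
mlp_parameters <- function(hidden_weights, hidden_bias, output_weights,
                           output_bias, resample_factor = 300,
                           n_max = 2048, sigmoid = c("standard", "as_printed")) {
  sigmoid <- match.arg(sigmoid)
  hidden_weights <- as.matrix(hidden_weights)
  H <- ncol(hidden_weights)
  stopifnot(length(hidden_bias) == H, length(output_weights) == H,
            length(output_bias) == 1, resample_factor > 0, n_max > 0)
  structure(list(layer_sizes = c(nrow(hidden_weights), H, 1L),
                 hidden_weights = hidden_weights,
                 hidden_bias = as.numeric(hidden_bias),
                 output_weights = as.numeric(output_weights),
                 output_bias = as.numeric(output_bias),
                 resample_factor = resample_factor,
                 n_max = n_max,
                 sigmoid = sigmoid),
            class = "mlp_parameters")
}

#' @export
print.mlp_parameters <- function(x, ...) {
  cat(sprintf("<mlp_parameters> %s network, R = %g g, n_max = %g, %s sigmoid\n",
              paste(x$layer_sizes, collapse = "-"), x$resample_factor,
              x$n_max, x$sigmoid))
  invisible(x)
}

#' The deployed 9-3-1 network for lesser kestrels
#'
#' The connection weights published for the field deployment (rounded to six
#' decimals). The original input scaling was not published, so these weights
#' serve as a fixture for verifying the forward pass; gram-accurate
#' estimates on new data require retraining under the scaling declared in
#' [mlp_parameters()] (see the methods vignette).
#'
#' @param ... Passed on to [mlp_parameters()] (e.g. `resample_factor`).
#' @return An `mlp_parameters` object.
#' @export
kestrel_mlp <- function(...) {
  hw <- cbind(
    c(1.202640, -0.059006, -0.419412, -0.442465, 0.964739,
      -0.226521, 0.288798, 0.210606, 0.759511),
    c(2.025155, 0.280633, 1.299244, 0.771556, 2.033089,
      0.920540, 2.659565, 0.844355, 1.367401),
    c(-2.773383, 0.211419, -0.838220, -0.075977, 0.465052,
      -0.065647, -0.522707, 0.106924, 0.129165))
  rownames(hw) <- feature_names
  mlp_parameters(hidden_weights = hw,
                 hidden_bias = c(-0.967833, -0.247893, 3.395910),
                 output_weights = c(2.357087, 3.643371, -4.810658),
                 output_bias = -0.778603,
                 ...)
}

#' Scale a feature vector for the network input
#'
#' Weight-valued features (`max_1`, `max_2`, `max_c1`, `max_c2`) are divided
#' by the resample factor; count-valued features by `n_max`.
#'
#' @param features Named numeric vector from [extract_features()], or a
#'   matrix with 9 columns (one row per pattern).
#' @param params An `mlp_parameters` object.
#' @return Scaled features, same shape as the input.
#' @export
scale_features <- function(features, params) {
  idx_w <- c(1, 3, 5, 7)
  if (is.matrix(features)) {
    stopifnot(ncol(features) == params$layer_sizes[1])
    out <- features / params$n_max
    out[, idx_w] <- features[, idx_w] / params$resample_factor
    out
  } else {
    stopifnot(length(features) == params$layer_sizes[1])
    out <- features / params$n_max
    out[idx_w] <- features[idx_w] / params$resample_factor
    out
  }
}

mlp_sigmoid <- function(x, orientation) {
  if (orientation == "standard") 1 / (1 + exp(-x)) else 1 / (1 + exp(x))
}

#' Feed-forward weight estimate
#'
#' Runs the scaled features through the sigmoid layers; the output neuron's
#' activation times the resample factor is the estimated weight, hence the
#' estimate is bounded in `(0, R)` for any finite input.
#'
#' @param features Named numeric vector of the 9 raw features, or a matrix
#'   with one row per pattern. Scaling per `params` is applied internally;
#'   pass `scaled = TRUE` if the input is already scaled.
#' @param params An `mlp_parameters` object.
#' @param scaled Set `TRUE` to skip input scaling.
#' @return Estimated weight(s) in grams.
#' @export
mlp_forward <- function(features, params, scaled = FALSE) {
  x <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  if (ncol(x) != params$layer_sizes[1])
    stop("feature vector length does not match the network input layer")
  if (!scaled) x <- scale_features(x, params)
  h <- mlp_sigmoid(sweep(x %*% params$hidden_weights, 2, params$hidden_bias, "+"),
                   params$sigmoid)
  y <- mlp_sigmoid(drop(h %*% params$output_weights) + params$output_bias,
                   params$sigmoid)
  unname(params$resample_factor * y)
}

#' Weight estimate record
#'
#' @param grams Estimated weight in grams.
#' @param method `"stable_mean"` or `"mlp"`.
#' @param nest_id,rfid,tick_range Provenance carried from the pattern.
#' @return An object of class `weight_estimate`; `stable_tag` is `TRUE`
#'   iff the estimate came from stable measurements.
#' @export
weight_estimate <- function(grams, method = c("stable_mean", "mlp"),
                            nest_id = "nest", rfid = NA_character_,
                            tick_range = c(NA_integer_, NA_integer_)) {
  method <- match.arg(method)
  structure(list(grams = grams, method = method,
                 stable_tag = method == "stable_mean",
                 nest_id = nest_id, rfid = rfid,
                 tick_range = tick_range),
            class = "weight_estimate")
}

#' @export
print.weight_estimate <- function(x, ...) {
  cat(sprintf("<weight_estimate> %.3f g (%s, %s) nest %s\n", x$grams,
              x$method, if (x$stable_tag) "stable" else "unstable", x$nest_id))
  invisible(x)
}

#' Arithmetic mean of a pattern's stable readings
#'
#' @param p A `weigh_pattern` containing at least one stable sample.
#' @return A [weight_estimate()] with `method = "stable_mean"`.
#' @export
stable_mean <- function(p) {
  w <- p$samples$weight_g[p$samples$stable]
  if (length(w) == 0)
    stop("pattern has no stable samples; use the MLP path")
  weight_estimate(mean(w), "stable_mean", nest_id = p$nest_id, rfid = p$rfid,
                  tick_range = c(p$start_tick, p$end_tick))
}

#' Estimate the body weight behind one pattern
#'
#' Dispatches on the presence of stable readings: their arithmetic mean if
#' any exist, otherwise the MLP applied to the nine pattern summaries. The
#' returned estimate carries the stable/unstable tag that is sent with it.
#'
#' @param p A validated `weigh_pattern`.
#' @param params An `mlp_parameters` object for the unstable path.
#' @param step Quantization step (g) for feature extraction.
#' @return A [weight_estimate()].
#' @export
estimate_weight <- function(p, params = kestrel_mlp(), step = 1) {
  if (any(p$samples$stable)) return(stable_mean(p))
  f <- extract_features(p, step = step, exclude_stable = FALSE)
  weight_estimate(mlp_forward(f, params), "mlp", nest_id = p$nest_id,
                  rfid = p$rfid, tick_range = c(p$start_tick, p$end_tick))
}

#' Percent accuracy of an estimate against a manual capture
#'
#' `100 * (1 - |manual - estimated| / manual)`, the metric used to compare
#' automatic estimates against the closest-in-time manual weighing of the
#' same individual.
#'
#' @param manual Manually measured weight(s) in grams (> 0).
#' @param estimated Automatic estimate(s) in grams.
#' @param digits Decimal places for reporting (default 2); `NULL` to skip
#'   rounding.
#' @return Percent accuracy, vectorized over pairs.
#' @export
accuracy_percent <- function(manual, estimated, digits = 2) {
  if (any(manual <= 0)) stop("manual weight must be positive")
  acc <- 100 * (1 - abs(manual - estimated) / manual)
  if (is.null(digits)) acc else round(acc, digits)
}
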