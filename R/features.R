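# Nine pattern summaries feeding the MLP: the two most frequent quantized
# weights with their counts, the two longest runs with their lengths, and
# the sample count. Cheap to compute (a frequency table and a run-length
# encoding), which is what lets the estimator run on a microcontroller.

#' Quantize weights to a fixed resolution
#'
#' Repetition counts are undefined for continuous values, so weights are
#' snapped to the nearest multiple of `step` before counting, ties rounding
#' away from zero.
#'
#' @param weights Numeric vector of calibrated weights (g).
#' @param step Quantization step in grams (default 1 g).
#' @return Numeric vector of quantized weights.
#' @export
quantize <- function(weights, step = 1) {
  stopifnot(step > 0)
  step * trunc(abs(weights) / step + 0.5) * sign(weights)
}

feature_names <- c("max_1", "n_1", "max_2", "n_2",
                   "max_c1", "nc_1", "max_c2", "nc_2", "n_el")

#' Extract the nine pattern summary variables
#'
#' Over the (optionally stable-removed) quantized weight sequence:
#' * `max_1`, `n_1` — the most repeated weight and its count;
#' * `max_2`, `n_2` — the second most repeated weight and its count;
#' * `max_c1`, `nc_1` — the weight of the longest consecutive run and its
#'   length;
#' * `max_c2`, `nc_2` — the second longest run's weight and length;
#' * `n_el` — number of measurements used.
#'
#' All ties resolve to the larger weight. When fewer than two distinct
#' values (or runs) exist, the second-place pair is reported as 0/0.
#'
#' @param p A `weigh_pattern`, or a plain numeric vector of weights (in
#'   which case `exclude_stable` must be `FALSE`).
#' @param step Quantization step in grams, see [quantize()].
#' @param exclude_stable Drop stable-flagged samples first (used when
#'   building training examples; at inference the MLP only ever sees
#'   all-unstable patterns).
#' @return Named numeric vector of length 9, in the order
#'   `max_1, n_1, max_2, n_2, max_c1, nc_1, max_c2, nc_2, n_el`.
#' @export
extract_features <- function(p, step = 1, exclude_stable = FALSE) {
  if (inherits(p, "weigh_pattern")) {
    w <- p$samples$weight_g
    if (exclude_stable) w <- w[!p$samples$stable]
  } else {
    stopifnot(is.numeric(p), !exclude_stable)
    w <- p
  }
  if (length(w) == 0)
    stop("no measurements left to summarize (empty or all-stable pattern)")
  q <- quantize(w, step)

  tab <- table(q)
  vals <- as.numeric(names(tab))
  cnt <- as.integer(tab)
  ord <- order(-cnt, -vals)
  max_1 <- vals[ord[1]]; n_1 <- cnt[ord[1]]
  if (length(ord) >= 2) {
    max_2 <- vals[ord[2]]; n_2 <- cnt[ord[2]]
  } else {
    max_2 <- 0; n_2 <- 0L
  }

  r <- rle(q)
  rord <- order(-r$lengths, -r$values)
  max_c1 <- r$values[rord[1]]; nc_1 <- r$lengths[rord[1]]
  if (length(rord) >= 2) {
    max_c2 <- r$values[rord[2]]; nc_2 <- r$lengths[rord[2]]
  } else {
    max_c2 <- 0; nc_2 <- 0L
  }

  stats::setNames(c(max_1, n_1, max_2, n_2, max_c1, nc_1, max_c2, nc_2,
                    length(q)), feature_names)
}
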