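# Acquisition: turn a raw scale stream into calibrated, validated weighing
# patterns. The scale emits 16 readings per second, each tagged stable or
# unstable; while the pan is empty the tare is tracked continuously with a
# robust (IRLS/Huber) location estimate, and an above-threshold excursion
# opens a pattern that closes after a run of below-threshold readings.

#' Acquisition configuration
#'
#' Parameters controlling calibration, range filtering and pattern
#' segmentation of a raw scale stream.
#'
#' @param start_threshold Calibrated weight (g) that opens a pattern; a
#'   sample strictly above it while no pattern is open starts acquisition.
#' @param end_consecutive_below Number of consecutive samples at or below
#'   `start_threshold` that closes an open pattern. The default 5 encodes
#'   "more than four" below-threshold readings.
#' @param min_pattern_samples Minimum number of retained samples for a
#'   pattern to be valid. The default 17 requires strictly more than one
#'   second of data at 16 samples/s.
#' @param valid_range Two-element numeric, inclusive calibrated-weight range
#'   (g) of plausible on-pan readings; readings above the upper bound are
#'   treated as wind-induced outliers and dropped.
#' @param sps Samples per second emitted by the scale.
#' @param tare_window Number of recent empty-pan readings kept for the
#'   running tare estimate (64 samples = 4 s at the default rate).
#' @param irls_max_iter,irls_tol Iteration cap and convergence tolerance (g)
#'   of the IRLS tare update.
#' @param huber_k Huber tuning constant, in units of the robust scale
#'   (1.4826 * MAD) of the buffer.
#' @return An object of class `acquisition_config` (a list).
#' @export
acquisition_config <- function(start_threshold = 50,
                               end_consecutive_below = 5,
                               min_pattern_samples = 17,
                               valid_range = c(50, 300),
                               sps = 16,
                               tare_window = 64,
                               irls_max_iter = 10,
                               irls_tol = 1e-6,
                               huber_k = 1.345) {
  stopifnot(length(valid_range) == 2, valid_range[1] < valid_range[2],
            start_threshold > 0, end_consecutive_below >= 1,
            min_pattern_samples >= 1, sps > 0, tare_window >= 1)
  structure(list(start_threshold = start_threshold,
                 end_consecutive_below = end_consecutive_below,
                 min_pattern_samples = min_pattern_samples,
                 valid_range = valid_range,
                 sps = sps,
                 tare_window = tare_window,
                 irls_max_iter = irls_max_iter,
                 irls_tol = irls_tol,
                 huber_k = huber_k),
            class = "acquisition_config")
}

#' Gain calibration
#'
#' Linear map from raw scale readings to reference mass, fitted once per
#' season with certified weights.
#'
#' @param gain Dimensionless multiplier (> 0).
#' @param offset Additive offset in grams.
#' @param residual_rms Root-mean-square calibration residual in grams.
#' @return An object of class `gain_calibration`.
#' @export
gain_calibration <- function(gain = 1, offset = 0, residual_rms = 0) {
  stopifnot(is.finite(gain), gain > 0, is.finite(offset))
  structure(list(gain = gain, offset = offset, residual_rms = residual_rms),
            class = "gain_calibration")
}

#' Fit the scale gain against certified reference masses
#'
#' Ordinary least squares of reference mass on mean raw reading. Performed
#' offline (typically once a year); the result feeds [apply_calibration()].
#'
#' @param reference_mass Certified masses in grams.
#' @param mean_raw_reading Mean raw scale reading for each mass.
#' @return A [gain_calibration()] object with `residual_rms` filled in.
#' @export
fit_gain <- function(reference_mass, mean_raw_reading) {
  stopifnot(length(reference_mass) == length(mean_raw_reading))
  if (length(unique(mean_raw_reading)) < 2)
    stop("gain calibration needs at least 2 distinct reference readings")
  fit <- stats::lm(reference_mass ~ mean_raw_reading)
  co <- stats::coef(fit)
  gain_calibration(gain = unname(co[2]), offset = unname(co[1]),
                   residual_rms = sqrt(mean(stats::residuals(fit)^2)))
}

#' Apply gain and tare calibration to a raw reading
#'
#' @param raw_weight Raw scale output in grams (tare-inclusive).
#' @param tare Current tare estimate in grams, on the gain-corrected scale.
#' @param gain_cal A [gain_calibration()] object.
#' @return Calibrated weight in grams: `gain * raw + offset - tare`.
#' @export
apply_calibration <- function(raw_weight, tare, gain_cal = gain_calibration()) {
  gain_cal$gain * raw_weight + gain_cal$offset - tare
}

#' Range filter for calibrated readings
#'
#' @param weight Calibrated weight(s) in grams.
#' @param cfg An [acquisition_config()].
#' @return Logical: `TRUE` iff the weight lies inside `valid_range`
#'   (boundaries inclusive).
#' @export
is_in_range <- function(weight, cfg = acquisition_config()) {
  weight >= cfg$valid_range[1] & weight <= cfg$valid_range[2]
}

#' Tare tracking state
#'
#' Holds the bounded buffer of recent empty-pan readings (gain-corrected)
#' and the current robust tare estimate.
#'
#' @param tare Initial tare in grams (0 before any reading is seen).
#' @return An object of class `tare_state`.
#' @export
tare_state <- function(tare = 0) {
  structure(list(tare = tare, buffer = numeric(0), n_updates = 0L),
            class = "tare_state")
}

# Huber M-estimate of location at fixed robust scale (scaled MAD), solved by
# iteratively reweighted least squares with a warm start. Constant buffers
# (MAD = 0) fall back to the median.
huber_irls <- function(x, k = 1.345, max_iter = 10, tol = 1e-6,
                       mu0 = stats::median(x)) {
  s <- stats::mad(x)
  if (!is.finite(s) || s <= 0) return(stats::median(x))
  mu <- mu0
  for (i in seq_len(max_iter)) {
    r <- abs(x - mu) / s
    w <- pmin(1, k / pmax(r, .Machine$double.eps))
    mu_new <- sum(w * x) / sum(w)
    if (abs(mu_new - mu) < tol) return(mu_new)
    mu <- mu_new
  }
  mu
}

#' Update the tare from one empty-pan reading
#'
#' Appends the gain-corrected reading to the bounded buffer (evicting the
#' oldest beyond `tare_window`) and recomputes the tare as a Huber IRLS
#' location estimate over the buffer, warm-started from the previous tare.
#' Robust by construction: an occasional wind spike in the buffer barely
#' moves the estimate.
#'
#' @param state A [tare_state()].
#' @param raw_weight Raw reading in grams, taken with the pan empty
#'   (its calibrated value is below `start_threshold`; the caller —
#'   normally [segment_stream()] — guarantees this).
#' @param cfg An [acquisition_config()].
#' @param gain_cal A [gain_calibration()].
#' @return The updated `tare_state` (replaces the input).
#' @export
update_tare <- function(state, raw_weight, cfg = acquisition_config(),
                        gain_cal = gain_calibration()) {
  g <- gain_cal$gain * raw_weight + gain_cal$offset
  buf <- c(state$buffer, g)
  if (length(buf) > cfg$tare_window)
    buf <- buf[(length(buf) - cfg$tare_window + 1L):length(buf)]
  mu0 <- if (state$n_updates > 0L) state$tare else stats::median(buf)
  state$buffer <- buf
  state$tare <- huber_irls(buf, k = cfg$huber_k, max_iter = cfg$irls_max_iter,
                           tol = cfg$irls_tol, mu0 = mu0)
  state$n_updates <- state$n_updates + 1L
  state
}

#' Construct a weighing pattern
#'
#' A pattern is the ordered set of calibrated samples recorded between an
#' animal's arrival on and departure from the scale pan.
#'
#' @param samples Data frame with columns `tick`, `weight_g` (calibrated)
#'   and `stable` (logical).
#' @param nest_id,rfid Identifiers carried through from the stream
#'   (`rfid` may be `NA`).
#' @param sps Samples per second (sets `duration_s`).
#' @param truncated `TRUE` if the stream ended while the pattern was open.
#' @return An object of class `weigh_pattern`.
#' @export
weigh_pattern <- function(samples, nest_id = "nest", rfid = NA_character_,
                          sps = 16, truncated = FALSE) {
  stopifnot(is.data.frame(samples),
            all(c("tick", "weight_g", "stable") %in% names(samples)))
  n <- nrow(samples)
  structure(list(samples = samples,
                 nest_id = nest_id,
                 rfid = rfid,
                 start_tick = if (n) samples$tick[1] else NA_integer_,
                 end_tick = if (n) samples$tick[n] else NA_integer_,
                 duration_s = if (n) (samples$tick[n] - samples$tick[1] + 1) / sps else 0,
                 truncated = truncated),
            class = "weigh_pattern")
}

#' @export
print.weigh_pattern <- function(x, ...) {
  cat(sprintf("<weigh_pattern> nest %s rfid %s: %d samples (%.2f s), %d stable%s\n",
              x$nest_id, ifelse(is.na(x$rfid), "-", x$rfid),
              nrow(x$samples), x$duration_s, sum(x$samples$stable),
              if (isTRUE(x$truncated)) ", truncated" else ""))
  invisible(x)
}

#' Minimum-duration filter for patterns
#'
#' @param p A `weigh_pattern`.
#' @param cfg An [acquisition_config()].
#' @param include_truncated Accept patterns cut short by end of stream?
#' @return `TRUE` iff the pattern keeps at least `min_pattern_samples`
#'   samples (default: strictly more than 16, i.e. longer than one second)
#'   and, unless `include_truncated`, was closed by the threshold rule.
#' @export
validate_pattern <- function(p, cfg = acquisition_config(),
                             include_truncated = FALSE) {
  nrow(p$samples) >= cfg$min_pattern_samples &&
    (include_truncated || !isTRUE(p$truncated))
}

#' Segment a raw stream into weighing patterns
#'
#' Runs the acquisition state machine over a tick-sorted stream. While no
#' pattern is open, every sample updates the tare; the first calibrated
#' sample strictly above `start_threshold` opens a pattern and suspends tare
#' updating. While open, in-range samples are appended, above-range samples
#' (wind) are dropped, and a run of `end_consecutive_below` consecutive
#' at-or-below-threshold samples closes the pattern, stripping all trailing
#' below-threshold samples so a pattern never ends below threshold. Short
#' below-threshold dips (run shorter than the limit) stay in the pattern.
#' Tare updating resumes after the close.
#'
#' @param stream Data frame with columns `tick`, `raw_weight_g`, `stable`,
#'   and optionally `nest_id`, `rfid`, sorted by `tick`.
#' @param state A [tare_state()] carried across calls.
#' @param cfg An [acquisition_config()].
#' @param gain_cal A [gain_calibration()].
#' @param verbose Emit a per-stream summary message?
#' @return A list with `patterns` (list of `weigh_pattern`; a pattern open at
#'   end of stream is emitted with `truncated = TRUE`), `state` (final
#'   `tare_state`), and `summary` (samples read, outliers dropped, patterns
#'   emitted, tare updates, tare trajectory).
#' @export
segment_stream <- function(stream, state = tare_state(),
                           cfg = acquisition_config(),
                           gain_cal = gain_calibration(),
                           verbose = FALSE) {
  stopifnot(all(c("tick", "raw_weight_g", "stable") %in% names(stream)))
  n <- nrow(stream)
  n_updates0 <- state$n_updates
  if (n > 1 && any(diff(stream$tick) <= 0))
    stop("stream ticks must be strictly increasing")
  nest_id <- if ("nest_id" %in% names(stream) && n) stream$nest_id[1] else "nest"
  rfid_col <- if ("rfid" %in% names(stream)) stream$rfid else rep(NA_character_, n)

  patterns <- list()
  open <- FALSE
  below_run <- 0L
  buf_tick <- integer(n); buf_w <- numeric(n); buf_st <- logical(n)
  buf_n <- 0L
  pat_rfid <- NA_character_
  dropped <- 0L
  tare_traj <- numeric(0)

  close_pattern <- function(truncated) {
    k <- buf_n
    while (k > 0L && buf_w[k] <= cfg$start_threshold) k <- k - 1L
    if (k > 0L) {
      samples <- data.frame(tick = buf_tick[seq_len(k)],
                            weight_g = buf_w[seq_len(k)],
                            stable = buf_st[seq_len(k)])
      patterns[[length(patterns) + 1L]] <<- weigh_pattern(
        samples, nest_id = nest_id, rfid = pat_rfid, sps = cfg$sps,
        truncated = truncated)
    }
    open <<- FALSE
    below_run <<- 0L
    buf_n <<- 0L
    pat_rfid <<- NA_character_
  }

  for (i in seq_len(n)) {
    w <- gain_cal$gain * stream$raw_weight_g[i] + gain_cal$offset - state$tare
    if (!open) {
      if (w > cfg$start_threshold) {
        open <- TRUE
        below_run <- 0L
        buf_n <- 0L
        if (!is.na(rfid_col[i])) pat_rfid <- rfid_col[i]
        if (w <= cfg$valid_range[2]) {
          buf_n <- 1L
          buf_tick[1] <- stream$tick[i]; buf_w[1] <- w; buf_st[1] <- stream$stable[i]
        } else dropped <- dropped + 1L
      } else {
        state <- update_tare(state, stream$raw_weight_g[i], cfg, gain_cal)
        tare_traj <- c(tare_traj, state$tare)
      }
    } else {
      if (is.na(pat_rfid) && !is.na(rfid_col[i])) pat_rfid <- rfid_col[i]
      if (w <= cfg$start_threshold) {
        below_run <- below_run + 1L
        if (below_run >= cfg$end_consecutive_below) {
          close_pattern(truncated = FALSE)
        } else {
          buf_n <- buf_n + 1L
          buf_tick[buf_n] <- stream$tick[i]; buf_w[buf_n] <- w
          buf_st[buf_n] <- stream$stable[i]
        }
      } else if (w <= cfg$valid_range[2]) {
        below_run <- 0L
        buf_n <- buf_n + 1L
        buf_tick[buf_n] <- stream$tick[i]; buf_w[buf_n] <- w
        buf_st[buf_n] <- stream$stable[i]
      } else {
        # above-range wind outlier inside an open pattern: dropped, and the
        # below-threshold run counter is left untouched
        dropped <- dropped + 1L
      }
    }
  }
  if (open) close_pattern(truncated = TRUE)

  summary <- list(samples_read = n, outliers_dropped = dropped,
                  patterns_emitted = length(patterns),
                  tare_updates = state$n_updates - n_updates0,
                  tare_trajectory = tare_traj)
  if (verbose)
    message(sprintf("segment_stream: %d samples, %d outliers dropped, %d patterns, tare %.3f g after %d updates",
                    n, dropped, length(patterns), state$tare, state$n_updates))
  list(patterns = patterns, state = state, summary = summary)
}
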