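# Synthetic visit simulator. Emulates what the deployed scale sees: slow
# tare drift with empty-pan noise and sporadic wind spikes, and visits of
# 100-190 g birds whose movement produces an autocorrelated oscillation
# around the true weight, occasionally interrupted by a still plateau that
# the scale's stability rule tags as stable. Every stage of the pipeline is
# testable against the known ground truth returned alongside the stream.

#' Simulator configuration
#'
#' Defaults reproduce the deployment's conditions: 16 samples/s, birds of
#' 100-190 g, mean pattern duration 23.18 s, about 15% of patterns
#' containing stable readings.
#'
#' @param sps Samples per second.
#' @param true_weight_range Uniform range (g) for a visit's true weight.
#' @param duration_mean_s Mean pattern duration in seconds; durations are
#'   drawn lognormal with this mean and log-sd `duration_sdlog`.
#' @param duration_sdlog Dispersion (sd on the log scale) of durations.
#' @param stable_pattern_fraction Probability that a visit contains a still
#'   plateau (and hence stable-tagged readings).
#' @param osc_amplitude Peak excursion (g) of the movement oscillation; the
#'   AR(1) process is given stationary sd `osc_amplitude / 2`.
#' @param ar_coef AR(1) coefficient of the oscillation.
#' @param noise_sd Measurement noise sd (g) added to every sample.
#' @param plateau_len_range Run-length range (samples) of a still plateau.
#' @param tagger_k,tagger_delta The stability rule emulating the scale's
#'   internal tagging: a sample is stable iff the max-min spread of the
#'   trailing `tagger_k` samples is at most `tagger_delta` grams.
#' @param tare_level Empty-pan reading (g) at stream start.
#' @param tare_drift_per_hour Linear tare drift (g/h); the default is about
#'   1 g per day of dirt accumulation.
#' @param empty_noise_sd Empty-pan noise sd (g).
#' @param wind_rate_per_hour Poisson rate of out-of-range wind spikes on the
#'   empty pan.
#' @param wind_magnitude Range (g) of spike readings (above the valid range).
#' @param gap_mean_s Mean of the exponential inter-visit gap.
#' @param nest_id Nest identifier stamped on the stream.
#' @return An object of class `simulator_config`.
#' @export
simulator_config <- function(sps = 16,
                             true_weight_range = c(100, 190),
                             duration_mean_s = 23.18,
                             duration_sdlog = 0.35,
                             stable_pattern_fraction = 0.15,
                             osc_amplitude = 12,
                             ar_coef = 0.9,
                             noise_sd = 0.1,
                             plateau_len_range = c(16, 64),
                             tagger_k = 8,
                             tagger_delta = 1,
                             tare_level = 10,
                             tare_drift_per_hour = 1 / 24,
                             empty_noise_sd = 0.05,
                             wind_rate_per_hour = 2,
                             wind_magnitude = c(350, 500),
                             gap_mean_s = 30,
                             nest_id = "nest01") {
  stopifnot(sps > 0, diff(true_weight_range) > 0, duration_mean_s > 0,
            stable_pattern_fraction >= 0, stable_pattern_fraction <= 1,
            osc_amplitude >= 0, abs(ar_coef) < 1, noise_sd >= 0,
            wind_rate_per_hour >= 0)
  structure(as.list(environment()), class = "simulator_config")
}

# Trailing-window stability rule: stable iff max-min of the last k samples
# (including the current one) <= delta. The first k-1 samples are unstable.
tag_stability <- function(x, k, delta) {
  n <- length(x)
  if (n < k) return(rep(FALSE, n))
  hi <- x; lo <- x
  for (s in seq_len(k - 1)) {
    lag <- c(rep(NA_real_, s), x[seq_len(n - s)])
    hi <- pmax(hi, lag, na.rm = FALSE)
    lo <- pmin(lo, lag, na.rm = FALSE)
  }
  out <- (hi - lo) <= delta
  out[seq_len(k - 1)] <- FALSE
  out & !is.na(out)
}

#' Simulate one visit's raw samples
#'
#' Samples are `tare + true_weight + AR(1) oscillation + noise`; with
#' probability `stable_pattern_fraction` the oscillation is suppressed over
#' one plateau, whose samples the stability rule then tags as stable.
#'
#' @param cfg A [simulator_config()].
#' @param true_weight True body weight in grams.
#' @param tare Empty-pan level (g) during the visit.
#' @param rfid Tag code recorded with the visit.
#' @param start_tick Tick of the first sample.
#' @return A list with `samples` (data frame `tick`, `raw_weight_g`,
#'   `stable`, `nest_id`, `rfid`) and `event` (one-row data frame with the
#'   ground truth: `rfid`, `true_weight_g`, `arrival_tick`,
#'   `departure_tick`, `had_stable_run`).
#' @export
simulate_pattern <- function(cfg = simulator_config(), true_weight,
                             tare = cfg$tare_level, rfid = "tag0001",
                             start_tick = 1L) {
  n <- max(2L, as.integer(round(stats::rlnorm(
    1, meanlog = log(cfg$duration_mean_s) - cfg$duration_sdlog^2 / 2,
    sdlog = cfg$duration_sdlog) * cfg$sps)))
  sd_stat <- cfg$osc_amplitude / 2
  if (sd_stat > 0) {
    innov <- stats::rnorm(n, 0, sd_stat * sqrt(1 - cfg$ar_coef^2))
    osc <- as.numeric(stats::filter(innov, cfg$ar_coef, method = "recursive",
                                    init = stats::rnorm(1, 0, sd_stat)))
  } else osc <- numeric(n)
  if (stats::runif(1) < cfg$stable_pattern_fraction) {
    len <- min(n, sample(cfg$plateau_len_range[1]:cfg$plateau_len_range[2], 1))
    at <- sample.int(n - len + 1L, 1)
    osc[at:(at + len - 1L)] <- 0
  }
  raw <- tare + true_weight + osc + stats::rnorm(n, 0, cfg$noise_sd)
  stable <- tag_stability(raw, cfg$tagger_k, cfg$tagger_delta)
  ticks <- start_tick + seq_len(n) - 1L
  list(samples = data.frame(tick = ticks, raw_weight_g = raw,
                            stable = stable, nest_id = cfg$nest_id,
                            rfid = rfid),
       event = data.frame(rfid = rfid, true_weight_g = true_weight,
                          arrival_tick = ticks[1], departure_tick = ticks[n],
                          had_stable_run = any(stable)))
}

empty_segment <- function(cfg, n, start_tick) {
  ticks <- start_tick + seq_len(n) - 1L
  tare <- cfg$tare_level +
    cfg$tare_drift_per_hour * ticks / (3600 * cfg$sps)
  raw <- tare + stats::rnorm(n, 0, cfg$empty_noise_sd)
  n_spikes <- stats::rpois(1, cfg$wind_rate_per_hour * n / (3600 * cfg$sps))
  if (n_spikes > 0) {
    at <- sample.int(n, min(n_spikes, n))
    raw[at] <- stats::runif(length(at), cfg$wind_magnitude[1],
                            cfg$wind_magnitude[2])
  }
  data.frame(tick = ticks, raw_weight_g = raw,
             stable = tag_stability(raw, cfg$tagger_k, cfg$tagger_delta),
             nest_id = cfg$nest_id, rfid = NA_character_)
}

#' Simulate a raw stream of alternating empty-pan segments and visits
#'
#' @param cfg A [simulator_config()].
#' @param n_visits Number of visits in the stream.
#' @param rfid_pool Tag codes to draw visitors from.
#' @return A list with `samples` (the full tick-sorted stream) and `events`
#'   (one ground-truth row per visit).
#' @export
simulate_stream <- function(cfg = simulator_config(), n_visits,
                            rfid_pool = sprintf("tag%04d", 1:8)) {
  blocks <- list()
  events <- list()
  tick <- 1L
  for (v in seq_len(n_visits + 1L)) {
    gap_n <- max(cfg$tagger_k,
                 as.integer(round(stats::rexp(1, 1 / cfg$gap_mean_s) * cfg$sps)))
    seg <- empty_segment(cfg, gap_n, tick)
    blocks[[length(blocks) + 1L]] <- seg
    tick <- tick + gap_n
    if (v <= n_visits) {
      w <- stats::runif(1, cfg$true_weight_range[1], cfg$true_weight_range[2])
      tare_now <- cfg$tare_level +
        cfg$tare_drift_per_hour * tick / (3600 * cfg$sps)
      vis <- simulate_pattern(cfg, true_weight = w, tare = tare_now,
                              rfid = sample(rfid_pool, 1), start_tick = tick)
      blocks[[length(blocks) + 1L]] <- vis$samples
      events[[length(events) + 1L]] <- vis$event
      tick <- tick + nrow(vis$samples)
    }
  }
  list(samples = do.call(rbind, blocks),
       events = if (length(events)) do.call(rbind, events) else
         data.frame(rfid = character(0), true_weight_g = numeric(0),
                    arrival_tick = integer(0), departure_tick = integer(0),
                    had_stable_run = logical(0)))
}

#' Simulate a breeding-season's visits with per-bird weight trajectories
#'
#' Each bird follows a sex-specific linear trend (optionally with a
#' mid-season breakpoint) in its daily true weight; a Poisson number of
#' visits is scheduled each day. Intended for demonstrating seasonal trend
#' recovery from pipeline estimates.
#'
#' @param cfg A [simulator_config()].
#' @param n_birds Number of birds (sexes alternate).
#' @param days Season length in days.
#' @param visits_per_day Mean visits per bird per day (Poisson).
#' @param slope_g_per_day Weight trend in g/day (applies to both sexes).
#' @param sex_offset_g Added to male base weights.
#' @param breakpoint_day Optional day at which the slope changes.
#' @param slope_after Slope after the breakpoint (g/day).
#' @param intraday_sd Within-day jitter (g) of the weight at each visit.
#' @return A list with `samples` (concatenated per-visit sample blocks, one
#'   short empty-pan gap between visits), `events` (ground truth with added
#'   `day` and `sex` columns), and `birds` (per-bird base weights).
#' @export
simulate_season <- function(cfg = simulator_config(), n_birds, days,
                            visits_per_day = 2, slope_g_per_day = -0.2,
                            sex_offset_g = 15, breakpoint_day = NULL,
                            slope_after = NULL, intraday_sd = 1) {
  stopifnot(n_birds >= 1, days >= 1)
  sex <- rep(c("F", "M"), length.out = n_birds)
  base <- stats::runif(n_birds, 130, 150) + ifelse(sex == "M", sex_offset_g, 0)
  rfid <- sprintf("bird%03d", seq_len(n_birds))
  blocks <- list(); events <- list()
  tick <- 1L
  for (d in seq_len(days)) {
    day_w <- base + if (!is.null(breakpoint_day) && d > breakpoint_day)
      slope_g_per_day * breakpoint_day + slope_after * (d - breakpoint_day)
    else slope_g_per_day * d
    for (b in seq_len(n_birds)) {
      nv <- stats::rpois(1, visits_per_day)
      for (v in seq_len(nv)) {
        gap_n <- max(cfg$tagger_k,
                     as.integer(round(stats::rexp(1, 1 / cfg$gap_mean_s) * cfg$sps)))
        seg <- empty_segment(cfg, gap_n, tick)
        blocks[[length(blocks) + 1L]] <- seg
        tick <- tick + gap_n
        w <- day_w[b] + stats::rnorm(1, 0, intraday_sd)
        tare_now <- cfg$tare_level +
          cfg$tare_drift_per_hour * tick / (3600 * cfg$sps)
        vis <- simulate_pattern(cfg, true_weight = w, tare = tare_now,
                                rfid = rfid[b], start_tick = tick)
        ev <- vis$event
        ev$day <- d
        ev$sex <- sex[b]
        blocks[[length(blocks) + 1L]] <- vis$samples
        events[[length(events) + 1L]] <- ev
        tick <- tick + nrow(vis$samples)
      }
    }
  }
  blocks[[length(blocks) + 1L]] <- empty_segment(cfg, 2L * cfg$tagger_k, tick)
  list(samples = do.call(rbind, blocks),
       events = do.call(rbind, events),
       birds = data.frame(rfid = rfid, sex = sex, base_weight_g = base))
}
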