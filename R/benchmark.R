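# Desk-scale reproduction of the deployment's training protocol on fully
# synthetic visits: simulate patterns with known ground truth, build the
# supervised set from the ~15% of patterns that contain stable readings,
# split 50/50, train the 9-H-1 network, and score both the held-out
# examples and the dual-path estimates of every visit.

#' Simulate visits and run the full training protocol
#'
#' Simulates `n_visits` patterns under `cfg` (true weights uniform over the
#' configured range), calibrates them with the known tare, trains the
#' network on the mixed-pattern examples (target = stable mean, features
#' from the stable-removed sequence) after a random 50/50 split, and
#' evaluates: mean percent accuracy on the held-out examples, and the mean
#' absolute error of the dual-path estimator over all visits against the
#' true weights.
#'
#' @param n_visits Number of simulated visits.
#' @param seed Seed for simulation, split and weight initialization.
#' @param cfg A [simulator_config()].
#' @param train_cfg A [train_config()]; its seed is overridden by `seed`.
#' @param hidden_size Hidden neurons of the trained network.
#' @return A list: `model` (fitted `mlp_parameters`), `held_out_accuracy`
#'   (mean percent accuracy on the test half), `mae_g` (pipeline mean
#'   absolute error over all visits), `n_examples`, `n_visits`,
#'   `stable_fraction` (fraction of visits with any stable reading).
#' @export
synthetic_training_run <- function(n_visits = 7856, seed = 1234,
                                   cfg = simulator_config(),
                                   train_cfg = train_config(),
                                   hidden_size = 3) {
  train_cfg$seed <- seed
  with_seed(seed, {
    pats <- vector("list", n_visits)
    truth <- numeric(n_visits)
    for (i in seq_len(n_visits)) {
      w <- stats::runif(1, cfg$true_weight_range[1], cfg$true_weight_range[2])
      truth[i] <- w
      v <- simulate_pattern(cfg, true_weight = w, tare = cfg$tare_level)
      pats[[i]] <- weigh_pattern(
        data.frame(tick = v$samples$tick,
                   weight_g = v$samples$raw_weight_g - cfg$tare_level,
                   stable = v$samples$stable),
        nest_id = cfg$nest_id, rfid = v$event$rfid, sps = cfg$sps)
    }
    examples <- build_training_set(pats, step = train_cfg$step)
    parts <- split_dataset(examples, train_cfg$split_fraction, seed)
    model <- train_mlp(parts$train, train_cfg, hidden_size)
    est <- vapply(pats, function(p)
      estimate_weight(p, model, step = train_cfg$step)$grams, numeric(1))
    list(model = model,
         held_out_accuracy = evaluate_model(model, parts$test),
         mae_g = mean(abs(est - truth)),
         n_examples = length(examples$target),
         n_visits = n_visits,
         stable_fraction = mean(vapply(pats, function(p)
           any(p$samples$stable), logical(1))))
  })
}

#' Simulate a season and recover the weight trend from pipeline estimates
#'
#' Runs [simulate_season()], segments the raw stream, estimates every valid
#' pattern with the dual-path estimator, matches estimates back to the
#' ground-truth visits and fits a per-bird fixed-effect linear trend to the
#' estimated weights.
#'
#' @param seed Seed for the whole run.
#' @param model `mlp_parameters` for the unstable path.
#' @param cfg A [simulator_config()]; the default shortens the inter-visit
#'   gap to keep the stream compact.
#' @param n_birds,days,visits_per_day,slope_g_per_day Passed to
#'   [simulate_season()].
#' @return A list: `slope_g_per_day` (recovered), `true_slope`, `mae_g`,
#'   `n_estimates`, `sex_difference_g` (male minus female mean estimate,
#'   adjusted for nothing).
#' @export
season_trend_run <- function(seed = 1, model,
                             cfg = simulator_config(gap_mean_s = 5),
                             n_birds = 8, days = 60, visits_per_day = 2,
                             slope_g_per_day = -0.2) {
  with_seed(seed, {
    season <- simulate_season(cfg, n_birds = n_birds, days = days,
                              visits_per_day = visits_per_day,
                              slope_g_per_day = slope_g_per_day)
    seg <- segment_stream(season$samples, cfg = acquisition_config())
    valid <- Filter(validate_pattern, seg$patterns)
    ests <- estimates_to_df(lapply(valid, estimate_weight, params = model))
    hit <- vapply(seq_len(nrow(ests)), function(i) {
      j <- which(season$events$arrival_tick <= ests$start_tick[i] &
                   season$events$departure_tick >= ests$end_tick[i])
      if (length(j)) j[1] else NA_integer_
    }, integer(1))
    ok <- !is.na(hit)
    d <- cbind(ests[ok, ], day = season$events$day[hit[ok]],
               sex = season$events$sex[hit[ok]],
               truth = season$events$true_weight_g[hit[ok]])
    fit <- stats::lm(weight_g ~ day + rfid, data = d)
    list(slope_g_per_day = unname(stats::coef(fit)["day"]),
         true_slope = slope_g_per_day,
         mae_g = mean(abs(d$weight_g - d$truth)),
         n_estimates = nrow(d),
         sex_difference_g = mean(d$weight_g[d$sex == "M"]) -
           mean(d$weight_g[d$sex == "F"]))
  })
}
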