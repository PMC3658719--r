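# Offline training protocol. Patterns that contain both stable and unstable
# readings supply supervised examples: the target is the arithmetic mean of
# the stable readings, and the nine features are computed from the pattern
# after removing every stable reading. Networks with 1-9 hidden neurons are
# fitted by full-batch back-propagation on the scaled squared error and the
# smallest network within tolerance of the best held-out accuracy is kept.

#' Training configuration
#'
#' @param hidden_sizes Hidden-layer sizes to sweep (default 1..9).
#' @param split_fraction Fraction of examples assigned to training.
#' @param seed Seed controlling the split and the weight initialization.
#' @param learning_rate Gradient-descent step size.
#' @param epochs Maximum number of full-batch epochs.
#' @param patience Early-stopping patience: training stops when the
#'   monitored MSE has not improved by `min_delta` for this many epochs.
#' @param min_delta Minimum MSE improvement (scaled units) that resets the
#'   patience counter.
#' @param n_restarts Independent random initializations per fit; the
#'   restart with the lowest final training MSE is kept (guards against
#'   poor local minima of the non-convex loss).
#' @param step Quantization step (g) for feature extraction.
#' @param resample_factor,n_max Scaling constants, see [mlp_parameters()].
#' @param select_tol Parsimony tolerance (percentage points) for model
#'   selection, see [select_model()].
#' @return An object of class `train_config`.
#' @export
train_config <- function(hidden_sizes = 1:9, split_fraction = 0.5,
                         seed = 1L, learning_rate = 5, epochs = 10000,
                         patience = 200, min_delta = 1e-7, n_restarts = 3,
                         step = 1,
                         resample_factor = 300, n_max = 2048,
                         select_tol = 0.1) {
  stopifnot(split_fraction > 0, split_fraction < 1, learning_rate > 0,
            epochs >= 1, all(hidden_sizes >= 1))
  structure(as.list(environment()), class = "train_config")
}

#' Build supervised examples from mixed patterns
#'
#' Only patterns with at least one stable and one unstable reading are
#' eligible: the stable mean is the target and the features come from the
#' stable-removed sequence. Others are skipped (with a count reported).
#'
#' @param patterns List of `weigh_pattern` objects.
#' @param step Quantization step (g).
#' @param verbose Report how many patterns were skipped?
#' @return A list with `features` (matrix, one row per example), `target`
#'   (numeric, grams) and `n_skipped`.
#' @export
build_training_set <- function(patterns, step = 1, verbose = FALSE) {
  keep <- vapply(patterns, function(p) {
    any(p$samples$stable) && any(!p$samples$stable)
  }, logical(1))
  if (!any(keep))
    stop("no eligible patterns: training needs patterns with both stable and unstable readings")
  eligible <- patterns[keep]
  feats <- t(vapply(eligible, function(p)
    extract_features(p, step = step, exclude_stable = TRUE), numeric(9)))
  colnames(feats) <- feature_names
  target <- vapply(eligible, function(p)
    mean(p$samples$weight_g[p$samples$stable]), numeric(1))
  if (verbose)
    message(sprintf("build_training_set: %d examples, %d patterns skipped",
                    sum(keep), sum(!keep)))
  list(features = feats, target = target, n_skipped = sum(!keep))
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Split examples into disjoint train and test sets
#'
#' @param examples A list as returned by [build_training_set()].
#' @param fraction Training fraction; the train set gets
#'   `ceiling(n * fraction)` examples.
#' @param seed Seed making the split reproducible.
#' @return A list with `train` and `test`, each holding `features` and
#'   `target`; together they are disjoint and exhaustive.
#' @export
split_dataset <- function(examples, fraction = 0.5, seed = 1L) {
  n <- length(examples$target)
  stopifnot(n >= 2, fraction > 0, fraction < 1)
  idx <- with_seed(seed, sample.int(n, ceiling(n * fraction)))
  subset_ex <- function(i) list(features = examples$features[i, , drop = FALSE],
                                target = examples$target[i])
  list(train = subset_ex(idx), test = subset_ex(setdiff(seq_len(n), idx)))
}

#' Train one network by back-propagation
#'
#' Full-batch gradient descent on the mean squared error of the scaled
#' output (targets divided by the resample factor), sigmoid activations
#' throughout, weights initialized uniform on (-0.5, 0.5) from the run's
#' seed. The loss is non-convex, so `n_restarts` independent
#' initializations are fitted and the one with the lowest final training
#' MSE is returned. Deterministic for a fixed seed.
#'
#' @param train A list with `features` (matrix) and `target` (grams).
#' @param cfg A [train_config()].
#' @param hidden_size Number of hidden neurons.
#' @return A fitted [mlp_parameters()] object with attribute `"history"`
#'   (per-epoch training MSE of the kept restart, in scaled units).
#' @export
train_mlp <- function(train, cfg = train_config(), hidden_size = 3) {
  X <- scale_features(train$features,
                      list(layer_sizes = c(ncol(train$features), hidden_size, 1),
                           resample_factor = cfg$resample_factor,
                           n_max = cfg$n_max))
  t_scaled <- train$target / cfg$resample_factor
  if (any(!is.finite(X)) || any(!is.finite(t_scaled)))
    stop("non-finite training inputs")
  best_fit <- NULL
  for (r in seq_len(max(1L, cfg$n_restarts))) {
    fit <- backprop_fit(X, t_scaled, hidden_size, cfg,
                        init_seed = cfg$seed + hidden_size + 7919L * (r - 1L))
    if (is.null(best_fit) || fit$final_mse < best_fit$final_mse)
      best_fit <- fit
  }
  params <- mlp_parameters(hidden_weights = best_fit$W1,
                           hidden_bias = best_fit$b1,
                           output_weights = best_fit$w2,
                           output_bias = best_fit$b2,
                           resample_factor = cfg$resample_factor,
                           n_max = cfg$n_max)
  attr(params, "history") <- best_fit$history
  params
}

# One gradient-descent run from one random initialization.
backprop_fit <- function(X, t_scaled, H, cfg, init_seed) {
  n <- nrow(X); d <- ncol(X)
  init <- with_seed(init_seed, stats::runif(d * H + H + H + 1, -0.5, 0.5))
  W1 <- matrix(init[seq_len(d * H)], d, H)
  b1 <- init[d * H + seq_len(H)]
  w2 <- init[d * H + H + seq_len(H)]
  b2 <- init[d * H + 2 * H + 1]

  sig <- function(x) 1 / (1 + exp(-x))
  lr <- cfg$learning_rate
  best <- Inf; stall <- 0L
  history <- numeric(cfg$epochs)
  mse <- Inf
  for (ep in seq_len(cfg$epochs)) {
    Hid <- sig(sweep(X %*% W1, 2, b1, "+"))          # n x H
    y <- sig(drop(Hid %*% w2) + b2)                  # n
    err <- y - t_scaled
    mse <- mean(err^2)
    if (!is.finite(mse)) stop(sprintf(
      "training diverged at epoch %d (H=%d, lr=%g)", ep, H, lr))
    history[ep] <- mse
    # output layer: dL/dz2 = 2/n * err * y(1-y)
    dz2 <- 2 * err * y * (1 - y) / n                 # n
    gw2 <- drop(crossprod(Hid, dz2))                 # H
    gb2 <- sum(dz2)
    dH <- tcrossprod(dz2, w2) * Hid * (1 - Hid)      # n x H
    gW1 <- crossprod(X, dH)                          # d x H
    gb1 <- colSums(dH)
    W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
    w2 <- w2 - lr * gw2; b2 <- b2 - lr * gb2
    if (mse < best - cfg$min_delta) { best <- mse; stall <- 0L }
    else stall <- stall + 1L
    if (stall >= cfg$patience) { history <- history[seq_len(ep)]; break }
  }
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2, final_mse = mse,
       history = history)
}

#' Mean percent accuracy of a model on a test set
#'
#' @param model An `mlp_parameters` object.
#' @param test A list with `features` and `target`.
#' @return Mean of [accuracy_percent()] (unrounded) over the test examples;
#'   invariant to example order.
#' @export
evaluate_model <- function(model, test) {
  stopifnot(length(test$target) >= 1)
  pred <- mlp_forward(test$features, model)
  mean(accuracy_percent(test$target, pred, digits = NULL))
}

#' Select the most parsimonious near-best network
#'
#' Ranks candidates by mean test accuracy and returns the smallest hidden
#' size whose accuracy is within `tol` percentage points of the best
#' (exact ties therefore go to the smallest network).
#'
#' @param candidates Named list of fitted `mlp_parameters`, names = hidden
#'   sizes.
#' @param test Held-out examples (`features`, `target`).
#' @param tol Parsimony tolerance in percentage points.
#' @return The selected `mlp_parameters`, with attributes
#'   `"selected_hidden"` and `"accuracy_table"` (data frame of hidden size
#'   vs mean accuracy).
#' @export
select_model <- function(candidates, test, tol = 0.1) {
  stopifnot(length(candidates) >= 1)
  hs <- vapply(candidates, function(m) m$layer_sizes[2], numeric(1))
  acc <- vapply(candidates, evaluate_model, numeric(1), test = test)
  ord <- order(hs)
  hs <- hs[ord]; acc <- acc[ord]; candidates <- candidates[ord]
  pick <- which(acc >= max(acc) - tol)[1]
  out <- candidates[[pick]]
  attr(out, "selected_hidden") <- unname(hs[pick])
  attr(out, "accuracy_table") <- data.frame(hidden = hs,
                                            mean_accuracy = acc)
  out
}

#' Run the full hidden-size sweep
#'
#' Convenience wrapper: split, train one network per hidden size, evaluate
#' on the held-out half and select.
#'
#' @param examples Output of [build_training_set()].
#' @param cfg A [train_config()].
#' @return The selected model (see [select_model()]); its
#'   `"accuracy_table"` attribute is the per-size report.
#' @export
train_sweep <- function(examples, cfg = train_config()) {
  parts <- split_dataset(examples, cfg$split_fraction, cfg$seed)
  fits <- lapply(cfg$hidden_sizes, function(h) train_mlp(parts$train, cfg, h))
  names(fits) <- cfg$hidden_sizes
  select_model(fits, parts$test, tol = cfg$select_tol)
}
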