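# Supervised set construction, splitting, back-propagation and model
# selection.

toy_examples <- function(n = 60, seed = 1) {
  # targets equal the modal weight: a noiseless learnable mapping
  set.seed(seed)
  feats <- t(replicate(n, extract_features(
    sample(140:160, 40, replace = TRUE))))
  list(features = feats, target = unname(feats[, "max_1"]))
}

test_that("training examples pair stable means with stable-removed features", {
  p <- make_pattern(c(150, 151, 140, 160, 160, 145),
                    stable = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  all_stable <- make_pattern(rep(150, 5), stable = rep(TRUE, 5))
  all_unstable <- make_pattern(rep(150, 5))
  ex <- build_training_set(list(p, all_stable, all_unstable))
  expect_equal(length(ex$target), 1)
  expect_equal(ex$target, 150.5)
  expect_equal(ex$features[1, "n_el"], c(n_el = 4))  # stable samples removed
  expect_equal(ex$features[1, "max_1"], c(max_1 = 160))
  expect_equal(ex$n_skipped, 2)
  expect_error(build_training_set(list(all_stable, all_unstable)),
               "no eligible")
})

test_that("the random split is disjoint, exhaustive and reproducible", {
  ex <- toy_examples(21)
  s1 <- split_dataset(ex, 0.5, seed = 9)
  s2 <- split_dataset(ex, 0.5, seed = 9)
  expect_identical(s1$train$target, s2$train$target)
  expect_equal(length(s1$train$target), 11)  # ceiling(21 * 0.5)
  expect_equal(length(s1$test$target), 10)
  expect_equal(sort(c(s1$train$target, s1$test$target)), sort(ex$target))

  ex3 <- list(features = ex$features[1:3, ], target = ex$target[1:3])
  s3 <- split_dataset(ex3, 0.5, seed = 1)
  expect_equal(length(s3$train$target), 2)
  expect_equal(length(s3$test$target), 1)

  for (seed in 1:5) {
    s <- split_dataset(ex, 0.3, seed = seed)
    expect_equal(length(s$train$target) + length(s$test$target),
                 length(ex$target))
  }
})

test_that("back-propagation fits a noiseless toy mapping", {
  ex <- toy_examples(80, seed = 3)
  cfg <- train_config(seed = 3)
  m <- train_mlp(ex, cfg, hidden_size = 3)
  hist <- attr(m, "history")
  expect_lt(hist[length(hist)], 1e-3)
  expect_lt(hist[length(hist)], hist[1])
  # loss decreases in the large: the running minimum keeps dropping
  expect_lt(min(hist[seq_len(50)]) , hist[1])
  pred <- mlp_forward(ex$features, m)
  expect_lt(mean(abs(pred - ex$target)), 5)
})

test_that("a single example is fitted to near-zero loss", {
  ex <- toy_examples(1, seed = 5)
  m <- train_mlp(ex, train_config(seed = 5), hidden_size = 2)
  hist <- attr(m, "history")
  expect_lt(hist[length(hist)], 1e-6)
})

test_that("training is deterministic for a fixed seed", {
  ex <- toy_examples(40, seed = 7)
  cfg <- train_config(seed = 11, epochs = 500)
  m1 <- train_mlp(ex, cfg, 3)
  m2 <- train_mlp(ex, cfg, 3)
  expect_identical(m1$hidden_weights, m2$hidden_weights)
  expect_identical(m1$output_weights, m2$output_weights)
  m3 <- train_mlp(ex, train_config(seed = 12, epochs = 500), 3)
  expect_false(identical(m1$hidden_weights, m3$hidden_weights))
})

test_that("model selection applies the parsimony rule", {
  # constant-output candidates engineered to fixed accuracies on a
  # one-example test set with target 150 g
  test_set <- list(features = matrix(c(150, 40, 149, 10, 150, 8, 149, 5, 40),
                                     nrow = 1), target = 150)
  acc_to_pred <- function(acc) 150 * (1 + (1 - acc / 100))
  cands <- list(`1` = constant_mlp(acc_to_pred(97.0), hidden = 1),
                `3` = constant_mlp(acc_to_pred(98.5), hidden = 3),
                `9` = constant_mlp(acc_to_pred(98.55), hidden = 9))
  sel <- select_model(cands, test_set, tol = 0.1)
  expect_equal(attr(sel, "selected_hidden"), 3)
  tab <- attr(sel, "accuracy_table")
  expect_equal(tab$hidden, c(1, 3, 9))
  expect_equal(tab$mean_accuracy, c(97.0, 98.5, 98.55), tolerance = 1e-6)

  sel1 <- select_model(cands["3"], test_set)
  expect_equal(attr(sel1, "selected_hidden"), 3)

  # exact tie: smallest network wins
  tied <- list(`2` = constant_mlp(153, hidden = 2),
               `5` = constant_mlp(153, hidden = 5))
  expect_equal(attr(select_model(tied, test_set, tol = 0), "selected_hidden"), 2)
})

test_that("evaluation metric is exact on engineered predictors and order-free", {
  test_set <- list(features = matrix(rep(1, 18), nrow = 2), target = c(150, 150))
  expect_equal(evaluate_model(constant_mlp(150), test_set), 100)
  expect_equal(evaluate_model(constant_mlp(150 * 1.015), test_set), 98.5,
               tolerance = 1e-9)

  ex <- toy_examples(30, seed = 13)
  m <- train_mlp(ex, train_config(seed = 13, epochs = 300), 2)
  perm <- sample(seq_along(ex$target))
  shuffled <- list(features = ex$features[perm, ], target = ex$target[perm])
  expect_equal(evaluate_model(m, ex), evaluate_model(m, shuffled))
})
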