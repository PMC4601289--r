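test_that("separable toy problems are fitted exactly", {
  X <- matrix(c(1, 1, 0, 0,
                0, 0, 1, 1), ncol = 2)
  y <- c(1, 1, 0, 0)
  m <- train_ensemble(X, y, learner_params(n_trees = 10, k_features = 2,
                                           seed = 3))
  expect_equal(unname(predict_proba(m, X)), y)

  # fully grown trees reach purity, so training probabilities equal labels
  # for any seed
  m2 <- train_ensemble(X, y, learner_params(n_trees = 50, k_features = 2,
                                            seed = 99))
  expect_equal(unname(predict_proba(m2, X)), y)
})

test_that("degenerate single-class input yields a constant model", {
  X <- matrix(rnorm(20), 10, 2)
  m1 <- train_ensemble(X, rep(1, 10), fast_params())
  expect_equal(unname(predict_proba(m1, X)), rep(1, 10))
  m0 <- train_ensemble(X, rep(0, 10), fast_params())
  expect_equal(unname(predict_proba(m0, X)), rep(0, 10))
  # no splits happen, so importances are all zero
  expect_equal(sum(feature_importances(m1)$importance), 0)
})

test_that("training is deterministic given a seed", {
  set.seed(10)
  X <- matrix(rnorm(200), 50, 4)
  y <- as.integer(X[, 1] + rnorm(50, sd = 0.5) > 0)
  Xt <- matrix(rnorm(80), 20, 4)
  m1 <- train_ensemble(X, y, learner_params(n_trees = 20, seed = 7))
  m2 <- train_ensemble(X, y, learner_params(n_trees = 20, seed = 7))
  expect_identical(predict_proba(m1, Xt), predict_proba(m2, Xt))
  m3 <- train_ensemble(X, y, learner_params(n_trees = 20, seed = 8))
  expect_false(identical(predict_proba(m1, Xt), predict_proba(m3, Xt)))
})

test_that("ensemble probability is the mean of per-tree leaf frequencies", {
  set.seed(2)
  X <- matrix(rnorm(120), 40, 3)
  y <- as.integer(X[, 2] > 0)
  m <- train_ensemble(X, y, learner_params(n_trees = 2, seed = 5))
  Xt <- matrix(rnorm(30), 10, 3)
  leaves <- leaf_assignments(m, Xt)
  manual <- sapply(seq_len(10), function(i) {
    mean(sapply(1:2, function(t) m$forest$trees[[t]]$prob[leaves[i, t] + 1L, 1]))
  })
  expect_equal(unname(predict_proba(m, Xt)), manual)
})

test_that("leaf assignments reflect identical decision paths", {
  X <- matrix(c(1, 1, 0, 0,
                0, 0, 1, 1), ncol = 2)
  y <- c(1, 1, 0, 0)
  m <- train_ensemble(X, y, learner_params(n_trees = 1, k_features = 2,
                                           seed = 3))
  leaves <- leaf_assignments(m, X)
  # one binary split: exactly two leaves, grouping the two classes
  expect_length(unique(leaves[, 1]), 2)
  expect_equal(leaves[1, 1], leaves[2, 1])
  expect_equal(leaves[3, 1], leaves[4, 1])
  # identical samples land in identical leaves in every tree
  m2 <- train_ensemble(X, y, fast_params())
  l2 <- leaf_assignments(m2, X[c(1, 1), , drop = FALSE])
  expect_equal(l2[1, ], l2[2, ])
  # depth-0 tree (constant labels): everything in the root leaf
  m3 <- train_ensemble(X, rep(1, 4), learner_params(n_trees = 3, seed = 1))
  expect_true(all(leaf_assignments(m3, X) == 0))
})

test_that("feature importances are normalized and identify the signal", {
  set.seed(4)
  X <- cbind(sig = rep(c(0, 1), each = 25), noise = rnorm(50))
  y <- X[, 1]
  m <- train_ensemble(X, y, learner_params(n_trees = 30, seed = 2))
  imp <- feature_importances(m)
  expect_equal(sum(imp$importance), 1)
  # with K = 1 the noise feature is drawn half the time and collects small
  # chance gains, but the separating feature must dominate
  expect_gt(imp$importance[imp$feature == "sig"], 0.8)
  # with both features inspected at every node, the split is always the
  # separating one
  m2 <- train_ensemble(X, y, learner_params(n_trees = 30, k_features = 2,
                                            seed = 2))
  expect_equal(feature_importances(m2)$importance, c(1, 0))
})

test_that("multi-output models fit one ensemble jointly over all outputs", {
  set.seed(6)
  X <- matrix(rnorm(200), 50, 4)
  Y <- cbind(a = as.integer(X[, 1] > 0), b = as.integer(X[, 1] > 0.5))
  m <- train_ensemble(X, Y, learner_params(n_trees = 20, seed = 9))
  pr <- predict_proba(m, X)
  expect_equal(dim(pr), c(50, 2))
  expect_equal(colnames(pr), c("a", "b"))
  expect_true(all(pr >= 0 & pr <= 1))
  # a single forest serves both outputs: leaf structure shared
  expect_equal(m$n_outputs, 2)
  expect_gt(auroc(pr[, 1], Y[, 1]), 0.95)
  expect_gt(auroc(pr[, 2], Y[, 2]), 0.95)
})

test_that("shape and label validation errors are raised", {
  X <- matrix(rnorm(20), 10, 2)
  y <- rep(c(0, 1), 5)
  m <- train_ensemble(X, y, fast_params())
  expect_error(predict_proba(m, matrix(0, 2, 3)),
               class = "treepairs_shape_error")
  expect_error(train_ensemble(X, y[-1], fast_params()),
               class = "treepairs_shape_error")
  expect_error(train_ensemble(X, y + 1, fast_params()),
               class = "treepairs_label_error")
})

test_that("bootstrap resampling changes trees but keeps determinism", {
  set.seed(11)
  X <- matrix(rnorm(200), 50, 4)
  y <- as.integer(X[, 1] > 0)
  p <- learner_params(n_trees = 15, bootstrap = TRUE, seed = 4)
  m1 <- train_ensemble(X, y, p)
  m2 <- train_ensemble(X, y, p)
  expect_identical(predict_proba(m1, X), predict_proba(m2, X))
  expect_gt(auroc(predict_proba(m1, X), y), 0.9)
})

test_that("predictions agree with an independent extra-trees implementation", {
  skip_if_not_installed("ranger")
  set.seed(12)
  n <- 300
  X <- matrix(rnorm(n * 6), n, 6)
  colnames(X) <- paste0("f", 1:6)
  y <- as.integer(X[, 1] + 0.5 * X[, 2] + rnorm(n, sd = 0.7) > 0)
  tr <- 1:200
  te <- 201:n
  ours <- train_ensemble(X[tr, ], y[tr], learner_params(n_trees = 100,
                                                        seed = 3))
  s_ours <- predict_proba(ours, X[te, ])
  rf <- ranger::ranger(y = factor(y[tr]), x = as.data.frame(X[tr, ]),
                       num.trees = 100, splitrule = "extratrees",
                       probability = TRUE, replace = FALSE,
                       sample.fraction = 1, mtry = round(sqrt(6)),
                       num.random.splits = 1, seed = 3)
  s_ref <- predict(rf, as.data.frame(X[te, ]))$predictions[, "1"]
  a1 <- auroc(s_ours, y[te])
  a2 <- auroc(s_ref, y[te])
  expect_lt(abs(a1 - a2), 0.05)
  expect_gt(a1, 0.8)
})
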