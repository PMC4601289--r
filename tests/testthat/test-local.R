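test_that("single-output training builds one model per learning-sample node", {
  net <- signal_net(5)
  ls <- known_pairs(net)
  # 3 rows x 2 cols fully known: 2 column models + 3 row models
  sub <- dplyr::filter(ls, row <= 3, col <= 2)
  m <- train_local_so(net, sub, fast_params())
  expect_length(m$col_models, 2)
  expect_length(m$row_models, 3)
  expect_equal(glance(m)$n_models, 5)

  hom <- tiny_homogeneous()
  mh <- train_local_so(hom, known_pairs(hom), fast_params())
  expect_length(mh$node_models, 4)
})

test_that("an all-negative node gets a constant-zero model", {
  net <- tiny_bipartite()
  ls <- known_pairs(net)
  # column 3 has a single known pair with label 1; column 1 labels are 0/1;
  # force an all-zero column by relabeling
  ls0 <- dplyr::mutate(ls, label = ifelse(col == 2, 0L, label))
  m <- train_local_so(net, ls0, fast_params())
  expect_equal(unname(predict_proba(m$col_models[["2"]],
                                    net$rows$features)), c(0, 0))
})

test_that("LS x LS scores are the exact mean of the two component models", {
  net <- signal_net(7)
  ls <- known_pairs(net)
  m <- train_local_so(net, ls, fast_params())
  test <- ls[c(3, 50, 200), ]
  s <- predict_lsls_local(m, net, test)
  manual <- sapply(seq_len(nrow(test)), function(i) {
    r <- test$row[i]
    cc <- test$col[i]
    fr <- predict_proba(m$row_models[[as.character(r)]],
                        net$cols$features[cc, , drop = FALSE])
    fc <- predict_proba(m$col_models[[as.character(cc)]],
                        net$rows$features[r, , drop = FALSE])
    (fr + fc) / 2
  })
  expect_equal(s$score, manual)

  # homogeneous swap-invariance
  hom <- signal_net_homog(8)
  mh <- train_local_so(hom, known_pairs(hom), fast_params())
  q <- tibble::tibble(row = c(2L, 9L), col = c(9L, 2L))
  sh <- predict_lsls_local(mh, hom, q)
  expect_identical(sh$score[1], sh$score[2])
})

test_that("LS x TS scores are the LS node's single prediction", {
  net <- signal_net(5)
  all_p <- known_pairs(net)
  ts_r <- 1:8
  ts_c <- 1:6
  train <- dplyr::filter(all_p, !(row %in% ts_r), !(col %in% ts_c))
  m <- train_local_so(net, train, fast_params())
  lsts <- dplyr::filter(all_p, !(row %in% ts_r), col %in% ts_c)[1:5, ]
  s <- predict_lsts_local(m, net, lsts)
  manual <- sapply(seq_len(nrow(lsts)), function(i) {
    predict_proba(m$row_models[[as.character(lsts$row[i])]],
                  net$cols$features[lsts$col[i], , drop = FALSE])
  })
  expect_equal(s$score, manual)
  # pairs with two LS nodes are rejected here
  expect_error(predict_lsts_local(m, net, train[1, ]),
               class = "treepairs_validation_error")
})

test_that("multi-output training demands a fully observed block", {
  net <- signal_net(5)
  ls <- known_pairs(net)
  m <- train_local_mo(net, ls, fast_params())
  expect_equal(m$model_rows$n_outputs, ncol(net$adjacency))
  expect_equal(m$model_cols$n_outputs, nrow(net$adjacency))
  masked <- mask_entries(net, 0.05, seed = 1)
  expect_error(train_local_mo(masked, known_pairs(masked), fast_params()),
               class = "treepairs_precondition_error")
})

test_that("single- and multi-output variants agree on an easy fixture", {
  net <- signal_net(6)
  all_p <- known_pairs(net)
  ts_r <- 1:8
  ts_c <- 1:6
  train <- dplyr::filter(all_p, !(row %in% ts_r), !(col %in% ts_c))
  lsts <- dplyr::filter(all_p, !(row %in% ts_r), col %in% ts_c)
  p <- fast_params(50)
  a <- sapply(c("so", "mo"), function(v) {
    m <- if (v == "so") train_local_so(net, train, p)
         else train_local_mo(net, train, p)
    auroc(predict_lsts_local(m, net, lsts)$score, lsts$label)
  })
  expect_gt(a[["so"]], 0.85)
  expect_gt(a[["mo"]], 0.85)
  expect_lt(abs(a[["so"]] - a[["mo"]]), 0.1)
})

test_that("choose_threshold realizes the largest proportion below target", {
  ct <- choose_threshold(c(0.9, 0.8, 0.3, 0.1), threshold_rule(0.5))
  expect_equal(ct$m, 2L)
  expect_gt(ct$cutoff, 0.3)
  expect_lte(ct$cutoff, 0.8)
  expect_equal(choose_threshold(c(0.4, 0.2), threshold_rule(0))$m, 0L)
  expect_equal(choose_threshold(c(0.4, 0.2), threshold_rule(1))$m, 2L)

  # ties at the cutoff: deterministic admission by (row, col)
  pairs <- tibble::tibble(row = c(2L, 1L, 1L, 3L), col = c(1L, 2L, 1L, 1L),
                          score = c(0.5, 0.5, 0.5, 0.1))
  b <- binarize_scores(pairs, threshold_rule(0.5))
  expect_equal(sum(b$pred), 2)
  expect_equal(b$pred[b$row == 1L & b$col == 1L], 1L)
  expect_equal(b$pred[b$row == 1L & b$col == 2L], 1L)
  expect_equal(b$pred[b$row == 2L], 0L)
})

test_that("threshold proportion bound holds against brute force", {
  set.seed(33)
  for (i in 1:300) {
    n <- sample(1:40, 1)
    scores <- round(runif(n), sample(c(1, 2), 1)) # induce ties
    target <- runif(1)
    ct <- choose_threshold(scores, threshold_rule(target))
    # oracle: the largest m with m/n <= target
    m_star <- max(which(c(0, seq_len(n)) / n <= target)) - 1L
    expect_equal(ct$m, m_star)
    pairs <- tibble::tibble(row = seq_len(n), col = 1L, score = scores)
    b <- binarize_scores(pairs, threshold_rule(target))
    expect_equal(sum(b$pred), m_star)
    # all predicted positives score at least as high as any negative
    if (m_star > 0 && m_star < n) {
      expect_gte(min(b$score[b$pred == 1]), max(b$score[b$pred == 0]))
    }
  }
})

test_that("the two-step procedure scores unseen-unseen pairs by averaging", {
  net <- signal_net(5)
  all_p <- known_pairs(net)
  ts_r <- 1:8
  ts_c <- 1:6
  train <- dplyr::filter(all_p, !(row %in% ts_r), !(col %in% ts_c))
  m <- train_local_so(net, train, fast_params())
  ts2 <- two_step_train(m, net, ts_r, ts_c)
  expect_length(ts2$row_step2, 8)
  expect_length(ts2$col_step2, 6)
  tst <- dplyr::filter(all_p, row %in% ts_r, col %in% ts_c)[1:6, ]
  s <- predict_tsts_local(ts2, net, tst)
  manual <- sapply(seq_len(nrow(tst)), function(i) {
    c1 <- predict_proba(ts2$row_step2[[as.character(tst$row[i])]],
                        net$cols$features[tst$col[i], , drop = FALSE])
    c2 <- predict_proba(ts2$col_step2[[as.character(tst$col[i])]],
                        net$rows$features[tst$row[i], , drop = FALSE])
    (c1 + c2) / 2
  })
  expect_equal(s$score, manual)
  # empty TS sets produce empty model sets
  e <- two_step_train(m, net, integer(), integer())
  expect_length(e$row_step2, 0)

  # an LS node or an uncovered node is rejected
  expect_error(predict_tsts_local(ts2, net,
                                  tibble::tibble(row = 20L, col = 1L)),
               class = "treepairs_validation_error")
})

test_that("an all-negative binarized row yields a constant-zero model", {
  net <- noiseless_net()
  all_p <- known_pairs(net)
  ts_r <- 41:48
  ts_c <- 33:40
  train <- dplyr::filter(all_p, !(row %in% ts_r), !(col %in% ts_c))
  m <- train_local_so(net, train, fast_params())
  # force an absurdly low target: nothing admitted, all models constant 0
  ts2 <- two_step_train(m, net, ts_r, ts_c, rule = threshold_rule(0))
  tst <- dplyr::filter(all_p, row %in% ts_r, col %in% ts_c)
  s <- predict_tsts_local(ts2, net, tst)
  expect_true(all(s$score == 0))
})

test_that("the model count contract holds for both variants", {
  net <- signal_net(5)
  all_p <- known_pairs(net)
  ts_r <- 1:8
  ts_c <- 1:6
  train <- dplyr::filter(all_p, !(row %in% ts_r), !(col %in% ts_c))
  so <- train_local_so(net, train, fast_params())
  expect_equal(glance(so)$n_models, (40 - 8) + (30 - 6))
  mo <- train_local_mo(net, train, fast_params())
  expect_equal(glance(mo)$n_models, 2)
  ts_so <- two_step_train(so, net, ts_r, ts_c)
  expect_equal(length(ts_so$row_step2) + length(ts_so$col_step2), 8 + 6)
  ts_mo <- two_step_train(mo, net, ts_r, ts_c)
  # multi-output: one joint second-step model per side, four in total
  expect_s3_class(ts_mo$row_step2, "et_ensemble")
  expect_s3_class(ts_mo$col_step2, "et_ensemble")
})
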