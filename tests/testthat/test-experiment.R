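small_synth <- list(n_rows = 40, n_cols = 30, p_rows = 12, p_cols = 12,
                    k_row_groups = 4, k_col_groups = 4,
                    feature_noise_sd = 0.1, degree_skew = 0, seed = 5)
small_synth$block_density <- block_pattern(4, 4, 0.25, 0.9)

test_that("run_experiment writes a deterministic report and artifacts", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  base <- run_config(method = "global", cv = "nodes", folds = 3, runs = 1,
                     seed = 4, learner = list(n_trees = 10),
                     synth = small_synth, out_dir = dir1)
  rep1 <- run_experiment(base)
  paths <- attr(rep1, "paths")
  expect_true(all(file.exists(paths)))
  expect_setequal(names(paths), c("report", "summary", "importances"))
  g <- glance(rep1)
  expect_setequal(g$family, c("LSxTS", "TSxLS", "TSxTS"))

  base$out_dir <- dir2
  rep2 <- run_experiment(base)
  expect_identical(readLines(paths[["report"]]),
                   readLines(attr(rep2, "paths")[["report"]]))
})

test_that("baseline runs train no ensembles and masked nets get predictions", {
  dir <- withr::local_tempdir()
  cfg <- run_config(method = "baseline", cv = "pairs", folds = 3, runs = 1,
                    seed = 2, synth = small_synth, out_dir = dir)
  t0 <- Sys.time()
  rep <- run_experiment(cfg)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 5)
  expect_false("importances" %in% names(attr(rep, "paths")))

  # with unknown entries, the final model scores them
  masked <- small_synth
  dir3 <- withr::local_tempdir()
  net <- mask_entries(generate_network(do.call(synth_config, small_synth)),
                      0.2, seed = 7)
  write_network(net, dir3)
  cfg2 <- run_config(method = "global", cv = "pairs", folds = 3, runs = 1,
                     seed = 2, learner = list(n_trees = 10),
                     data = list(adjacency = file.path(dir3, "adjacency.tsv"),
                                 row_features = file.path(dir3, "row_features.tsv"),
                                 col_features = file.path(dir3, "col_features.tsv")),
                     out_dir = withr::local_tempdir())
  rep2 <- run_experiment(cfg2)
  pp <- attr(rep2, "paths")[["predictions"]]
  pred <- readr::read_tsv(pp, show_col_types = FALSE)
  expect_equal(nrow(pred), sum(is.na(net$adjacency)))
  expect_true(all(pred$score >= 0 & pred$score <= 1))
})

test_that("configs reject unknown keys and invalid combinations", {
  expect_error(run_config(method = "local-mo", cv = "pairs"),
               class = "treepairs_config_error")
  expect_error(run_config(learner = list(trees = 5)),
               class = "treepairs_config_error")
  expect_error(run_config(synth = list(n_row = 5)),
               class = "treepairs_config_error")
  expect_error(run_config(data = list(adjacency = "a.tsv")),
               class = "treepairs_config_error")
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(method = "global", cv = "pairs", bogus = 1), path)
  expect_error(read_run_config(path), class = "treepairs_config_error")
})

test_that("multi-output biclusters tile the learning-sample adjacency", {
  net <- generate_network(do.call(synth_config, small_synth))
  ls <- known_pairs(net)
  mo <- train_local_mo(net, ls, fast_params(5))
  bc <- export_biclusters(mo, net)
  expect_equal(sum(bc$n_pairs), nrow(net$adjacency) * ncol(net$adjacency))
  expect_true(all(c("row_leaf", "col_leaf", "purity", "rule") %in% names(bc)))
  # sorted by interaction count
  expect_true(all(diff(bc$n_edges) <= 0))

  # constant model: a single bicluster covering the whole block
  net0 <- net
  net0$adjacency[] <- 0
  mo0 <- train_local_mo(net0, known_pairs(net0), fast_params(5))
  bc0 <- export_biclusters(mo0, net0)
  expect_equal(nrow(bc0), 1)
  expect_equal(bc0$n_pairs, nrow(net$adjacency) * ncol(net$adjacency))

  # a separable single-tree global model isolates pure edge regions
  nn <- noiseless_net()
  g1 <- train_global(nn, known_pairs(nn),
                     learner_params(n_trees = 1, seed = 3))
  bcg <- export_biclusters(g1, nn)
  expect_gte(nrow(bcg), 2)
  expect_true(any(bcg$purity > 0.99) && any(bcg$purity < 0.01))
})

test_that("the command-line interface runs end to end", {
  script <- system.file("scripts", "treepairs.R", package = "treepairs")
  expect_true(nzchar(script))
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "synth.yaml")
  yaml::write_yaml(list(n_rows = 30, n_cols = 20, p_rows = 8, p_cols = 8,
                        k_row_groups = 4, k_col_groups = 4,
                        feature_noise_sd = 0.1, degree_skew = 0, seed = 3),
                   cfg_path)
  run <- function(...) {
    out <- system2(file.path(R.home("bin"), "Rscript"), c(script, ...),
                   stdout = TRUE, stderr = TRUE)
    expect_null(attr(out, "status"))
    out
  }
  run("synth", "--config", cfg_path, "--out-dir", dir)
  expect_true(file.exists(file.path(dir, "adjacency.tsv")))

  model_path <- file.path(dir, "model.rds")
  run("global", "train", "--adjacency", file.path(dir, "adjacency.tsv"),
      "--row-features", file.path(dir, "row_features.tsv"),
      "--col-features", file.path(dir, "col_features.tsv"),
      "--model", model_path, "--seed", "2")
  expect_true(file.exists(model_path))

  run("biclusters", "--model", model_path,
      "--adjacency", file.path(dir, "adjacency.tsv"),
      "--row-features", file.path(dir, "row_features.tsv"),
      "--col-features", file.path(dir, "col_features.tsv"),
      "--out", file.path(dir, "biclusters.tsv"))
  bc <- readr::read_tsv(file.path(dir, "biclusters.tsv"),
                        show_col_types = FALSE)
  expect_true(nrow(bc) >= 1)

  run("evaluate", "--method", "baseline", "--cv", "pairs",
      "--folds", "3", "--runs", "1", "--seed", "5",
      "--adjacency", file.path(dir, "adjacency.tsv"),
      "--row-features", file.path(dir, "row_features.tsv"),
      "--col-features", file.path(dir, "col_features.tsv"),
      "--out-dir", file.path(dir, "eval"))
  expect_true(file.exists(file.path(dir, "eval", "report.tsv")))
})
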