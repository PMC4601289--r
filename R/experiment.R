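# End-to-end experiment runner and interpretability exports. This is the
# layer the command-line interface (inst/scripts/treepairs.R) drives.

#' Experiment configuration
#'
#' Assembles and validates a full experiment description: where the network
#' comes from (TSV files or the synthetic generator), which method and CV
#' scheme to run, and the learner parameters. Unknown keys are rejected.
#'
#' @param method `"global"`, `"local-so"`, `"local-mo"` or `"baseline"`.
#' @param cv `"pairs"` or `"nodes"`.
#' @param folds,runs CV geometry (a 5-fold option is the standard choice for
#'   large networks).
#' @param seed Master seed; per-run, per-fold and per-model seeds derive
#'   from it deterministically.
#' @param learner Named list of [learner_params()] arguments.
#' @param data Named list with `adjacency`, `row_features` and optionally
#'   `col_features` paths, or `NULL` to use `synth`.
#' @param synth Named list of [synth_config()] arguments (used when `data`
#'   is `NULL`).
#' @param out_dir Output directory for report and artifact files.
#' @param plots Also write a PR/ROC (or boxplot) figure.
#' @param keep_scores Retain per-pair scores for pooled curves.
#' @return An object of class `run_config`.
#' @export
run_config <- function(method = "global", cv = "pairs", folds = 10,
                       runs = 10, seed = 1, learner = list(), data = NULL,
                       synth = list(), out_dir = tempfile("treepairs_run_"),
                       plots = FALSE, keep_scores = FALSE) {
  method <- match.arg(method, c("global", "local-so", "local-mo", "baseline"))
  cv <- match.arg(cv, c("pairs", "nodes"))
  if (cv == "pairs" && method == "local-mo") {
    abort("the local multi-output variant cannot be evaluated by CV on pairs (missing outputs)",
          class = "treepairs_config_error")
  }
  bad <- setdiff(names(learner), names(formals(learner_params)))
  if (length(bad)) {
    abort(paste0("unknown learner key(s): ", paste(bad, collapse = ", ")),
          class = "treepairs_config_error")
  }
  bad <- setdiff(names(synth), names(formals(synth_config)))
  if (length(bad)) {
    abort(paste0("unknown synth key(s): ", paste(bad, collapse = ", ")),
          class = "treepairs_config_error")
  }
  if (!is.null(data)) {
    bad <- setdiff(names(data), c("adjacency", "row_features", "col_features"))
    if (length(bad)) {
      abort(paste0("unknown data key(s): ", paste(bad, collapse = ", ")),
            class = "treepairs_config_error")
    }
    if (!all(c("adjacency", "row_features") %in% names(data))) {
      abort("data needs at least `adjacency` and `row_features` paths",
            class = "treepairs_config_error")
    }
  }
  structure(list(method = method, cv = cv, folds = folds, runs = runs,
                 seed = seed, learner = learner, data = data, synth = synth,
                 out_dir = out_dir, plots = plots, keep_scores = keep_scores),
            class = "run_config")
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file whose top-level keys are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), names(formals(run_config)))
  if (length(bad)) {
    abort(paste0("unknown config key(s) in ", path, ": ",
                 paste(bad, collapse = ", ")),
          class = "treepairs_config_error")
  }
  do.call(run_config, cfg)
}

config_network <- function(cfg) {
  if (!is.null(cfg$data)) {
    read_network(cfg$data$adjacency, cfg$data$row_features,
                 cfg$data$col_features)
  } else {
    generate_network(do.call(synth_config, cfg$synth))
  }
}

#' Run a full evaluation experiment
#'
#' Loads (or generates) the network, runs the configured cross-validation
#' protocol, and writes `report.tsv` (per-fold metrics), `summary.json`
#' (per-family averages), feature-importance rankings for the final model
#' fitted on all known pairs (one ranking for the global approach, separate
#' row- and column-feature rankings for the local multi-output approach),
#' `predictions.tsv` with scores for the unknown adjacency entries (when any
#' exist and the method can score them), and optionally a figure.
#' Deterministic given the config seed.
#'
#' @param cfg A [run_config()] or path to a YAML config.
#' @return The `eval_report`, invisibly; artifact paths in attribute
#'   `"paths"`.
#' @export
run_experiment <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  net <- config_network(cfg)
  params <- do.call(learner_params, cfg$learner)
  report <- if (cfg$cv == "pairs") {
    cv_on_pairs(net, cfg$method, params, folds = cfg$folds, runs = cfg$runs,
                seed = cfg$seed, keep_scores = cfg$keep_scores)
  } else {
    cv_on_nodes(net, cfg$method, params, folds = cfg$folds, runs = cfg$runs,
                seed = cfg$seed, keep_scores = cfg$keep_scores)
  }
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  paths <- c(report = file.path(cfg$out_dir, "report.tsv"),
             summary = file.path(cfg$out_dir, "summary.json"))
  readr::write_tsv(tidy(report), paths[["report"]], progress = FALSE)
  jsonlite::write_json(glance(report), paths[["summary"]], digits = NA,
                       pretty = TRUE)

  if (cfg$method != "baseline") {
    ls <- known_pairs(net)
    p <- params
    p$seed <- seq_seed(cfg$seed, 999983L)
    final <- tryCatch(
      switch(cfg$method,
             global = train_global(net, ls, p),
             `local-so` = train_local_so(net, ls, p),
             `local-mo` = train_local_mo(net, ls, p)),
      treepairs_precondition_error = function(e) {
        message("final model skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(final)) {
      imp <- switch(cfg$method,
                    global = tidy(final),
                    `local-mo` = tidy(final),
                    `local-so` = NULL) # one ranking per node: not emitted
      if (!is.null(imp)) {
        paths <- c(paths, importances = file.path(cfg$out_dir,
                                                  "importances.tsv"))
        readr::write_tsv(imp, paths[["importances"]], progress = FALSE)
      }
      unknown <- which(is.na(net$adjacency), arr.ind = TRUE)
      if (net$homogeneous && nrow(unknown)) {
        unknown <- unknown[unknown[, 1] < unknown[, 2], , drop = FALSE]
      }
      if (nrow(unknown)) {
        qp <- tibble::tibble(row = as.integer(unknown[, 1]),
                             col = as.integer(unknown[, 2]))
        pred <- switch(cfg$method,
                       global = predict_pairs_global(final, net, qp),
                       `local-so` = predict_local_any(final, net, qp),
                       `local-mo` = NULL) # unknown entries break its training
        if (!is.null(pred)) {
          pred <- dplyr::mutate(pred,
                                row_id = net$rows$ids[.data$row],
                                col_id = net$cols$ids[.data$col],
                                .before = 1)
          paths <- c(paths, predictions = file.path(cfg$out_dir,
                                                    "predictions.tsv"))
          readr::write_tsv(dplyr::arrange(pred, dplyr::desc(.data$score)),
                           paths[["predictions"]], progress = FALSE)
        }
      }
    }
  }

  if (cfg$plots) {
    paths <- c(paths, plot = file.path(cfg$out_dir, "report.png"))
    ggplot2::ggsave(paths[["plot"]], autoplot(report), width = 8, height = 4,
                    dpi = 150)
  }
  attr(report, "paths") <- paths
  invisible(report)
}

#' Leaf biclusters of a fitted model
#'
#' A tree of the global model assigns every learning-sample pair to a leaf,
#' i.e. to a rectangular submatrix of the adjacency matrix characterized by
#' the conjunction of feature tests on its root-to-leaf path; the tree aims
#' at submatrices that are all-connected or all-disconnected. The local
#' multi-output model instead partitions rows and columns separately, so its
#' biclusters are (row-leaf x column-leaf) combinations tiling the
#' learning-sample adjacency exactly once (checkerboard structure).
#'
#' @param model A [train_global()] or [train_local_mo()] model.
#' @param net The network the model was trained on.
#' @param pairs Learning-sample pairs to assign (defaults to all known
#'   pairs).
#' @param tree Which tree of the ensemble(s) to cut into biclusters.
#' @param out_path Optional TSV output path.
#' @return A tibble, sorted by decreasing interaction count, with member
#'   nodes, `n_pairs`, `n_edges`, `purity` and the defining feature tests.
#' @export
export_biclusters <- function(model, net, pairs = known_pairs(net), tree = 1,
                              out_path = NULL) {
  stopifnot(inherits(net, "pair_network"))
  if (inherits(model, "global_model")) {
    d <- build_pair_matrix(net, pairs, duplicate_symmetric = FALSE)
    leaf <- leaf_assignments(model$ensemble, d$X)[, tree]
    rules <- leaf_rules(model$ensemble, tree)
    out <- tibble::tibble(leaf = leaf,
                          row_id = net$rows$ids[pairs$row],
                          col_id = net$cols$ids[pairs$col],
                          label = pairs$label) |>
      dplyr::group_by(.data$leaf) |>
      dplyr::summarise(
        row_nodes = paste(sort(unique(.data$row_id)), collapse = ","),
        col_nodes = paste(sort(unique(.data$col_id)), collapse = ","),
        n_pairs = dplyr::n(), n_edges = sum(.data$label),
        purity = mean(.data$label), .groups = "drop") |>
      dplyr::left_join(rules[, c("leaf", "rule")], by = "leaf")
  } else if (inherits(model, "local_mo_model")) {
    if (model$homogeneous) {
      nodes <- model$ls_nodes
      lr <- leaf_assignments(model$node_model,
                             net$rows$features[nodes, , drop = FALSE])[, tree]
      rules_r <- rules_c <- leaf_rules(model$node_model, tree)
      lc <- lr
      row_nodes <- col_nodes <- nodes
    } else {
      row_nodes <- model$ls_rows
      col_nodes <- model$ls_cols
      lr <- leaf_assignments(model$model_rows,
                             net$rows$features[row_nodes, , drop = FALSE])[, tree]
      lc <- leaf_assignments(model$model_cols,
                             net$cols$features[col_nodes, , drop = FALSE])[, tree]
      rules_r <- leaf_rules(model$model_rows, tree)
      rules_c <- leaf_rules(model$model_cols, tree)
    }
    adj <- net$adjacency[row_nodes, col_nodes, drop = FALSE]
    grid <- tidyr::expand_grid(row_leaf = sort(unique(lr)),
                               col_leaf = sort(unique(lc)))
    out <- purrr::pmap_dfr(grid, function(row_leaf, col_leaf) {
      ri <- which(lr == row_leaf)
      ci <- which(lc == col_leaf)
      block <- adj[ri, ci, drop = FALSE]
      tibble::tibble(
        row_leaf = row_leaf, col_leaf = col_leaf,
        row_nodes = paste(net$rows$ids[row_nodes[ri]], collapse = ","),
        col_nodes = paste(net$cols$ids[col_nodes[ci]], collapse = ","),
        n_pairs = length(block), n_edges = sum(block, na.rm = TRUE),
        purity = mean(block, na.rm = TRUE),
        rule = paste0("row: ",
                      rules_r$rule[match(row_leaf, rules_r$leaf)],
                      " | col: ",
                      rules_c$rule[match(col_leaf, rules_c$leaf)]))
    })
  } else {
    abort("biclusters are defined for global and local multi-output models",
          class = "treepairs_validation_error")
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$n_edges))
  if (!is.null(out_path)) readr::write_tsv(out, out_path, progress = FALSE)
  out
}
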