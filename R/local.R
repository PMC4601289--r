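# The local approach: instead of one classifier over pairs, train per-node
# models predicting each node's interaction profile (single-output variant),
# or one multi-output model per node family (multiple-output variant), plus
# the two-step procedure that extends either variant to pairs of two unseen
# nodes.

seq_seed <- function(base, i) as.integer((base + i) %% .Machine$integer.max)

#' Train the local single-output models
#'
#' For every column node appearing in the learning sample, fits a model from
#' the features of row nodes to the known labels of the pairs involving that
#' column node; symmetrically for row nodes. A homogeneous network gets a
#' single family of per-node models over node features. Nodes whose pairs
#' are single-class get constant-probability models, not errors.
#'
#' @param net A [network()] object.
#' @param ls Learning sample of pairs (tibble with `row`, `col`, `label`).
#' @param params A [learner_params()].
#' @return An object of class `local_so_model`.
#' @export
train_local_so <- function(net, ls, params = learner_params()) {
  stopifnot(inherits(net, "pair_network"), nrow(ls) >= 1)
  base <- resolve_seed(params$seed)
  fit_family <- function(key, partner, features, seed_off) {
    groups <- split(seq_len(nrow(ls)), key)
    models <- vector("list", length(groups))
    names(models) <- names(groups)
    for (i in seq_along(groups)) {
      rows <- groups[[i]]
      p <- params
      p$seed <- seq_seed(base, seed_off + i)
      models[[i]] <- train_ensemble(features[partner[rows], , drop = FALSE],
                                    ls$label[rows], p)
    }
    models
  }
  out <- list(homogeneous = net$homogeneous,
              prevalence = mean(ls$label),
              params = params, base_seed = base)
  if (net$homogeneous) {
    # pairs involving node n on either side; partner features as inputs
    key <- c(ls$row, ls$col)
    partner <- c(ls$col, ls$row)
    label <- c(ls$label, ls$label)
    groups <- split(seq_along(key), key)
    models <- vector("list", length(groups))
    names(models) <- names(groups)
    for (i in seq_along(groups)) {
      idx <- groups[[i]]
      p <- params
      p$seed <- seq_seed(base, i)
      models[[i]] <- train_ensemble(
        net$rows$features[partner[idx], , drop = FALSE], label[idx], p)
    }
    out$node_models <- models
  } else {
    out$col_models <- fit_family(ls$col, ls$row, net$rows$features, 0L)
    out$row_models <- fit_family(ls$row, ls$col, net$cols$features, 100000L)
  }
  structure(out, class = c("local_so_model", "local_model"))
}

#' @export
print.local_so_model <- function(x, ...) {
  if (x$homogeneous) {
    cat("<local_so_model> homogeneous; ", length(x$node_models),
        " node models\n", sep = "")
  } else {
    cat("<local_so_model> bipartite; ", length(x$row_models), " row + ",
        length(x$col_models), " column models\n", sep = "")
  }
  invisible(x)
}

#' Train the local multi-output models
#'
#' Fits one multi-output ensemble per node family: the row-family model maps
#' row-node features to the node's full interaction profile over the learning
#' sample's column nodes, and symmetrically for the column family (a
#' homogeneous network gets a single model over node features). Requires the
#' learning-sample submatrix to be fully observed, because multi-output trees
#' cannot cope with missing output values.
#'
#' @inheritParams train_local_so
#' @return An object of class `local_mo_model`.
#' @export
train_local_mo <- function(net, ls, params = learner_params()) {
  stopifnot(inherits(net, "pair_network"), nrow(ls) >= 1)
  base <- resolve_seed(params$seed)
  adj <- net$adjacency
  if (net$homogeneous) {
    nodes <- sort(unique(c(ls$row, ls$col)))
    block <- adj[nodes, nodes, drop = FALSE]
    if (any(is.na(block[row(block) != col(block)]))) {
      abort(paste("the learning-sample submatrix has unknown entries;",
                  "multi-output trees cannot handle missing outputs —",
                  "use the single-output variant (train_local_so)"),
            class = "treepairs_precondition_error")
    }
    diag(block) <- 0
    p <- params
    p$seed <- seq_seed(base, 1L)
    model <- train_ensemble(net$rows$features[nodes, , drop = FALSE], block, p)
    return(structure(list(homogeneous = TRUE, node_model = model,
                          ls_nodes = nodes, prevalence = mean(ls$label),
                          params = params, base_seed = base),
                     class = c("local_mo_model", "local_model")))
  }
  ls_rows <- sort(unique(ls$row))
  ls_cols <- sort(unique(ls$col))
  block <- adj[ls_rows, ls_cols, drop = FALSE]
  if (anyNA(block)) {
    abort(paste("the LS_r x LS_c submatrix has unknown entries;",
                "multi-output trees cannot handle missing outputs —",
                "use the single-output variant (train_local_so)"),
          class = "treepairs_precondition_error")
  }
  p1 <- params; p1$seed <- seq_seed(base, 1L)
  p2 <- params; p2$seed <- seq_seed(base, 2L)
  structure(
    list(homogeneous = FALSE,
         model_rows = train_ensemble(net$rows$features[ls_rows, , drop = FALSE],
                                     block, p1),
         model_cols = train_ensemble(net$cols$features[ls_cols, , drop = FALSE],
                                     t(block), p2),
         ls_rows = ls_rows, ls_cols = ls_cols,
         prevalence = mean(ls$label), params = params, base_seed = base),
    class = c("local_mo_model", "local_model")
  )
}

#' @export
print.local_mo_model <- function(x, ...) {
  if (x$homogeneous) {
    cat("<local_mo_model> homogeneous; 1 model, ", length(x$ls_nodes),
        " outputs\n", sep = "")
  } else {
    cat("<local_mo_model> bipartite; 2 models (", length(x$ls_cols), " and ",
        length(x$ls_rows), " outputs)\n", sep = "")
  }
  invisible(x)
}

ls_row_nodes <- function(model) {
  if (model$homogeneous) {
    if (inherits(model, "local_mo_model")) model$ls_nodes
    else as.integer(names(model$node_models))
  } else if (inherits(model, "local_mo_model")) model$ls_rows
  else as.integer(names(model$row_models))
}

ls_col_nodes <- function(model) {
  if (model$homogeneous) ls_row_nodes(model)
  else if (inherits(model, "local_mo_model")) model$ls_cols
  else as.integer(names(model$col_models))
}

# prediction of pairs from a family of per-key single-output models applied
# to the partner node's features; NA where no model exists for the key
score_by_key <- function(models, key, partner, features) {
  out <- rep(NA_real_, length(key))
  sp <- split(seq_along(key), key)
  for (k in names(sp)) {
    m <- models[[k]]
    if (is.null(m)) next
    ii <- sp[[k]]
    out[ii] <- predict_proba(m, features[partner[ii], , drop = FALSE])
  }
  out
}

# multi-output profile lookups: predict the profile of each distinct `new`
# node and pick the component matching its LS partner; NA if partner not in
# the model's output set
score_mo <- function(model, new_idx, partner_idx, new_features, output_nodes) {
  out <- rep(NA_real_, length(new_idx))
  uq <- unique(new_idx)
  prof <- predict_proba(model, new_features[uq, , drop = FALSE])
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = length(uq))
  pos <- match(partner_idx, output_nodes)
  ok <- !is.na(pos)
  ri <- match(new_idx, uq)
  out[ok] <- prof[cbind(ri[ok], pos[ok])]
  out
}

# both component predictions for each pair (NA where undefined)
local_components <- function(model, net, pairs) {
  if (inherits(model, "local_so_model")) {
    if (model$homogeneous) {
      f <- net$rows$features
      cbind(score_by_key(model$node_models, pairs$row, pairs$col, f),
            score_by_key(model$node_models, pairs$col, pairs$row, f))
    } else {
      cbind(score_by_key(model$row_models, pairs$row, pairs$col,
                         net$cols$features),
            score_by_key(model$col_models, pairs$col, pairs$row,
                         net$rows$features))
    }
  } else { # multi-output first-step models
    if (model$homogeneous) {
      f <- net$rows$features
      # model(x)[j] estimates the edge between the node with features x and
      # LS node j, so a component is defined iff the looked-up node is in LS
      c1 <- score_mo(model$node_model, pairs$col, pairs$row, f, model$ls_nodes)
      c2 <- score_mo(model$node_model, pairs$row, pairs$col, f, model$ls_nodes)
      cbind(c1, c2)
    } else {
      # from the row side: model_rows predicts the row node's profile over
      # LS columns; defined when the row node is scored and col is in LS_c
      c_row <- score_mo(model$model_rows, pairs$row, pairs$col,
                        net$rows$features, model$ls_cols)
      c_col <- score_mo(model$model_cols, pairs$col, pairs$row,
                        net$cols$features, model$ls_rows)
      cbind(c_row, c_col)
    }
  }
}

#' Score pairs of two learning-sample nodes with a local model
#'
#' For a pair whose two nodes both appear in the learning sample, two
#' component predictions exist (one per node's model); the pair score is
#' their exact arithmetic mean, which also makes homogeneous predictions
#' swap-invariant.
#'
#' @param model A [train_local_so()] model (the multi-output variant cannot
#'   score LS x LS pairs: its training requires the full submatrix, leaving
#'   no held-out LS x LS pairs to score).
#' @param net The network supplying node features.
#' @param pairs Tibble with `row`, `col` columns; both nodes must be LS
#'   nodes.
#' @return `pairs` with a `score` column appended.
#' @export
predict_lsls_local <- function(model, net, pairs) {
  stopifnot(inherits(model, "local_so_model"))
  check_pair_indices(net, pairs)
  comp <- local_components(model, net, pairs)
  if (anyNA(comp)) {
    abort("all pair nodes must be learning-sample nodes for LS x LS scoring",
          class = "treepairs_validation_error")
  }
  dplyr::mutate(pairs, score = unname((comp[, 1] + comp[, 2]) / 2))
}

#' Score pairs of one learning-sample node and one unseen node
#'
#' Exactly one node of each pair must be a learning-sample node; its model
#' (single-output variant) or its family's multi-output model is applied to
#' the unseen node's features. No averaging: only one prediction exists.
#'
#' @param model A [train_local_so()] or [train_local_mo()] model.
#' @param net The network supplying node features.
#' @param pairs Tibble with `row`, `col` columns.
#' @return `pairs` with a `score` column appended.
#' @export
predict_lsts_local <- function(model, net, pairs) {
  stopifnot(inherits(model, "local_model"))
  check_pair_indices(net, pairs)
  comp <- local_components(model, net, pairs)
  n_def <- rowSums(!is.na(comp))
  if (any(n_def != 1)) {
    abort("each pair must have exactly one learning-sample node for LS x TS scoring",
          class = "treepairs_validation_error")
  }
  score <- ifelse(is.na(comp[, 1]), comp[, 2], comp[, 1])
  dplyr::mutate(pairs, score = unname(score))
}

# lenient scorer used by CV on pairs: average the defined components, fall
# back to the training prevalence when a fold leaves a node model-less
predict_local_any <- function(model, net, pairs) {
  comp <- local_components(model, net, pairs)
  score <- rowMeans(comp, na.rm = TRUE)
  score[is.nan(score)] <- model$prevalence
  dplyr::mutate(pairs, score = unname(score))
}

#' Threshold rule matching a target positive proportion
#'
#' @param target_proportion Desired fraction of predicted positives, usually
#'   the edge prevalence of the learning sample of pairs.
#' @return An object of class `threshold_rule`.
#' @export
threshold_rule <- function(target_proportion) {
  stopifnot(target_proportion >= 0, target_proportion <= 1)
  structure(list(target_proportion = target_proportion),
            class = "threshold_rule")
}

#' Score cutoff realizing a target positive proportion
#'
#' Returns the cutoff such that labelling the top-scoring fraction of pairs
#' positive yields the largest proportion not exceeding
#' `target_proportion` — i.e. `m = floor(target * N)` predicted positives.
#' Scores tied at the cutoff are admitted in ascending (row, col) order by
#' [binarize_scores()] until the proportion would be exceeded.
#'
#' @param scores Numeric vector of predicted probabilities.
#' @param rule A [threshold_rule()] or a bare target proportion.
#' @return A list with `cutoff` (score of the last admitted pair; `Inf` when
#'   nothing is admitted), `m` (number of predicted positives) and `n`.
#' @export
choose_threshold <- function(scores, rule) {
  if (!inherits(rule, "threshold_rule")) rule <- threshold_rule(rule)
  n <- length(scores)
  stopifnot(n >= 1)
  target <- rule$target_proportion
  m <- floor(target * n + 1e-9)
  cutoff <- if (m == 0) Inf else sort(scores, decreasing = TRUE)[m]
  list(cutoff = cutoff, m = as.integer(m), n = n, target = target)
}

#' Binarize pair scores at a target positive proportion
#'
#' Deterministic binarization used between the two steps of the two-step
#' procedure: pairs are ranked by (score decreasing, row, col) and the top
#' `floor(target * N)` are labelled 1. The (row, col) tie-break makes the
#' outcome reproducible when scores tie at the cutoff.
#'
#' @param pairs Tibble with `row`, `col`, `score` columns.
#' @param rule A [threshold_rule()] or bare target proportion.
#' @return `pairs` with a 0/1 `pred` column appended.
#' @export
binarize_scores <- function(pairs, rule) {
  if (!inherits(rule, "threshold_rule")) rule <- threshold_rule(rule)
  m <- choose_threshold(pairs$score, rule)$m
  ord <- order(-pairs$score, pairs$row, pairs$col)
  pred <- integer(nrow(pairs))
  pred[ord[seq_len(m)]] <- 1L
  dplyr::mutate(pairs, pred = pred)
}

#' Second-step models for unseen nodes
#'
#' The two-step procedure extends the local approach to pairs of two unseen
#' nodes. Step 1 scores every (unseen row, LS column) pair with the
#' first-step models (and symmetrically for unseen columns) and binarizes
#' each block so its positive proportion matches the learning sample's edge
#' prevalence. Step 2 fits, for each unseen node, a model from the LS
#' partners' features to these binarized pseudo-labels (the multi-output
#' variant fits one joint model per side, for four ensembles in total).
#'
#' @param model A first-step [train_local_so()] or [train_local_mo()] model.
#' @param net The network supplying node features.
#' @param ts_rows,ts_cols Integer indices of the unseen row/column nodes
#'   (for a homogeneous network pass the unseen nodes as `ts_rows`).
#' @param rule A [threshold_rule()]; defaults to the learning sample's edge
#'   prevalence as recorded in `model`.
#' @return An object of class `two_step_model`, retaining the binarized
#'   step-1 blocks for inspection.
#' @export
two_step_train <- function(model, net, ts_rows, ts_cols = integer(),
                           rule = NULL) {
  stopifnot(inherits(model, "local_model"))
  rule <- rule %||% threshold_rule(model$prevalence)
  params <- model$params
  base <- model$base_seed
  mo <- inherits(model, "local_mo_model")

  step1_block <- function(new_idx, partner_nodes, new_is_row) {
    # score all (new node, LS partner) pairs with the first-step models
    grid <- tidyr::expand_grid(new = new_idx, partner = partner_nodes)
    pairs <- if (new_is_row) {
      tibble::tibble(row = grid$new, col = grid$partner)
    } else {
      tibble::tibble(row = grid$partner, col = grid$new)
    }
    comp <- local_components(model, net, pairs)
    stopifnot(rowSums(!is.na(comp)) == 1)
    pairs$score <- ifelse(is.na(comp[, 1]), comp[, 2], comp[, 1])
    binarize_scores(pairs, rule)
  }

  fit_step2 <- function(block, new_idx, new_is_row, partner_nodes,
                        partner_features, seed_off) {
    if (length(new_idx) == 0) return(if (mo) NULL else list())
    key <- if (new_is_row) block$row else block$col
    partner <- if (new_is_row) block$col else block$row
    X <- partner_features[partner_nodes, , drop = FALSE]
    if (mo) {
      # outputs ordered by new_idx; rows ordered by partner_nodes
      Y <- matrix(0L, length(partner_nodes), length(new_idx))
      Y[cbind(match(partner, partner_nodes), match(key, new_idx))] <- block$pred
      p <- params
      p$seed <- seq_seed(base, seed_off)
      train_ensemble(X, Y, p)
    } else {
      models <- vector("list", length(new_idx))
      names(models) <- as.character(new_idx)
      for (i in seq_along(new_idx)) {
        sel <- key == new_idx[i]
        y <- block$pred[sel][match(partner_nodes, partner[sel])]
        p <- params
        p$seed <- seq_seed(base, seed_off + i)
        models[[i]] <- train_ensemble(X, y, p)
      }
      models
    }
  }

  if (model$homogeneous) {
    ts_nodes <- sort(unique(c(ts_rows, ts_cols)))
    ls_nodes <- ls_row_nodes(model)
    out <- list(variant = if (mo) "mo" else "so", homogeneous = TRUE,
                ts_rows = ts_nodes, ts_cols = ts_nodes, rule = rule)
    if (length(ts_nodes)) {
      blk <- step1_block(ts_nodes, ls_nodes, new_is_row = TRUE)
      out$binarized <- list(rows = blk)
      out$row_step2 <- fit_step2(blk, ts_nodes, TRUE, ls_nodes,
                                 net$rows$features, 200000L)
      out$col_step2 <- out$row_step2
    } else {
      out$binarized <- list()
      out$row_step2 <- if (mo) NULL else list()
      out$col_step2 <- out$row_step2
    }
    return(structure(out, class = "two_step_model"))
  }

  ts_rows <- sort(unique(ts_rows))
  ts_cols <- sort(unique(ts_cols))
  ls_rows <- ls_row_nodes(model)
  ls_cols <- ls_col_nodes(model)
  out <- list(variant = if (mo) "mo" else "so", homogeneous = FALSE,
              ts_rows = ts_rows, ts_cols = ts_cols, rule = rule,
              binarized = list())
  if (length(ts_rows)) {
    blk_r <- step1_block(ts_rows, ls_cols, new_is_row = TRUE)
    out$binarized$rows <- blk_r
    out$row_step2 <- fit_step2(blk_r, ts_rows, TRUE, ls_cols,
                               net$cols$features, 200000L)
  } else {
    out$row_step2 <- if (mo) NULL else list()
  }
  if (length(ts_cols)) {
    blk_c <- step1_block(ts_cols, ls_rows, new_is_row = FALSE)
    out$binarized$cols <- blk_c
    out$col_step2 <- fit_step2(blk_c, ts_cols, FALSE, ls_rows,
                               net$rows$features, 300000L)
  } else {
    out$col_step2 <- if (mo) NULL else list()
  }
  structure(out, class = "two_step_model")
}

#' @export
print.two_step_model <- function(x, ...) {
  cat("<two_step_model> variant=", x$variant,
      if (x$homogeneous) " (homogeneous)" else "",
      "; ", length(x$ts_rows), " unseen row node(s), ",
      length(x$ts_cols), " unseen column node(s)\n", sep = "")
  invisible(x)
}

#' Score pairs of two unseen nodes
#'
#' Averages the two second-step predictions: the unseen row node's model
#' applied to the column node's features and vice versa (for a homogeneous
#' network, the two unseen nodes' models applied to each other's features).
#'
#' @param second_step A [two_step_train()] model.
#' @param net The network supplying node features.
#' @param pairs Tibble with `row`, `col` columns; both nodes must be unseen
#'   nodes covered by the second-step models.
#' @return `pairs` with a `score` column appended.
#' @export
predict_tsts_local <- function(second_step, net, pairs) {
  stopifnot(inherits(second_step, "two_step_model"))
  check_pair_indices(net, pairs)
  x <- second_step
  if (!all(pairs$row %in% x$ts_rows) || !all(pairs$col %in% x$ts_cols)) {
    abort("both nodes of each pair must be unseen nodes covered by the second-step models",
          class = "treepairs_validation_error")
  }
  fr <- net$rows$features
  fc <- if (x$homogeneous) fr else net$cols$features
  if (x$variant == "so") {
    c1 <- score_by_key(x$row_step2, pairs$row, pairs$col, fc)
    c2 <- score_by_key(x$col_step2, pairs$col, pairs$row, fr)
  } else {
    c1 <- score_mo(x$row_step2, pairs$col, pairs$row, fc, x$ts_rows)
    c2 <- score_mo(x$col_step2, pairs$row, pairs$col, fr, x$ts_cols)
  }
  dplyr::mutate(pairs, score = unname((c1 + c2) / 2))
}

#' @export
tidy.local_mo_model <- function(x, ...) {
  if (x$homogeneous) {
    dplyr::mutate(feature_importances(x$node_model), side = "node",
                  .before = 1)
  } else {
    dplyr::bind_rows(
      dplyr::mutate(feature_importances(x$model_rows), side = "row",
                    .before = 1),
      dplyr::mutate(feature_importances(x$model_cols), side = "col",
                    .before = 1)
    )
  }
}

#' @export
glance.local_mo_model <- function(x, ...) {
  tibble::tibble(
    variant = "mo",
    homogeneous = x$homogeneous,
    n_models = if (x$homogeneous) 1L else 2L,
    train_prevalence = x$prevalence
  )
}

#' @export
glance.local_so_model <- function(x, ...) {
  tibble::tibble(
    variant = "so",
    homogeneous = x$homogeneous,
    n_models = if (x$homogeneous) length(x$node_models)
               else length(x$row_models) + length(x$col_models),
    train_prevalence = x$prevalence
  )
}
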