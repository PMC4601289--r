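#' Design matrix of concatenated pair features
#'
#' Builds the training matrix of the global approach: the feature vector of a
#' pair is the concatenation of the feature vectors of its two nodes. For a
#' homogeneous network, each unordered pair can contribute both orderings
#' `(a,b)` and `(b,a)` with the same label, so the learnt function gets a
#' chance to be (approximately) symmetric in its arguments.
#'
#' @param net A [network()] object.
#' @param pairs A pair tibble (see [known_pairs()]) with `row`, `col` and
#'   optionally `label` columns.
#' @param duplicate_symmetric Add the swapped ordering of every pair
#'   (homogeneous networks only). Defaults to `net$homogeneous`.
#' @return A list with the design matrix `X` (and labels `y` when `pairs`
#'   carries a `label` column).
#' @export
build_pair_matrix <- function(net, pairs, duplicate_symmetric = net$homogeneous) {
  stopifnot(inherits(net, "pair_network"))
  if (duplicate_symmetric && !net$homogeneous) {
    abort("duplicate_symmetric only applies to homogeneous networks",
          class = "treepairs_validation_error")
  }
  Xr <- net$rows$features
  Xc <- net$cols$features
  X <- cbind(Xr[pairs$row, , drop = FALSE], Xc[pairs$col, , drop = FALSE])
  colnames(X) <- c(paste0("row.", colnames(Xr)), paste0("col.", colnames(Xc)))
  y <- pairs$label
  if (duplicate_symmetric) {
    Xs <- cbind(Xr[pairs$col, , drop = FALSE], Xc[pairs$row, , drop = FALSE])
    colnames(Xs) <- colnames(X)
    X <- rbind(X, Xs)
    y <- c(y, y)
  }
  rownames(X) <- NULL
  list(X = X, y = y)
}

#' Train the global model
#'
#' The global approach fits a single tree ensemble on the learning sample of
#' pairs, over the cartesian product of the two node feature spaces. Any
#' pair, whatever family it falls in, can then be scored by concatenating
#' the two nodes' features.
#'
#' @param net A [network()] object.
#' @param ls Learning sample of pairs ([known_pairs()] or a subset).
#' @param params A [learner_params()].
#' @return An object of class `global_model`.
#' @export
train_global <- function(net, ls, params = learner_params()) {
  stopifnot(inherits(net, "pair_network"), nrow(ls) >= 1)
  d <- build_pair_matrix(net, ls)
  structure(
    list(ensemble = train_ensemble(d$X, d$y, params),
         homogeneous = net$homogeneous,
         p_row = ncol(net$rows$features), p_col = ncol(net$cols$features),
         params = params),
    class = "global_model"
  )
}

#' @export
print.global_model <- function(x, ...) {
  cat("<global_model> ", if (x$homogeneous) "homogeneous" else "bipartite",
      "; input dim ", x$p_row, "+", x$p_col, "\n", sep = "")
  print(x$ensemble)
  invisible(x)
}

# bare numeric scores for row/col index vectors (fast path used by CV)
predict_global_scores <- function(model, net, row, col,
                                  combine = c("mean", "max")) {
  combine <- match.arg(combine)
  Xr <- net$rows$features
  Xc <- net$cols$features
  X <- cbind(Xr[row, , drop = FALSE], Xc[col, , drop = FALSE])
  s <- predict_proba(model$ensemble, X)
  if (model$homogeneous) {
    Xs <- cbind(Xr[col, , drop = FALSE], Xc[row, , drop = FALSE])
    s2 <- predict_proba(model$ensemble, Xs)
    s <- if (combine == "mean") (s + s2) / 2 else pmax(s, s2)
  }
  unname(s)
}

#' Score pairs with a global model
#'
#' For bipartite networks the score of `(r, c)` is the ensemble probability
#' on the concatenated features. For homogeneous networks the probabilities
#' of the two orderings are combined — by arithmetic mean (default), making
#' the prediction exactly swap-invariant, or by maximum.
#'
#' @param model A [train_global()] model.
#' @param net The network supplying node features.
#' @param pairs Tibble with `row` and `col` index columns.
#' @param combine `"mean"` or `"max"` combination of the two orderings
#'   (homogeneous networks).
#' @return `pairs` with a `score` column appended.
#' @export
predict_pairs_global <- function(model, net, pairs, combine = c("mean", "max")) {
  stopifnot(inherits(model, "global_model"))
  check_pair_indices(net, pairs)
  dplyr::mutate(pairs,
                score = predict_global_scores(model, net, pairs$row,
                                              pairs$col, combine))
}

check_pair_indices <- function(net, pairs) {
  if (!all(c("row", "col") %in% names(pairs))) {
    abort("pairs must have `row` and `col` columns",
          class = "treepairs_validation_error")
  }
  if (any(pairs$row < 1 | pairs$row > nrow(net$adjacency)) ||
      any(pairs$col < 1 | pairs$col > ncol(net$adjacency))) {
    abort("pair indices outside the network's node sets",
          class = "treepairs_node_error")
  }
  invisible(TRUE)
}

#' @export
tidy.global_model <- function(x, ...) {
  feature_importances(x$ensemble)
}

#' @export
glance.global_model <- function(x, ...) {
  tibble::tibble(
    n_trees = length(x$ensemble$forest$trees),
    k_used = x$ensemble$k_used,
    input_dim = x$p_row + x$p_col,
    homogeneous = x$homogeneous,
    train_prevalence = unname(x$ensemble$prevalence[1])
  )
}
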