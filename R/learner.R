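#' Parameters for an extra-trees ensemble
#'
#' Bundles the tuning parameters of the extremely randomized tree ensembles
#' used throughout the package. The defaults follow standard practice for
#' this learner: 100 trees, `K = round(sqrt(p))` random split candidates per
#' node, no bootstrap resampling, fully grown trees.
#'
#' @param n_trees Number of trees in the ensemble.
#' @param k_features Number of random split candidates drawn at each node:
#'   either a positive integer or `"sqrt"` (resolved to `round(sqrt(p))`
#'   at fit time, where `p` is the number of columns of the design matrix —
#'   for the global approach that is the concatenated dimension).
#' @param bootstrap Grow each tree on a bootstrap resample of the training
#'   rows. Off by default; recommended when all features are binary, where
#'   random cut-points alone cannot create diversity between trees.
#' @param seed Integer seed for the ensemble's random stream, or `NULL` to
#'   draw one from R's RNG (so `set.seed()` still gives reproducibility).
#' @param min_samples_split Minimum node size that may still be split.
#' @param smoothing Laplace smoothing constant added to leaf class counts;
#'   0 (the default) gives raw leaf class frequencies.
#'
#' @return An object of class `learner_params` (a list).
#' @examples
#' learner_params(n_trees = 50, seed = 1)
#' @export
learner_params <- function(n_trees = 100, k_features = "sqrt",
                           bootstrap = FALSE, seed = NULL,
                           min_samples_split = 2, smoothing = 0) {
  stopifnot(is.numeric(n_trees), length(n_trees) == 1, n_trees >= 1)
  if (!(identical(k_features, "sqrt") ||
        (is.numeric(k_features) && length(k_features) == 1 && k_features >= 1))) {
    rlang::abort("`k_features` must be \"sqrt\" or a positive integer",
                 class = "treepairs_param_error")
  }
  stopifnot(is.logical(bootstrap), length(bootstrap) == 1)
  stopifnot(min_samples_split >= 2, smoothing >= 0)
  structure(
    list(n_trees = as.integer(n_trees), k_features = k_features,
         bootstrap = bootstrap, seed = seed,
         min_samples_split = as.integer(min_samples_split),
         smoothing = smoothing),
    class = "learner_params"
  )
}

#' @export
print.learner_params <- function(x, ...) {
  cat("<learner_params> n_trees=", x$n_trees,
      " k_features=", if (identical(x$k_features, "sqrt")) "sqrt(p)" else x$k_features,
      " bootstrap=", x$bootstrap,
      " min_samples_split=", x$min_samples_split, "\n", sep = "")
  invisible(x)
}

resolve_k <- function(k_features, p) {
  k <- if (identical(k_features, "sqrt")) round(sqrt(p)) else as.integer(k_features)
  max(1L, min(as.integer(k), as.integer(p)))
}

resolve_seed <- function(seed) {
  if (is.null(seed)) sample.int(.Machine$integer.max, 1L) else as.integer(seed)
}

as_design_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1)
  storage.mode(X) <- "double"
  X
}

#' Train an ensemble of extremely randomized trees
#'
#' Fits a single- or multi-output binary classification ensemble. When `Y`
#' is a 0/1 matrix, one ensemble is grown jointly over all outputs: each
#' split is scored by the Gini impurity decrease summed over outputs, so the
#' tree groups samples with similar output profiles.
#'
#' Degenerate inputs are not errors: a single-class `Y` yields a constant
#' model predicting the observed class prevalence.
#'
#' @param X Numeric matrix (or data frame) of training features, one row per
#'   sample.
#' @param Y Binary label vector, or 0/1 matrix with one column per output.
#' @param params A [learner_params()] object.
#' @return An object of class `et_ensemble` with the fitted forest, feature
#'   and output names, and the per-output training prevalence.
#' @examples
#' X <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), ncol = 2)
#' m <- train_ensemble(X, c(1, 1, 0, 0), learner_params(n_trees = 10, seed = 1))
#' predict_proba(m, X)
#' @export
train_ensemble <- function(X, Y, params = learner_params()) {
  stopifnot(inherits(params, "learner_params"))
  X <- as_design_matrix(X)
  y_vec <- is.null(dim(Y))
  Ym <- if (y_vec) matrix(as.numeric(Y), ncol = 1) else {
    Ym <- as.matrix(Y); storage.mode(Ym) <- "double"; Ym
  }
  if (nrow(Ym) != nrow(X)) {
    rlang::abort("X and Y must have the same number of rows",
                 class = "treepairs_shape_error")
  }
  if (anyNA(Ym)) {
    rlang::abort("labels must not contain missing values",
                 class = "treepairs_label_error")
  }
  if (!all(Ym %in% c(0, 1))) {
    rlang::abort("labels must be binary 0/1", class = "treepairs_label_error")
  }
  k <- resolve_k(params$k_features, ncol(X))
  seed <- resolve_seed(params$seed)
  forest <- .et_fit_cpp(X, Ym, params$n_trees, k, params$bootstrap,
                        params$min_samples_split, params$smoothing, seed)
  structure(
    list(forest = forest,
         n_outputs = ncol(Ym),
         vector_output = y_vec,
         feature_names = colnames(X) %||% paste0("f", seq_len(ncol(X))),
         output_names = colnames(Ym),
         prevalence = colMeans(Ym),
         k_used = k, seed_used = seed,
         params = params),
    class = "et_ensemble"
  )
}

#' @export
print.et_ensemble <- function(x, ...) {
  cat("<et_ensemble> ", length(x$forest$trees), " trees, ",
      length(x$feature_names), " features, ", x$n_outputs, " output(s); K=",
      x$k_used, "\n", sep = "")
  invisible(x)
}

#' Predicted class-1 probabilities
#'
#' Returns, for each sample (and output, for multi-output models), the mean
#' over trees of the class-1 frequency of the leaf the sample falls into.
#'
#' @param model A fitted [train_ensemble()] model.
#' @param X Numeric matrix with the same number of columns as at training.
#' @return A numeric vector (single-output models trained on a label vector)
#'   or a matrix with one column per output.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "et_ensemble"))
  X <- as_design_matrix(X)
  if (ncol(X) != length(model$feature_names)) {
    rlang::abort(sprintf("feature count mismatch: model expects %d, got %d",
                         length(model$feature_names), ncol(X)),
                 class = "treepairs_shape_error")
  }
  pr <- .et_predict_cpp(model$forest, X)
  if (model$vector_output) drop(pr[, 1]) else {
    colnames(pr) <- model$output_names
    pr
  }
}

#' Impurity-based feature importances
#'
#' Total Gini impurity decrease contributed by each feature over all splits
#' of all trees, normalized to sum to one. A model that never splits (e.g.
#' constant labels) has an all-zero importance vector.
#'
#' @param model A fitted [train_ensemble()] model.
#' @return A tibble with columns `feature` and `importance`, sorted by
#'   decreasing importance.
#' @export
feature_importances <- function(model) {
  stopifnot(inherits(model, "et_ensemble"))
  raw <- model$forest$importance_raw
  tot <- sum(raw)
  imp <- if (tot > 0) raw / tot else raw
  dplyr::arrange(
    tibble::tibble(feature = model$feature_names, importance = imp),
    dplyr::desc(.data$importance)
  )
}

#' Per-tree leaf assignments
#'
#' Maps each sample to the leaf it reaches in every tree of the ensemble.
#' Leaf ids are node indices within each tree, so two samples share an id in
#' a given tree exactly when they follow the same root-to-leaf test path.
#'
#' @param model A fitted [train_ensemble()] model.
#' @param X Numeric matrix of samples to drop down the trees.
#' @return An integer matrix, samples by trees.
#' @export
leaf_assignments <- function(model, X) {
  stopifnot(inherits(model, "et_ensemble"))
  X <- as_design_matrix(X)
  if (ncol(X) != length(model$feature_names)) {
    rlang::abort(sprintf("feature count mismatch: model expects %d, got %d",
                         length(model$feature_names), ncol(X)),
                 class = "treepairs_shape_error")
  }
  .et_leaf_cpp(model$forest, X)
}

#' Root-to-leaf decision paths of one tree
#'
#' Walks the stored structure of tree `tree` and returns, for each leaf, the
#' conjunction of feature tests that defines it — the textual form of the
#' rectangular region of the adjacency matrix associated with the leaf.
#'
#' @param model A fitted [train_ensemble()] model.
#' @param tree Tree index (1-based).
#' @return A tibble with columns `leaf` (0-based node id), `n_node`, and
#'   `rule` (human-readable conjunction of tests).
#' @export
leaf_rules <- function(model, tree = 1) {
  stopifnot(inherits(model, "et_ensemble"))
  tr <- model$forest$trees[[tree]]
  fn <- model$feature_names
  paths <- list()
  walk <- function(node, conds) {
    f <- tr$feature[node + 1L]
    if (f < 0) {
      paths[[length(paths) + 1L]] <<- tibble::tibble(
        leaf = node, n_node = tr$n_node[node + 1L],
        rule = if (length(conds)) paste(conds, collapse = " & ") else "(root)"
      )
      return(invisible(NULL))
    }
    thr <- signif(tr$threshold[node + 1L], 4)
    walk(tr$left[node + 1L], c(conds, sprintf("%s <= %g", fn[f + 1L], thr)))
    walk(tr$right[node + 1L], c(conds, sprintf("%s > %g", fn[f + 1L], thr)))
  }
  walk(0L, character())
  dplyr::bind_rows(paths)
}
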