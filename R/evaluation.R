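# Four-family evaluation protocol: cross-validation on pairs (LS x LS) and
# on nodes (LS x TS, TS x LS, TS x TS), scored by AUROC and step-wise AUPR,
# against node-degree and random baselines. Skewed networks make AUPR the
# more informative of the two summaries.

#' Area under the ROC curve
#'
#' Computed as the Mann–Whitney statistic
#' `P(score_pos > score_neg) + 0.5 P(tie)` via midranks, so a
#' constant-score ranking is exactly 0.5.
#'
#' @param scores Numeric predicted scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.9, 0.1), c(1, 0))
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    abort("AUROC is undefined when only one class is present",
          class = "treepairs_metric_error")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision–recall curve
#'
#' Step-wise (non-interpolated average-precision) rule: thresholds sweep the
#' distinct score values from high to low and the area accumulates
#' `precision * delta-recall` at each step. Tied scores enter together, so a
#' constant-score ranking scores exactly the positive prevalence — the
#' random baseline for skewed networks. Linear interpolation between PR
#' points is deliberately avoided: it overestimates the area on skewed
#' problems.
#'
#' @param scores Numeric predicted scores.
#' @param labels 0/1 labels; at least one positive required.
#' @return AUPR in `(0, 1]`.
#' @examples
#' aupr(c(0.9, 0.8, 0.7), c(1, 0, 1)) # (1 + 2/3) / 2
#' @export
aupr <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1)
  if (n_pos == 0) {
    abort("AUPR is undefined without positive labels",
          class = "treepairs_metric_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  n_seen <- seq_along(y)
  last <- which(c(s[-1] != s[-length(s)], TRUE)) # end of each tied group
  prec <- tp[last] / n_seen[last]
  rec <- tp[last] / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Degree-baseline scores for test pairs
#'
#' Ranks pairs by node degrees computed from the training pairs only: the
#' degree sum for pairs of two learning-sample nodes, and the LS-side node's
#' degree when the other node is unseen. Pairs of two unseen nodes get `NA`
#' (no degree information exists; random guessing is the baseline there,
#' with AUROC 0.5 and AUPR equal to the positive prevalence).
#'
#' @param train_pairs Training pair tibble (degrees are computed from these
#'   and nothing else).
#' @param net The [network()] object.
#' @param test_pairs Pairs to score.
#' @param ts_rows,ts_cols Indices of unseen row/column nodes (for a
#'   homogeneous network pass the unseen node set as both).
#' @return Numeric scores, `NA` for unseen-unseen pairs.
#' @export
degree_baseline <- function(train_pairs, net, test_pairs,
                            ts_rows = integer(), ts_cols = integer()) {
  dv <- degree_vectors(train_pairs, net)
  r_ls <- !(test_pairs$row %in% ts_rows)
  c_ls <- !(test_pairs$col %in% ts_cols)
  s <- ifelse(r_ls, dv$row[test_pairs$row], 0) +
    ifelse(c_ls, dv$col[test_pairs$col], 0)
  s[!r_ls & !c_ls] <- NA_real_
  unname(s)
}

new_eval_report <- function(metrics, scores, method, scheme, folds, runs,
                            seed) {
  structure(list(metrics = metrics, scores = scores, method = method,
                 scheme = scheme, folds = folds, runs = runs, seed = seed),
            class = "eval_report")
}

# one metrics row for a scored fold; single-class test sets are skipped with
# a warning and recorded (NA metrics, skipped = TRUE)
fold_metrics <- function(family, run, fold, scores, labels, note = NA_character_) {
  n_pos <- sum(labels == 1)
  skipped <- length(labels) == 0 || n_pos == 0 || n_pos == length(labels)
  if (skipped) {
    warning(sprintf("fold %d (run %d, %s): single-class test labels, fold skipped",
                    fold, run, family), call. = FALSE)
    a_roc <- a_pr <- NA_real_
  } else if (!is.na(note) && note == "random") {
    a_roc <- 0.5
    a_pr <- n_pos / length(labels)
  } else {
    a_roc <- auroc(scores, labels)
    a_pr <- aupr(scores, labels)
  }
  tibble::tibble(family = family, run = run, fold = fold,
                 n_test = length(labels), n_pos = n_pos,
                 auroc = a_roc, aupr = a_pr, skipped = skipped, note = note)
}

fold_assignment <- function(n, folds, seed) {
  with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
}

#' Cross-validation on pairs (LS x LS generalization)
#'
#' Randomly partitions the known pairs into `folds` groups (per run), trains
#' on the rest and scores the held-out pairs. All held-out pairs have both
#' nodes represented in the training pairs (up to rare model-less nodes, see
#' the vignette), so this protocol measures LS x LS generalization. Metrics
#' are computed per fold, then averaged over folds and runs.
#'
#' @param net A [network()] object.
#' @param method `"global"`, `"local-so"` or `"baseline"`. The local
#'   multi-output variant is not applicable: it requires a fully observed
#'   training submatrix and so cannot hold out individual pairs.
#' @param params A [learner_params()] for the tree ensembles.
#' @param folds,runs Number of CV folds and independent CV repetitions.
#' @param seed Integer seed; fold assignments and model seeds derive from it
#'   deterministically (per run and fold), so any fold can be re-run in
#'   isolation.
#' @param combine Ordering combination for homogeneous global predictions.
#' @param keep_scores Retain per-pair scores and labels in the report
#'   (needed for pooled PR/ROC curves).
#' @return An `eval_report`; see [tidy.eval_report()] and
#'   [glance.eval_report()].
#' @export
cv_on_pairs <- function(net, method = c("global", "local-so", "baseline"),
                        params = learner_params(), folds = 10, runs = 10,
                        seed = 1, combine = "mean", keep_scores = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(net, "pair_network"))
  pairs <- known_pairs(net)
  if (nrow(pairs) < folds) {
    abort("fewer known pairs than folds", class = "treepairs_validation_error")
  }
  metrics <- list()
  scores_kept <- list()
  for (run in seq_len(runs)) {
    assign <- fold_assignment(nrow(pairs), folds, seq_seed(seed, run * 1009L))
    for (f in seq_len(folds)) {
      train <- pairs[assign != f, , drop = FALSE]
      test <- pairs[assign == f, , drop = FALSE]
      p <- params
      p$seed <- seq_seed(seed, run * 1009L + f)
      s <- switch(method,
        global = predict_global_scores(train_global(net, train, p), net,
                                       test$row, test$col, combine),
        `local-so` = predict_local_any(train_local_so(net, train, p), net,
                                       test)$score,
        baseline = degree_baseline(train, net, test)
      )
      metrics[[length(metrics) + 1L]] <- fold_metrics("LSxLS", run, f, s,
                                                      test$label)
      if (keep_scores) {
        scores_kept[[length(scores_kept) + 1L]] <- tibble::tibble(
          family = "LSxLS", run = run, fold = f, row = test$row,
          col = test$col, score = s, label = test$label)
      }
    }
  }
  new_eval_report(dplyr::bind_rows(metrics),
                  if (keep_scores) dplyr::bind_rows(scores_kept) else NULL,
                  method, "pairs", folds, runs, seed)
}

#' Cross-validation on nodes (LS x TS, TS x LS, TS x TS generalization)
#'
#' Per run, the row and column node sets are independently partitioned into
#' `folds` groups; fold `i` holds out row-group `i` and column-group `i`
#' jointly. Models are trained on the known pairs between the remaining
#' nodes and scored separately on the three test families (two for
#' homogeneous networks, where LS x TS and TS x LS coincide).
#'
#' Unseen-unseen pairs are scored by the two-step procedure for the local
#' methods, directly for the global model, and by random guessing for the
#' baseline (AUROC 0.5, AUPR = prevalence).
#'
#' @inheritParams cv_on_pairs
#' @param method `"global"`, `"local-so"`, `"local-mo"` or `"baseline"`.
#' @return An `eval_report`.
#' @export
cv_on_nodes <- function(net, method = c("global", "local-so", "local-mo",
                                        "baseline"),
                        params = learner_params(), folds = 10, runs = 10,
                        seed = 1, combine = "mean", keep_scores = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(net, "pair_network"))
  pairs <- known_pairs(net)
  nr <- nrow(net$adjacency)
  nc <- ncol(net$adjacency)
  if (nr < folds || (!net$homogeneous && nc < folds)) {
    abort("fewer nodes than folds", class = "treepairs_validation_error")
  }
  metrics <- list()
  scores_kept <- list()

  keep <- function(family, run, fold, test, s) {
    metrics[[length(metrics) + 1L]] <<- fold_metrics(
      family, run, fold, s, test$label,
      note = if (is.null(s)) "random" else NA_character_)
    if (keep_scores && !is.null(s)) {
      scores_kept[[length(scores_kept) + 1L]] <<- tibble::tibble(
        family = family, run = run, fold = fold, row = test$row,
        col = test$col, score = s, label = test$label)
    }
  }

  for (run in seq_len(runs)) {
    row_assign <- fold_assignment(nr, folds, seq_seed(seed, run * 2003L))
    col_assign <- if (net$homogeneous) row_assign else
      fold_assignment(nc, folds, seq_seed(seed, run * 2003L + 1L))
    for (f in seq_len(folds)) {
      ts_r <- which(row_assign == f)
      ts_c <- which(col_assign == f)
      in_ts_r <- pairs$row %in% ts_r
      in_ts_c <- pairs$col %in% ts_c
      if (net$homogeneous) {
        # for unordered pairs, membership counts how many ends are unseen
        n_unseen <- (pairs$row %in% ts_r) + (pairs$col %in% ts_r)
        train <- pairs[n_unseen == 0, , drop = FALSE]
        fam <- list(LSxTS = pairs[n_unseen == 1, , drop = FALSE],
                    TSxTS = pairs[n_unseen == 2, , drop = FALSE])
      } else {
        train <- pairs[!in_ts_r & !in_ts_c, , drop = FALSE]
        fam <- list(LSxTS = pairs[!in_ts_r & in_ts_c, , drop = FALSE],
                    TSxLS = pairs[in_ts_r & !in_ts_c, , drop = FALSE],
                    TSxTS = pairs[in_ts_r & in_ts_c, , drop = FALSE])
      }
      p <- params
      p$seed <- seq_seed(seed, run * 2003L + 2L * f)

      if (method == "global") {
        m <- train_global(net, train, p)
        for (fm in names(fam)) {
          keep(fm, run, f, fam[[fm]],
               predict_global_scores(m, net, fam[[fm]]$row, fam[[fm]]$col,
                                     combine))
        }
      } else if (method %in% c("local-so", "local-mo")) {
        m <- if (method == "local-so") train_local_so(net, train, p)
             else train_local_mo(net, train, p)
        for (fm in setdiff(names(fam), "TSxTS")) {
          keep(fm, run, f, fam[[fm]],
               predict_lsts_local(m, net, fam[[fm]])$score)
        }
        ts2 <- two_step_train(m, net, ts_r, if (net$homogeneous) integer()
                              else ts_c)
        keep("TSxTS", run, f, fam$TSxTS,
             predict_tsts_local(ts2, net, fam$TSxTS)$score)
      } else { # baseline
        for (fm in setdiff(names(fam), "TSxTS")) {
          keep(fm, run, f, fam[[fm]],
               degree_baseline(train, net, fam[[fm]], ts_r,
                               if (net$homogeneous) ts_r else ts_c))
        }
        keep("TSxTS", run, f, fam$TSxTS, NULL) # random guessing
      }
    }
  }
  new_eval_report(dplyr::bind_rows(metrics),
                  if (keep_scores) dplyr::bind_rows(scores_kept) else NULL,
                  method, "nodes", folds, runs, seed)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> method=", x$method, ", CV on ", x$scheme, ", ",
      x$runs, " run(s) x ", x$folds, " fold(s), seed ", x$seed, "\n",
      sep = "")
  print(glance(x))
  invisible(x)
}

#' Per-fold metrics of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble with one row per (family, run, fold): `n_test`, `n_pos`,
#'   `auroc`, `aupr`, and skip bookkeeping.
#' @export
tidy.eval_report <- function(x, ...) x$metrics

#' Per-family summary of an evaluation report
#'
#' Averages AUROC and AUPR over folds and runs, the protocol's headline
#' numbers.
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble with one row per family.
#' @export
glance.eval_report <- function(x, ...) {
  x$metrics |>
    dplyr::filter(!.data$skipped) |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(aupr = mean(.data$aupr), auroc = mean(.data$auroc),
                     n_folds = dplyr::n(),
                     mean_prevalence = mean(.data$n_pos / .data$n_test),
                     .groups = "drop") |>
    dplyr::mutate(method = x$method, scheme = x$scheme, .before = 1)
}

#' Pooled precision–recall and ROC curve points
#'
#' Pools the retained per-pair scores of a report (run with
#' `keep_scores = TRUE`) across folds and runs and computes curve points per
#' family. Pooled curves are for plotting; reported areas always come from
#' per-fold computation.
#'
#' @param report An `eval_report` with retained scores.
#' @return Tibble with columns `family`, `curve` (`"pr"`/`"roc"`), `x`, `y`.
#' @export
curve_points <- function(report) {
  stopifnot(inherits(report, "eval_report"))
  if (is.null(report$scores)) {
    abort("report has no retained scores; rerun with keep_scores = TRUE",
          class = "treepairs_validation_error")
  }
  report$scores |>
    dplyr::group_by(.data$family) |>
    dplyr::group_modify(function(d, key) {
      ord <- order(d$score, decreasing = TRUE)
      y <- d$label[ord]
      s <- d$score[ord]
      tp <- cumsum(y)
      fp <- cumsum(1 - y)
      last <- which(c(s[-1] != s[-length(s)], TRUE))
      n_pos <- sum(y)
      n_neg <- length(y) - n_pos
      dplyr::bind_rows(
        tibble::tibble(curve = "pr", x = tp[last] / n_pos,
                       y = tp[last] / (tp[last] + fp[last])),
        tibble::tibble(curve = "roc", x = c(0, fp[last] / n_neg),
                       y = c(0, tp[last] / n_pos))
      )
    }) |>
    dplyr::ungroup()
}

#' Plot an evaluation report
#'
#' With retained scores, draws pooled PR and ROC curves per family;
#' otherwise, per-fold AUPR/AUROC distributions as boxplots.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  if (!is.null(object$scores)) {
    pts <- curve_points(object)
    ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y,
                                      colour = .data$family)) +
      ggplot2::geom_step() +
      ggplot2::facet_wrap(~ .data$curve, scales = "free",
                          labeller = ggplot2::as_labeller(
                            c(pr = "precision-recall", roc = "ROC"))) +
      ggplot2::labs(x = "recall / FPR", y = "precision / TPR",
                    title = sprintf("%s, CV on %s", object$method,
                                    object$scheme)) +
      ggplot2::theme_bw()
  } else {
    long <- tidyr::pivot_longer(
      dplyr::filter(object$metrics, !.data$skipped),
      c("aupr", "auroc"), names_to = "metric", values_to = "value")
    ggplot2::ggplot(long, ggplot2::aes(.data$family, .data$value)) +
      ggplot2::geom_boxplot() +
      ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
      ggplot2::labs(x = NULL, y = NULL,
                    title = sprintf("%s, CV on %s", object$method,
                                    object$scheme)) +
      ggplot2::theme_bw()
  }
}
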