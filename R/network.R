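#' Node set with feature descriptions
#'
#' A node set couples an ordered vector of unique node identifiers with a
#' numeric feature matrix (one row per node). Features arrive precomputed —
#' expression profiles, phylogenetic profiles, presence/absence of domains or
#' substructures, etc.; the package does no feature construction.
#'
#' @param ids Character vector of unique node identifiers.
#' @param features Numeric matrix or data frame, `length(ids)` rows.
#' @return An object of class `node_set`.
#' @export
node_set <- function(ids, features) {
  ids <- trimws(as.character(ids))
  if (anyDuplicated(ids)) {
    abort("node ids must be unique", class = "treepairs_node_error")
  }
  features <- as_design_matrix(features)
  if (nrow(features) != length(ids)) {
    abort("feature matrix must have one row per node id",
          class = "treepairs_node_error")
  }
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  all_na <- apply(features, 2, function(v) all(is.na(v)))
  if (any(all_na)) {
    abort(paste0("feature column(s) entirely missing: ",
                 paste(colnames(features)[all_na], collapse = ", ")),
          class = "treepairs_node_error")
  }
  rownames(features) <- ids
  structure(list(ids = ids, features = features,
                 feature_names = colnames(features)),
            class = "node_set")
}

#' @export
print.node_set <- function(x, ...) {
  cat("<node_set> ", length(x$ids), " nodes x ", ncol(x$features),
      " features\n", sep = "")
  invisible(x)
}

#' Partially observed interaction network
#'
#' Couples a 0/1/NA adjacency matrix with the feature descriptions of its row
#' and column nodes. `NA` entries are the unknown pairs to be predicted.
#' Homogeneous (single node family, undirected) networks use the same
#' `node_set` for rows and columns and must have a symmetric pattern of known
#' entries; bipartite networks (e.g. TF–gene, drug–protein) have two node
#' families with possibly different feature spaces.
#'
#' @param adjacency Numeric matrix with entries in `{0, 1, NA}`; row and
#'   column names must match the node-set ids (order-insensitively).
#' @param rows A [node_set()] describing the row nodes.
#' @param cols A [node_set()] for the column nodes, or `NULL` for a
#'   homogeneous network.
#' @return An object of class `pair_network`.
#' @export
network <- function(adjacency, rows, cols = NULL) {
  homogeneous <- is.null(cols)
  if (homogeneous) cols <- rows
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  bad <- !(adjacency %in% c(0, 1, NA))
  if (any(bad)) {
    abort(sprintf("adjacency entries must be 0, 1 or NA (found %s)",
                  paste(unique(adjacency[bad]), collapse = ", ")),
          class = "treepairs_parse_error")
  }
  if (!is.null(rownames(adjacency))) {
    adjacency <- align_adjacency(adjacency, rows$ids, cols$ids)
  }
  if (nrow(adjacency) != length(rows$ids) || ncol(adjacency) != length(cols$ids)) {
    abort("adjacency dimensions must match the node sets",
          class = "treepairs_validation_error")
  }
  dimnames(adjacency) <- list(rows$ids, cols$ids)
  if (homogeneous) {
    both <- !is.na(adjacency) & !is.na(t(adjacency))
    if (any(adjacency[both] != t(adjacency)[both])) {
      abort("homogeneous adjacency must be symmetric wherever both (i,j) and (j,i) are known",
            class = "treepairs_validation_error")
    }
  }
  structure(list(rows = rows, cols = cols, adjacency = adjacency,
                 homogeneous = homogeneous),
            class = "pair_network")
}

align_adjacency <- function(adjacency, row_ids, col_ids) {
  r <- trimws(rownames(adjacency))
  c <- trimws(colnames(adjacency))
  if (!setequal(r, row_ids) || anyDuplicated(r)) {
    abort("adjacency row ids do not match the row feature table",
          class = "treepairs_node_error")
  }
  if (!setequal(c, col_ids) || anyDuplicated(c)) {
    abort("adjacency column ids do not match the column feature table",
          class = "treepairs_node_error")
  }
  adjacency[match(row_ids, r), match(col_ids, c), drop = FALSE]
}

#' @export
print.pair_network <- function(x, ...) {
  known <- sum(!is.na(x$adjacency))
  cat("<pair_network> ", if (x$homogeneous) "homogeneous" else "bipartite",
      ", ", nrow(x$adjacency), " x ", ncol(x$adjacency), " adjacency; ",
      known, " known entries (", sum(x$adjacency == 1, na.rm = TRUE),
      " edges)\n", sep = "")
  invisible(x)
}

read_feature_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        name_repair = "minimal")
  ids <- as.character(df[[1]])
  features <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(features)) {
    abort(sprintf("non-numeric feature cells in %s", path),
          class = "treepairs_parse_error")
  }
  node_set(ids, features)
}

#' Read a network from tab-separated files
#'
#' The adjacency file is a TSV whose first row holds the column-node ids and
#' first column the row-node ids, with cells 0, 1 or NA (unknown). Feature
#' tables are TSVs with node ids in the first column and feature names in the
#' header. Ids are matched exactly after whitespace trimming; the adjacency
#' is re-ordered to the feature tables' node order. Omitting
#' `col_features_path` declares the network homogeneous.
#'
#' @param adjacency_path,row_features_path,col_features_path File paths;
#'   `col_features_path = NULL` for a homogeneous network.
#' @return A [network()] object.
#' @export
read_network <- function(adjacency_path, row_features_path,
                         col_features_path = NULL) {
  adj_df <- readr::read_tsv(adjacency_path, show_col_types = FALSE,
                            progress = FALSE, name_repair = "minimal",
                            na = c("NA", ""))
  adj <- as.matrix(adj_df[, -1, drop = FALSE])
  if (!is.numeric(adj)) {
    abort(sprintf("adjacency cells must be 0, 1 or NA in %s", adjacency_path),
          class = "treepairs_parse_error")
  }
  rownames(adj) <- as.character(adj_df[[1]])
  rows <- read_feature_table(row_features_path)
  cols <- if (is.null(col_features_path)) NULL else read_feature_table(col_features_path)
  network(adj, rows, cols)
}

#' Write a network to tab-separated files
#'
#' Inverse of [read_network()]: writes `adjacency.tsv`, `row_features.tsv`
#' and (bipartite only) `col_features.tsv` under `dir`.
#'
#' @param net A [network()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, dir) {
  stopifnot(inherits(net, "pair_network"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tbl <- function(m, path) {
    df <- dplyr::bind_cols(tibble::tibble(id = rownames(m)),
                           tibble::as_tibble(as.data.frame(m)))
    readr::write_tsv(df, path, na = "NA", progress = FALSE)
    path
  }
  paths <- c(
    write_tbl(net$adjacency, file.path(dir, "adjacency.tsv")),
    write_tbl(net$rows$features, file.path(dir, "row_features.tsv"))
  )
  if (!net$homogeneous) {
    paths <- c(paths, write_tbl(net$cols$features,
                                file.path(dir, "col_features.tsv")))
  }
  invisible(paths)
}

#' Enumerate the learning sample of known pairs
#'
#' Returns every known adjacency entry as a labeled pair — the learning
#' sample of pairs from which all models are trained. For homogeneous
#' networks only unordered pairs with `row < col` are enumerated and the
#' diagonal (self-interaction) is excluded.
#'
#' @param net A [network()] object.
#' @return A tibble with columns `row`, `col` (1-based indices), `row_id`,
#'   `col_id`, and `label` (0/1).
#' @export
known_pairs <- function(net) {
  stopifnot(inherits(net, "pair_network"))
  known <- !is.na(net$adjacency)
  if (net$homogeneous) known <- known & upper.tri(known)
  idx <- which(known, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  tibble::tibble(
    row = as.integer(idx[, 1]),
    col = as.integer(idx[, 2]),
    row_id = net$rows$ids[idx[, 1]],
    col_id = net$cols$ids[idx[, 2]],
    label = as.integer(net$adjacency[idx])
  )
}

#' Node degrees within a pair sample
#'
#' The degree of a node is the number of positive (label 1) pairs of the
#' sample it appears in; nodes absent from the sample have degree 0. Degrees
#' drive the non-trivial baseline: high-degree nodes have a higher chance of
#' being connected to any new node.
#'
#' @param pairs A pair tibble as returned by [known_pairs()].
#' @param net The [network()] the pairs refer to.
#' @return A tibble with columns `side` (`"row"`/`"col"`, or `"node"` for a
#'   homogeneous network where both sides refer to the same family),
#'   `node` (index), `id`, `degree`.
#' @export
node_degrees <- function(pairs, net) {
  stopifnot(inherits(net, "pair_network"))
  pos <- pairs[pairs$label == 1, , drop = FALSE]
  if (net$homogeneous) {
    deg <- tabulate(c(pos$row, pos$col), nbins = length(net$rows$ids))
    return(tibble::tibble(side = "node", node = seq_along(deg),
                          id = net$rows$ids, degree = deg))
  }
  dr <- tabulate(pos$row, nbins = length(net$rows$ids))
  dc <- tabulate(pos$col, nbins = length(net$cols$ids))
  dplyr::bind_rows(
    tibble::tibble(side = "row", node = seq_along(dr), id = net$rows$ids,
                   degree = dr),
    tibble::tibble(side = "col", node = seq_along(dc), id = net$cols$ids,
                   degree = dc)
  )
}

# degree lookup vectors used internally by the baseline
degree_vectors <- function(pairs, net) {
  d <- node_degrees(pairs, net)
  if (net$homogeneous) {
    v <- d$degree
    list(row = v, col = v)
  } else {
    list(row = d$degree[d$side == "row"], col = d$degree[d$side == "col"])
  }
}
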