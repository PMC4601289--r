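# Programmatic fixtures shared across the test files.

# tiny bipartite network with hand-set adjacency and features
tiny_bipartite <- function() {
  adj <- matrix(c(0, 1, NA,
                  1, 0, 1), nrow = 2, byrow = TRUE,
                dimnames = list(c("r1", "r2"), c("c1", "c2", "c3")))
  rows <- node_set(c("r1", "r2"), matrix(c(1, 0, 0, 1), 2, 2,
                                         dimnames = list(NULL, c("a", "b"))))
  cols <- node_set(c("c1", "c2", "c3"),
                   matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE,
                          dimnames = list(NULL, c("u", "v", "w"))))
  network(adj, rows, cols)
}

# homogeneous 4-node network, fully known, zero diagonal
tiny_homogeneous <- function() {
  adj <- matrix(0, 4, 4, dimnames = list(paste0("n", 1:4), paste0("n", 1:4)))
  adj["n1", "n2"] <- adj["n2", "n1"] <- 1
  adj["n2", "n3"] <- adj["n3", "n2"] <- 1
  rows <- node_set(paste0("n", 1:4),
                   matrix(c(1, 0, 0, 1, 1, 1, 0, 0), 4, 2,
                          dimnames = list(NULL, c("a", "b"))))
  network(adj, rows)
}

# noiseless deterministic bipartite network: 4 row groups connect to exactly
# one of 4 equally sized column groups, so every row has edge fraction 1/4
# and the adjacency is a deterministic function of the (pure one-hot)
# features
noiseless_net <- function(n_rows = 48, n_cols = 40, seed = 42) {
  generate_network(synth_config(
    n_rows = n_rows, n_cols = n_cols, p_rows = 4, p_cols = 4,
    k_row_groups = 4, k_col_groups = 4,
    block_density = diag(4), feature_noise_sd = 0, label_flip_prob = 0,
    degree_skew = 0, balanced_groups = TRUE, seed = seed))
}

# moderate bipartite fixture with clear feature signal
signal_net <- function(seed = 5) {
  generate_network(synth_config(
    n_rows = 40, n_cols = 30, p_rows = 12, p_cols = 12,
    k_row_groups = 4, k_col_groups = 4,
    block_density = block_pattern(4, 4, 0.25, 0.9),
    feature_noise_sd = 0.1, label_flip_prob = 0, degree_skew = 0,
    seed = seed))
}

# homogeneous counterpart
signal_net_homog <- function(seed = 9, n = 40) {
  generate_network(synth_config(
    n_rows = n, n_cols = n, p_rows = 12, p_cols = 12,
    k_row_groups = 4, k_col_groups = 4,
    block_density = block_pattern(4, 4, 0.2, 0.9),
    feature_noise_sd = 0.1, label_flip_prob = 0, degree_skew = 0,
    homogeneous = TRUE, seed = seed))
}

fast_params <- function(n_trees = 25, seed = 1, ...) {
  learner_params(n_trees = n_trees, seed = seed, ...)
}

# independent AUROC oracle: exhaustive pairwise comparison
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# independent AUPR oracle: explicit precision/recall table over thresholds
aupr_oracle <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  area <- 0
  prev_rec <- 0
  for (t in thr) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / n_pos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}
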