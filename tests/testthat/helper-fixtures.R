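# Shared fixture builders for the test suite. Everything is generated in
# code at test time; no stored data files.

# A small random feature graph over p nodes.
random_graph <- function(p, n_edges, directed = FALSE) {
  edges <- cbind(sample.int(p, n_edges, replace = TRUE),
                 sample.int(p, n_edges, replace = TRUE))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  feature_graph(paste0("f", seq_len(p)), edges, directed = directed)
}

# A linearly separable two-feature toy classification set.
separable_toy <- function(n = 200, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * 2), n, 2)
  y <- as.integer(x[, 1] + x[, 2] > 0)
  x <- x + matrix(rnorm(n * 2, sd = 0.05), n, 2)
  colnames(x) <- c("f1", "f2")
  list(x = x, y = y)
}

# Small simulated dataset + stratified split, for model-level tests.
toy_sim <- function(p = 40, n = 300, pt = 0.2, seed = 1) {
  ds <- simulate_dataset(simulation_config(p = p, pt = pt, n = n, seed = seed))
  sp <- stratified_split(ds$data$y, 0.8, seed = seed)
  list(sim = ds, train = ds$data[sp$train], test = ds$data[sp$test])
}

# Fast training settings for unit tests (the defaults are benchmark-scale).
fast_config <- function(seed = 1, epochs = 8L, learning_rate = 5e-3, ...) {
  training_config(learning_rate = learning_rate, epochs = epochs,
                  seed = seed, ...)
}

# Independent ROC-AUC oracle: enumerate every threshold and integrate the
# ROC curve with the trapezoidal rule.
roc_auc_enumeration <- function(y, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[y == 1] >= t), 0), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[y == 0] >= t), 0), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Brute-force traversal oracle for the per-tree directed feature graph.
tree_edges_oracle <- function(tree) {
  e <- matrix(integer(0), ncol = 2)
  for (i in which(!tree$is_leaf)) {
    for (ch in c(tree$left_child[i], tree$right_child[i])) {
      if (!tree$is_leaf[ch] && tree$split_feature[i] != tree$split_feature[ch]) {
        e <- rbind(e, c(tree$split_feature[i], tree$split_feature[ch]))
      }
    }
  }
  unique(e)
}
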