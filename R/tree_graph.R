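#' Tree-ensemble configuration
#'
#' Settings for the tree ensemble from which the generated (directed)
#' feature graph is extracted. The default number of trees scales with the
#' feature count as `0.2 * p` (see [default_n_trees()]); boosted ensembles
#' use a binary logistic objective with max depth 6, learning rate 0.3 and
#' L2 regularization 1.
#'
#' @param n_trees number of trees; `NULL` derives it from the feature count.
#' @param kind `"boosted"` (gradient-boosted trees) or `"random_forest"`.
#' @param max_depth,learning_rate,lambda boosted-tree hyperparameters
#'   (ignored for random forests).
#' @return list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_trees = NULL, kind = c("boosted", "random_forest"),
                            max_depth = 6L, learning_rate = 0.3, lambda = 1) {
  kind <- match.arg(kind)
  if (!is.null(n_trees) && n_trees < 1L) stop("n_trees must be >= 1")
  structure(list(n_trees = n_trees, kind = kind,
                 max_depth = as.integer(max_depth),
                 learning_rate = learning_rate, lambda = lambda),
            class = "ensemble_config")
}

round_half_up <- function(x) floor(x + 0.5)

#' Default ensemble size
#'
#' The number of trees is set proportional to the feature count,
#' `0.2 * p`, rounded half-up and floored at 1.
#'
#' @param p number of features (>= 1).
#' @return positive integer.
#' @examples
#' default_n_trees(250) # 50
#' @export
default_n_trees <- function(p) {
  if (p < 1) stop("p must be >= 1")
  max(1L, as.integer(round_half_up(0.2 * p)))
}

#' Fit a tree ensemble and parse its tree structures
#'
#' Fits either a gradient-boosted ensemble (binary logistic objective) or a
#' random forest on a binary-labelled training matrix and returns the parsed
#' structure of every tree: for each node, whether it is a leaf, the split
#' feature index (1-based) and the child node ids. Single-threaded and
#' seeded, so structures are reproducible.
#'
#' @param x numeric training matrix (n x p) or an [expression_dataset()].
#' @param y binary labels (ignored when `x` is a dataset).
#' @param config an [ensemble_config()].
#' @param seed integer seed.
#' @return list of class `fitted_ensemble` with `trees` (list of per-tree
#'   node data frames), `model` (the underlying fit), `kind`, `n_features`.
#' @export
fit_ensemble <- function(x, y = NULL, config = ensemble_config(), seed = 1L) {
  if (inherits(x, "expression_dataset")) {
    y <- x$y
    x <- x$x
  }
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  p <- ncol(x)
  n_trees <- config$n_trees %||% default_n_trees(p)
  colnames(x) <- colnames(x) %||% paste0("f", seq_len(p))
  set.seed(seed)
  if (config$kind == "boosted") {
    model <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = config$max_depth,
                    eta = config$learning_rate, lambda = config$lambda,
                    nthread = 1L),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
      nrounds = n_trees, verbose = 0
    )
    trees <- parse_xgb_trees(model, colnames(x), n_trees)
  } else {
    model <- randomForest::randomForest(x, factor(y), ntree = n_trees)
    trees <- lapply(seq_len(n_trees), function(k) {
      parse_rf_tree(randomForest::getTree(model, k, labelVar = FALSE))
    })
  }
  structure(list(trees = trees, model = model, kind = config$kind,
                 n_features = p, feature_names = colnames(x)),
            class = "fitted_ensemble")
}

# xgboost dump -> list of node tables (1-based node ids within each tree).
parse_xgb_trees <- function(model, feature_names, n_trees) {
  dt <- xgboost::xgb.model.dt.tree(model = model)
  dt <- as.data.frame(dt)
  lapply(seq_len(n_trees) - 1L, function(tr) {
    nd <- dt[dt$Tree == tr, , drop = FALSE]
    if (!nrow(nd)) {
      return(data.frame(node_id = 1L, is_leaf = TRUE, split_feature = NA_integer_,
                        left_child = NA_integer_, right_child = NA_integer_))
    }
    id_map <- stats::setNames(seq_len(nrow(nd)), nd$ID)
    is_leaf <- nd$Feature == "Leaf"
    feat <- match(nd$Feature, feature_names)
    data.frame(
      node_id = seq_len(nrow(nd)),
      is_leaf = is_leaf,
      split_feature = ifelse(is_leaf, NA_integer_, feat),
      left_child = ifelse(is_leaf, NA_integer_,
                          unname(id_map[as.character(nd$Yes)])),
      right_child = ifelse(is_leaf, NA_integer_,
                           unname(id_map[as.character(nd$No)]))
    )
  })
}

# randomForest::getTree matrix -> node table.
parse_rf_tree <- function(tr) {
  is_leaf <- tr[, "status"] == -1
  data.frame(
    node_id = seq_len(nrow(tr)),
    is_leaf = is_leaf,
    split_feature = ifelse(is_leaf, NA_integer_, tr[, "split var"]),
    left_child = ifelse(is_leaf, NA_integer_, tr[, "left daughter"]),
    right_child = ifelse(is_leaf, NA_integer_, tr[, "right daughter"])
  )
}

#' Extract the directed feature graph of a single decision tree
#'
#' Each tree induces a directed graph on the features it splits on: for
#' every internal node splitting on feature `f` whose child is itself an
#' internal node splitting on `f2`, a directed edge `f -> f2` reflects the
#' hierarchical splitting order. Self-pairs (parent and child splitting on
#' the same feature) are dropped here; self-loops enter globally through
#' [add_self_loops()] on the aggregated graph. Leaves contribute nothing,
#' and repeated parent/child pairs collapse to one edge.
#'
#' @param tree a per-tree node data frame from [fit_ensemble()].
#' @param node_labels the full feature label space (length p); the returned
#'   graph is embedded in it, so unselected features are isolated nodes.
#' @return A directed [feature_graph()] over all p features.
#' @export
extract_tree_graph <- function(tree, node_labels) {
  p <- length(node_labels)
  internal <- which(!tree$is_leaf)
  if (any(tree$split_feature[internal] > p)) {
    stop("split feature index exceeds the feature space")
  }
  edges <- matrix(integer(0), ncol = 2L)
  for (i in internal) {
    f <- tree$split_feature[i]
    for (ch in c(tree$left_child[i], tree$right_child[i])) {
      if (!is.na(ch) && !tree$is_leaf[ch]) {
        edges <- rbind(edges, c(f, tree$split_feature[ch]))
      }
    }
  }
  feature_graph(node_labels, edges, directed = TRUE)
}

#' Build the generated feature graph from a tree ensemble
#'
#' Fits the ensemble on the training data and merges the per-tree directed
#' graphs into one aggregated graph over the full feature space (edge set is
#' the union across trees; features never split on remain isolated nodes).
#' The self-loop augmentation of its adjacency happens where the graph is
#' used as a network mask.
#'
#' @inheritParams fit_ensemble
#' @return A directed [feature_graph()]; the fitted ensemble is attached as
#'   attribute `"ensemble"` for reuse (e.g. tree-baseline predictions).
#' @export
build_generated_graph <- function(x, y = NULL, config = ensemble_config(),
                                  seed = 1L) {
  ens <- fit_ensemble(x, y, config, seed)
  g <- union_graphs(lapply(ens$trees, extract_tree_graph,
                           node_labels = ens$feature_names))
  attr(g, "ensemble") <- ens
  g
}
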