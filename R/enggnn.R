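#' Fit a dual-graph neural network classifier
#'
#' `enggnn()` trains the dual-graph model: two graph-embedded deep
#' feedforward network (GEDFN) branches whose first layers are masked by,
#' respectively, the self-loop-augmented adjacency of an external undirected
#' feature graph and of a directed feature graph extracted from a
#' gradient-boosted tree ensemble fitted to the same training data. The two
#' 16-wide branch embeddings are concatenated and passed through a
#' feedforward fusion head (one hidden layer of width 16) with a 2-class
#' softmax output. All components are trained jointly end to end under the
#' categorical cross-entropy loss with Adam, mini-batches, dropout on the
#' fully connected hidden layers, and early stopping with best-weight
#' restoration.
#'
#' Features are z-score normalized using statistics of the supplied
#' (training) rows; the statistics are stored in the model and re-applied by
#' [predict.enggnn()]. The generated graph is likewise built from the
#' training rows only, so no test information leaks into the model.
#'
#' @param x training matrix (n x p) or an [expression_dataset()].
#' @param y binary 0/1 labels (ignored when `x` is a dataset).
#' @param graph the external undirected [feature_graph()] over the same
#'   features (positionally aligned; labels checked when both sides carry
#'   names).
#' @param config a [training_config()].
#' @param tree_config an [ensemble_config()] for the generated graph.
#' @param hidden widths of the fully connected branch layers after the
#'   masked layer (the masked layer itself always has width p).
#' @return An object of class `enggnn` with components `net`, `graph_e`,
#'   `graph_g`, `masks`, `norm` (center/scale), `trace` (monitored loss per
#'   epoch), `config`, `feature_names`.
#' @seealso [predict.enggnn()], [importance()], [gedfn()], [fit_baseline()]
#' @export
enggnn <- function(x, y = NULL, graph, config = training_config(),
                   tree_config = ensemble_config(), hidden = c(64L, 16L)) {
  d <- prepare_training_data(x, y, graph)
  set.seed(config$seed)
  gg <- build_generated_graph(d$x, d$y, tree_config, seed = config$seed)
  attr(gg, "ensemble") <- NULL
  mask_e <- add_self_loops(to_adjacency(d$graph))
  mask_g <- add_self_loops(to_adjacency(gg))
  p <- ncol(d$x)
  net <- list(
    type = "dual",
    e = branch_stack(p, hidden, mask_e, config$dropout_rate),
    g = branch_stack(p, hidden, mask_g, config$dropout_rate),
    head = list(new_layer(2L * hidden[length(hidden)], 16L,
                          dropout = config$dropout_rate),
                new_layer(16L, 2L, act = "linear"))
  )
  fit <- train_network(net, d$x, d$y, config)
  structure(list(net = fit$net, graph_e = d$graph, graph_g = gg,
                 masks = list(e = mask_e, g = mask_g),
                 norm = d$norm, trace = fit$trace,
                 best_loss = fit$best_loss, monitored = fit$monitored,
                 config = config, tree_config = tree_config,
                 feature_names = d$feature_names, n_train = nrow(d$x),
                 call = match.call()),
            class = "enggnn")
}

branch_stack <- function(p, hidden, mask, dropout) {
  widths <- c(p, hidden)
  stack <- vector("list", length(widths))
  stack[[1L]] <- new_layer(p, p, mask = mask)
  for (k in seq_along(hidden)) {
    stack[[k + 1L]] <- new_layer(widths[k], widths[k + 1L], dropout = dropout)
  }
  stack
}

prepare_training_data <- function(x, y, graph = NULL) {
  if (inherits(x, "expression_dataset")) {
    y <- x$y
    feature_names <- x$feature_names
    x <- x$x
  } else {
    x <- as.matrix(x)
    feature_names <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  }
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("training labels must contain both classes")
  if (!is.null(graph)) {
    if (!inherits(graph, "feature_graph")) stop("graph must be a feature_graph")
    if (n_nodes(graph) != ncol(x)) {
      stop("graph has ", n_nodes(graph), " nodes but data has ",
           ncol(x), " features")
    }
    if (!is.null(colnames(x)) &&
        !identical(graph$node_labels, colnames(x))) {
      stop("graph node labels do not align with data feature names")
    }
  }
  nz <- zscore_normalize(x)
  list(x = nz$x, y = y, graph = graph, feature_names = feature_names,
       norm = list(center = nz$center, scale = nz$scale))
}

#' Fit a single-graph or graph-free feedforward baseline
#'
#' One GEDFN branch (widths p masked, then 64, 16) feeding a 2-class softmax
#' output directly. The first-layer mask comes from the external graph
#' (`kind = "external"`), from a generated tree-ensemble graph fitted to the
#' training data (`"xgb"` or `"rf"`), or is all-ones (`"dfn"`), which makes
#' the model an ordinary fully connected deep feedforward network of the
#' same shape. Training matches [enggnn()].
#'
#' @inheritParams enggnn
#' @param kind which mask to use (see Details).
#' @return An object of class `gedfn` (same components as [enggnn()], with a
#'   single `graph`/`mask`).
#' @export
gedfn <- function(x, y = NULL, graph = NULL,
                  kind = c("external", "xgb", "rf", "dfn"),
                  config = training_config(), tree_config = ensemble_config(),
                  hidden = c(64L, 16L)) {
  kind <- match.arg(kind)
  d <- prepare_training_data(x, y, if (kind == "external") graph else NULL)
  p <- ncol(d$x)
  set.seed(config$seed)
  g_used <- switch(kind,
    external = {
      if (is.null(graph)) stop("kind = 'external' requires a feature graph")
      d$graph
    },
    xgb = {
      cfgb <- tree_config; cfgb$kind <- "boosted"
      g <- build_generated_graph(d$x, d$y, cfgb, seed = config$seed)
      attr(g, "ensemble") <- NULL
      g
    },
    rf = {
      cfgr <- tree_config; cfgr$kind <- "random_forest"
      g <- build_generated_graph(d$x, d$y, cfgr, seed = config$seed)
      attr(g, "ensemble") <- NULL
      g
    },
    dfn = NULL
  )
  mask <- if (is.null(g_used)) {
    m <- matrix(1, p, p)
    attr(m, "self_loops") <- TRUE
    m
  } else {
    add_self_loops(to_adjacency(g_used))
  }
  stack <- c(branch_stack(p, hidden, mask, config$dropout_rate),
             list(new_layer(hidden[length(hidden)], 2L, act = "linear")))
  net <- list(type = "single", net = stack)
  fit <- train_network(net, d$x, d$y, config)
  structure(list(net = fit$net, kind = kind, graph = g_used, mask = mask,
                 norm = d$norm, trace = fit$trace, best_loss = fit$best_loss,
                 monitored = fit$monitored, config = config,
                 feature_names = d$feature_names, n_train = nrow(d$x),
                 call = match.call()),
            class = "gedfn")
}

#' Fit any benchmark baseline by name
#'
#' Dispatcher covering the ablation and classical baselines of the
#' benchmarking protocol: `gedfn_e` (external graph only), `gedfn_xgb` /
#' `gedfn_rf` (generated graph only), `dfn` (no mask), and the plain tree
#' ensembles `xgboost` / `rf` (aliases `boosted_trees` / `random_forest`).
#' Every returned object supports [predict()] with class probabilities and
#' [importance()] with percentile-rank pseudo-probabilities.
#'
#' @inheritParams enggnn
#' @param kind baseline name (see Details).
#' @return A fitted `gedfn` or `tree_ensemble_model` object.
#' @export
fit_baseline <- function(kind, x, y = NULL, graph = NULL,
                         config = training_config(),
                         tree_config = ensemble_config()) {
  switch(kind,
    gedfn_e = gedfn(x, y, graph, kind = "external", config = config,
                    tree_config = tree_config),
    gedfn_xgb = gedfn(x, y, kind = "xgb", config = config,
                      tree_config = tree_config),
    gedfn_rf = gedfn(x, y, kind = "rf", config = config,
                     tree_config = tree_config),
    dfn = gedfn(x, y, kind = "dfn", config = config,
                tree_config = tree_config),
    xgboost = ,
    boosted_trees = fit_tree_model(x, y, tree_config, "boosted", config$seed),
    rf = ,
    random_forest = fit_tree_model(x, y, tree_config, "random_forest",
                                   config$seed),
    stop("unknown baseline kind: ", kind)
  )
}

fit_tree_model <- function(x, y, tree_config, kind, seed) {
  tree_config$kind <- kind
  d <- prepare_training_data(x, y)
  ens <- fit_ensemble(d$x, d$y, tree_config, seed = seed)
  structure(list(ensemble = ens, kind = kind, norm = d$norm,
                 feature_names = d$feature_names, call = match.call()),
            class = "tree_ensemble_model")
}

## ---- prediction ---------------------------------------------------------

predict_probs <- function(object, newdata) {
  x <- if (inherits(newdata, "expression_dataset")) newdata$x else
    as.matrix(newdata)
  if (ncol(x) != length(object$feature_names)) {
    stop("newdata has ", ncol(x), " features; model expects ",
         length(object$feature_names))
  }
  x <- zscore_normalize(x, stats = object$norm)$x
  probs <- softmax(model_forward(object$net, x)$logits)
  colnames(probs) <- c("0", "1")
  probs
}

finish_prediction <- function(probs, type) {
  if (type == "prob") probs else as.integer(max.col(probs) - 1L)
}

#' Predict method for dual-graph network fits
#'
#' Applies the stored training normalization and runs a deterministic
#' forward pass (dropout disabled). Class probabilities come from the
#' softmax output; predicted labels are the argmax (threshold 0.5).
#'
#' @param object a fitted [enggnn()] model.
#' @param newdata matrix or [expression_dataset()] with the same features.
#' @param type `"prob"` for an n x 2 probability matrix, `"class"` for
#'   0/1 labels.
#' @param ... ignored.
#' @export
predict.enggnn <- function(object, newdata, type = c("prob", "class"), ...) {
  finish_prediction(predict_probs(object, newdata), match.arg(type))
}

#' @rdname predict.enggnn
#' @export
predict.gedfn <- function(object, newdata, type = c("prob", "class"), ...) {
  finish_prediction(predict_probs(object, newdata), match.arg(type))
}

#' @rdname predict.enggnn
#' @export
predict.tree_ensemble_model <- function(object, newdata,
                                        type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "expression_dataset")) newdata$x else
    as.matrix(newdata)
  x <- zscore_normalize(x, stats = object$norm)$x
  colnames(x) <- object$feature_names
  p1 <- if (object$kind == "boosted") {
    stats::predict(object$ensemble$model,
                   xgboost::xgb.DMatrix(x, nthread = 1L))
  } else {
    stats::predict(object$ensemble$model, x, type = "prob")[, "1"]
  }
  probs <- cbind("0" = 1 - p1, "1" = p1)
  finish_prediction(probs, type)
}

## ---- print / summary / plot / coef --------------------------------------

#' @export
print.enggnn <- function(x, ...) {
  p <- length(x$feature_names)
  cat("Dual-graph neural network classifier (engGNN)\n")
  cat(sprintf("  features: %d, training samples: %d\n", p, x$n_train))
  cat(sprintf("  external graph: %d undirected edges; generated graph: %d directed edges\n",
              nrow(x$graph_e$edges), nrow(x$graph_g$edges)))
  cat(sprintf("  epochs run: %d (early stopping on %s loss, best %.4f)\n",
              length(x$trace), x$monitored, x$best_loss))
  invisible(x)
}

#' @export
print.gedfn <- function(x, ...) {
  cat(sprintf("GEDFN classifier (mask: %s)\n", x$kind))
  cat(sprintf("  features: %d, training samples: %d\n",
              length(x$feature_names), x$n_train))
  cat(sprintf("  epochs run: %d (best %s loss %.4f)\n",
              length(x$trace), x$monitored, x$best_loss))
  invisible(x)
}

#' @export
print.tree_ensemble_model <- function(x, ...) {
  cat(sprintf("Tree-ensemble classifier (%s, %d trees)\n",
              x$kind, length(x$ensemble$trees)))
  invisible(x)
}

#' @export
summary.enggnn <- function(object, ...) {
  print(object)
  imp <- importance(object)
  cat("\nTop features by connection-weight importance:\n")
  print(utils::head(imp[order(-imp$if_total),
                        c("feature", "if_ge", "if_gg", "if_total",
                          "percentile_rank")], 10L), row.names = FALSE)
  invisible(object)
}

#' Loss-trace plot
#'
#' Plots the monitored (validation by default) cross-entropy per epoch, with
#' the restored best epoch marked.
#'
#' @param x a fitted [enggnn()] or [gedfn()] model.
#' @param ... passed to [plot()].
#' @export
plot.enggnn <- function(x, ...) {
  plot(seq_along(x$trace), x$trace, type = "b", pch = 16,
       xlab = "epoch", ylab = paste(x$monitored, "cross-entropy"), ...)
  best <- which.min(x$trace)
  graphics::abline(v = best, lty = 2, col = "grey50")
  invisible(x)
}

#' @rdname plot.enggnn
#' @export
plot.gedfn <- plot.enggnn

#' @export
coef.enggnn <- function(object, ...) {
  imp <- importance(object)
  stats::setNames(imp$if_total, imp$feature)
}

#' @export
coef.gedfn <- coef.enggnn

#' Simulate labels from a fitted classifier's predictive distribution
#'
#' Draws Bernoulli labels for each row of `newdata` with the model's
#' predicted positive-class probabilities, `nsim` independent replicates.
#'
#' @param object a fitted [enggnn()] or [gedfn()] model.
#' @param nsim number of label vectors to draw.
#' @param seed optional seed (restores the RNG state afterwards, as
#'   [stats::simulate()] does).
#' @param newdata matrix or [expression_dataset()] to predict on.
#' @param ... ignored.
#' @return data frame with `nsim` columns of 0/1 labels, one row per
#'   sample.
#' @export
simulate.enggnn <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  p1 <- predict_probs(object, newdata)[, "1"]
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p1), 1L, p1)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @rdname simulate.enggnn
#' @export
simulate.gedfn <- simulate.enggnn
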