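#' Connection-weight feature scores for one masked layer
#'
#' For each feature `j`, sums the first-layer weights on the edges incident
#' to `j` that the mask admits: the masked row sum (weights from feature `j`
#' into its neighboring hidden units) plus the masked column sum (weights
#' from neighboring features into unit `j`). By default weight magnitudes
#' are summed, so positively and negatively contributing connections
#' reinforce rather than cancel; `abs_weights = FALSE` sums the signed
#' weights instead (with a signed sum, an informative feature whose
#' connections split between signs can score near zero).
#'
#' With an identity mask (isolated features, self-loops only) the signed
#' score of feature `j` reduces to `2 * w[j, j]`.
#'
#' @param w first-layer weight matrix (p x p, rows = input features).
#' @param mask the branch's self-loop-augmented 0/1 adjacency.
#' @param abs_weights sum `|w|` (default) instead of `w`.
#' @return numeric vector of length p.
#' @export
connection_weight_scores <- function(w, mask, abs_weights = TRUE) {
  if (!all(dim(w) == dim(mask))) stop("w and mask dimensions differ")
  wm <- w * (mask != 0)
  if (abs_weights) wm <- abs(wm)
  rowSums(wm) + colSums(wm)
}

#' Percentile-rank pseudo-probabilities
#'
#' Empirical-CDF transform of importance scores to (0, 1], making rankings
#' comparable across models: `rank_j` is the fraction of scores less than or
#' equal to `score_j`. Ties share the same (maximum) rank; the transform is
#' order-preserving and the largest score always maps to 1.
#'
#' @param scores finite numeric vector.
#' @return numeric vector of the same length in (0, 1].
#' @export
percentile_ranks <- function(scores) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  rank(scores, ties.method = "max") / length(scores)
}

#' Feature-importance table of a fitted model
#'
#' Computes per-feature importance and its percentile-rank
#' pseudo-probability. For the dual-graph model the total is the sum of the
#' connection-weight scores of the two branches (`if_total = if_ge +
#' if_gg`), each computed from that branch's first-layer weights at the
#' early-stopping checkpoint and its own mask. Single-branch models
#' contribute one component (the other is zero); the graph-free `dfn`
#' baseline uses its all-ones mask. Tree ensembles report their native
#' importance (split gain for boosted trees, mean decrease in impurity for
#' random forests; features never split on score 0) in `if_total`.
#'
#' @param object a fitted model.
#' @param abs_weights sum absolute weights (default) rather than signed
#'   weights (network models only; see [connection_weight_scores()]).
#' @param ... passed to methods.
#' @return data frame of class `importance_table` with columns `feature`,
#'   `if_ge`, `if_gg`, `if_total`, `percentile_rank`, `rank` (1 = most
#'   important).
#' @export
importance <- function(object, ...) UseMethod("importance")

#' @rdname importance
#' @export
importance.enggnn <- function(object, abs_weights = TRUE, ...) {
  if_ge <- connection_weight_scores(object$net$e[[1L]]$W, object$masks$e,
                                    abs_weights)
  if_gg <- connection_weight_scores(object$net$g[[1L]]$W, object$masks$g,
                                    abs_weights)
  importance_table(object$feature_names, if_ge, if_gg)
}

#' @rdname importance
#' @export
importance.gedfn <- function(object, abs_weights = TRUE, ...) {
  sc <- connection_weight_scores(object$net$net[[1L]]$W, object$mask,
                                 abs_weights)
  zero <- numeric(length(sc))
  if (object$kind %in% c("xgb", "rf")) {
    importance_table(object$feature_names, zero, sc)
  } else {
    importance_table(object$feature_names, sc, zero)
  }
}

#' @rdname importance
#' @export
importance.tree_ensemble_model <- function(object, ...) {
  sc <- tree_native_importance(object$ensemble)
  importance_table(object$feature_names, numeric(length(sc)), sc)
}

importance_table <- function(feature_names, if_ge, if_gg) {
  if_ge <- unname(if_ge)
  if_gg <- unname(if_gg)
  if_total <- if_ge + if_gg
  out <- data.frame(feature = feature_names, if_ge = if_ge, if_gg = if_gg,
                    if_total = if_total,
                    percentile_rank = percentile_ranks(if_total),
                    rank = rank(-if_total, ties.method = "min"))
  class(out) <- c("importance_table", "data.frame")
  out
}

# Native per-feature importance of a fitted tree ensemble, over all p
# features (0 where a feature is never used): split gain for boosted trees,
# Gini mean decrease in impurity for random forests.
tree_native_importance <- function(ens) {
  p <- ens$n_features
  sc <- stats::setNames(numeric(p), ens$feature_names)
  if (ens$kind == "boosted") {
    tab <- xgboost::xgb.importance(model = ens$model)
    if (!is.null(tab) && nrow(tab)) sc[tab$Feature] <- tab$Gain
  } else {
    gi <- randomForest::importance(ens$model, type = 2L)
    sc[rownames(gi)] <- gi[, 1L]
  }
  unname(sc)
}

#' Write an importance table to TSV
#'
#' @param imp an `importance_table` from [importance()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_importance <- function(imp, path) {
  utils::write.table(imp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
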