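#' Classification metrics
#'
#' Confusion counts and the derived accuracy, precision, recall, F1
#' (harmonic mean of precision and recall, defined as 0 when precision and
#' recall are both 0) for 0/1 predictions, plus ROC-AUC of the
#' positive-class scores. The ROC-AUC is the rank (Mann-Whitney) statistic,
#' which equals the trapezoidal area under the ROC curve traced over all
#' score thresholds, with ties contributing 1/2. When only one class is
#' present the ROC-AUC is undefined and reported as `NA`.
#'
#' @param y_true 0/1 labels.
#' @param y_pred 0/1 predicted labels.
#' @param y_scores optional positive-class scores for ROC-AUC.
#' @return list with `accuracy`, `precision`, `recall`, `f1`, `roc_auc`,
#'   `tp`, `tn`, `fp`, `fn`.
#' @examples
#' classification_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1), c(0.9, 0.4, 0.2, 0.6))
#' @export
classification_metrics <- function(y_true, y_pred, y_scores = NULL) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  tp <- sum(y_true == 1L & y_pred == 1L)
  tn <- sum(y_true == 0L & y_pred == 0L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  auc <- if (!is.null(y_scores)) roc_auc(y_true, y_scores) else NA_real_
  list(accuracy = (tp + tn) / length(y_true), precision = precision,
       recall = recall, f1 = f1, roc_auc = auc,
       tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Area under the ROC curve
#'
#' Rank-statistic form: the probability that a random positive outscores a
#' random negative, ties counting 1/2 — identical to the trapezoidal area
#' under the empirical ROC curve over all thresholds. `NA` when `y` has a
#' single class.
#'
#' @param y 0/1 labels.
#' @param scores positive-class scores.
#' @return scalar in [0, 1], or `NA`.
#' @export
roc_auc <- function(y, scores) {
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-function (average-precision) estimator: thresholds sweep the unique
#' score values in decreasing order and each recall increment is weighted by
#' the precision at that threshold, avoiding the optimistic bias of linear
#' PR interpolation. For random scores it concentrates around the positive
#' prevalence. `NA` when `y` has a single class.
#'
#' @inheritParams roc_auc
#' @return scalar in [0, 1], or `NA`.
#' @export
pr_auc <- function(y, scores) {
  y <- as.integer(y)
  n_pos <- sum(y == 1L)
  if (n_pos == 0L || n_pos == length(y)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  n_seen <- seq_along(y)
  last_of_tie <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- tp[last_of_tie]
  n_seen <- n_seen[last_of_tie]
  recall <- tp / n_pos
  precision <- tp / n_seen
  sum(diff(c(0, recall)) * precision)
}

#' Feature-selection metrics
#'
#' Evaluates how well importance pseudo-probabilities rank the truly
#' informative features: ROC-AUC and PR-AUC of the scores against the
#' binary informative indicator. Undefined (all-`NA`) when the indicator is
#' degenerate.
#'
#' @param true_mask logical or 0/1 indicator of informative features.
#' @param pseudo_probs importance pseudo-probabilities (e.g.
#'   [percentile_ranks()] of an importance score).
#' @return list with `fs_roc_auc` and `fs_pr_auc`.
#' @export
feature_selection_metrics <- function(true_mask, pseudo_probs) {
  m <- as.integer(as.logical(true_mask))
  list(fs_roc_auc = roc_auc(m, pseudo_probs),
       fs_pr_auc = pr_auc(m, pseudo_probs))
}

#' Welch's two-sample t-test between per-replicate metrics
#'
#' Two-sided t-test with unequal variances and Satterthwaite degrees of
#' freedom, used to compare two models' replicate-level metric vectors.
#' When both groups are constant with equal means the test is degenerate
#' and `t = 0`, `p = 1` is returned.
#'
#' @param a,b numeric metric vectors (length >= 2 each).
#' @return list with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_compare <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (equal) 0 else sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2,
                p_value = if (equal) 1 else 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}
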