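#' Benchmark scenario specification
#'
#' One cell of the simulation benchmark: a sample-to-feature ratio `pn`
#' (so `p = round(pn * n)`) and a true-feature proportion `pt`, replicated
#' datasets, an 80/20 class-stratified train/test split, and a set of models
#' to fit and evaluate. The full grid crosses
#' `pn, pt` over `{0.05, 0.1, 0.2}` (nine scenarios).
#'
#' @param pn sample-to-feature ratio (p / n).
#' @param pt true-feature proportion.
#' @param n sample size.
#' @param replicates independent simulated replicates.
#' @param train_fraction training fraction of each replicate.
#' @param models character vector among `"enggnn"`, `"gedfn_e"`,
#'   `"gedfn_xgb"`, `"gedfn_rf"`, `"dfn"`, `"xgboost"`, `"rf"`.
#' @param base_seed replicate `r` uses seed `base_seed + r` for simulation,
#'   splitting and model initialization.
#' @param config a [training_config()] (its seed is overridden per
#'   replicate).
#' @param tree_config an [ensemble_config()].
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(pn, pt, n = 5000L, replicates = 20L,
                          train_fraction = 0.8,
                          models = c("enggnn", "gedfn_e", "gedfn_xgb",
                                     "gedfn_rf", "dfn", "xgboost", "rf"),
                          base_seed = 0L, config = training_config(),
                          tree_config = ensemble_config()) {
  p <- as.integer(round_half_up(pn * n))
  stopifnot(replicates >= 1L, train_fraction > 0, train_fraction < 1, p >= 3L)
  structure(list(pn = pn, pt = pt, n = as.integer(n), p = p,
                 replicates = as.integer(replicates),
                 train_fraction = train_fraction, models = models,
                 base_seed = as.integer(base_seed), config = config,
                 tree_config = tree_config),
            class = "scenario_spec")
}

#' Class-stratified train/test split
#'
#' Samples `train_fraction` of the indices within each class, preventing
#' degenerate single-class test sets under class imbalance.
#'
#' @param y 0/1 labels.
#' @param train_fraction fraction per class assigned to training.
#' @param seed optional seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(y, train_fraction = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  train <- unlist(lapply(unique(y), function(cl) {
    idx <- which(y == cl)
    idx[sample.int(length(idx), max(1L, round(train_fraction * length(idx))))]
  }))
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

# Fit one model by benchmark name on a training dataset.
fit_model <- function(kind, train, graph, config, tree_config) {
  if (kind == "enggnn") {
    enggnn(train, graph = graph, config = config, tree_config = tree_config)
  } else {
    fit_baseline(kind, train, graph = graph, config = config,
                 tree_config = tree_config)
  }
}

#' Run a replicated benchmark scenario
#'
#' For each replicate: simulate a dataset (seed `base_seed + r`), split it
#' 80/20 stratified by class, fit every requested model on the training
#' split, and evaluate classification on the held-out split (accuracy,
#' ROC-AUC, F1) and feature selection against the simulator's informative
#' indicator (ROC-AUC and PR-AUC of the importance pseudo-probabilities).
#' A model failure in a replicate is caught, recorded as `NA` and warned
#' about, never silently dropped.
#'
#' @param spec a [scenario_spec()].
#' @param sim_overrides named list of [simulation_config()] arguments to
#'   override (e.g. a different threshold `s`).
#' @return A `benchmark_table`: data frame with columns `metric`, `pn`,
#'   `pt`, `model`, `mean`, `sd`, `n_ok`; the per-replicate long results
#'   (for e.g. [welch_compare()]) are in `attr(, "replicates")`.
#' @export
run_scenario <- function(spec, sim_overrides = list()) {
  stopifnot(inherits(spec, "scenario_spec"))
  rows <- list()
  for (r in seq_len(spec$replicates)) {
    seed <- spec$base_seed + r
    sim_args <- utils::modifyList(
      list(p = spec$p, pt = spec$pt, n = spec$n, seed = seed), sim_overrides)
    sim <- do.call(simulation_config, sim_args)
    ds <- simulate_dataset(sim)
    split <- stratified_split(ds$data$y, spec$train_fraction, seed = seed)
    train <- ds$data[split$train]
    test <- ds$data[split$test]
    cfg <- spec$config
    cfg$seed <- seed
    for (kind in spec$models) {
      res <- tryCatch({
        fitted <- fit_model(kind, train, ds$graph, cfg, spec$tree_config)
        probs <- predict(fitted, test)[, "1"]
        cm <- classification_metrics(test$y, as.integer(probs > 0.5), probs)
        fs <- feature_selection_metrics(
          ds$true_mask, importance(fitted)$percentile_rank)
        c(accuracy = cm$accuracy, roc_auc = cm$roc_auc, f1 = cm$f1,
          fs_roc_auc = fs$fs_roc_auc, fs_pr_auc = fs$fs_pr_auc)
      }, error = function(e) {
        warning("model '", kind, "' failed in replicate ", r, ": ",
                conditionMessage(e), call. = FALSE)
        c(accuracy = NA_real_, roc_auc = NA_real_, f1 = NA_real_,
          fs_roc_auc = NA_real_, fs_pr_auc = NA_real_)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, model = kind, metric = names(res), value = unname(res))
    }
  }
  long <- do.call(rbind, rows)
  agg <- stats::aggregate(value ~ metric + model, long,
                          function(v) c(mean = mean(v, na.rm = TRUE),
                                        sd = stats::sd(v, na.rm = TRUE),
                                        n_ok = sum(!is.na(v))),
                          na.action = stats::na.pass)
  out <- data.frame(metric = agg$metric, pn = spec$pn, pt = spec$pt,
                    model = agg$model,
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    n_ok = as.integer(agg$value[, "n_ok"]))
  out <- out[order(out$metric, out$model), ]
  rownames(out) <- NULL
  attr(out, "replicates") <- long
  class(out) <- c("benchmark_table", "data.frame")
  out
}

#' @export
print.benchmark_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$mean <- round(y$mean, 4)
  y$sd <- round(y$sd, 4)
  print(y, row.names = FALSE, ...)
  invisible(x)
}

#' Write a benchmark table to TSV
#'
#' Layout: one row per (metric, pn, pt, model) with mean and SD over
#' replicates.
#'
#' @param tab a `benchmark_table` from [run_scenario()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
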