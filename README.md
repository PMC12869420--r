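# enggnn

Dual-graph neural networks for disease classification and feature
selection on high-dimensional omics matrices.

## What it is for

Omics classification problems (case/control from gene expression,
proteomics, metabolomics) combine many correlated features with limited
samples. Two kinds of feature graphs help: curated biological networks
(e.g. tissue-specific functional networks, protein–protein interactions)
encode prior knowledge, and graphs extracted from tree ensembles fitted to
the data capture task-specific dependencies. This package implements the
engGNN architecture, which uses both at once, for analysts who want a
graph-informed classifier that also ranks features for downstream
biological interpretation (e.g. pathway enrichment on the top-ranked
genes).

## The model

Given features `X` (n × p), binary labels, an external undirected feature
graph `Ge` and a generated directed graph `Gg` read off a gradient-boosted
ensemble (`ntrees = 0.2 p`; per tree, an edge `f → f'` for every internal
node on `f` whose child splits on `f'`, unioned over trees), two
graph-embedded feedforward network (GEDFN) branches compute

    H1 = relu( X (W ⊙ Ã) + b ),    Ã = A + I,

one with `Ã` from `Ge`, one from `Gg`, each followed by dense layers of
widths 64 and 16. The two 16-wide embeddings are concatenated and fused by
a 16-unit hidden layer with 2-class softmax; everything trains jointly
under categorical cross-entropy (Adam, learning rate 1e-4, batches of 16,
dropout 0.2, early stopping). Feature `j`'s importance is the
connection-weight score — the masked row-plus-column sum of first-layer
weight magnitudes, summed over both branches — converted to percentile-rank
pseudo-probabilities for comparison across models. Single-graph ablations
(`gedfn_e`, `gedfn_xgb`, `gedfn_rf`), a graph-free network (`dfn`) and
plain tree ensembles (`xgboost`, `rf`) are included, together with a
scale-free simulator and a replicated benchmarking harness. See the
vignette `vignettes/dual-graph-networks.Rmd` for the full methods account.

## Worked example

```r
library(enggnn)

sim <- simulate_dataset(simulation_config(p = 100, pt = 0.2, n = 1000, seed = 1))
split <- stratified_split(sim$data$y, 0.8, seed = 1)
fit <- enggnn(sim$data[split$train], graph = sim$graph,
              config = training_config(seed = 1))
fit
#> Dual-graph neural network classifier (engGNN)
#>   features: 100, training samples: 800
#>   external graph: 99 undirected edges; generated graph: 9 directed edges
#>   epochs run: 50 (early stopping on validation loss, best 0.0200)

probs <- predict(fit, sim$data[split$test])
m <- classification_metrics(sim$data$y[split$test],
                            as.integer(probs[, "1"] > 0.5), probs[, "1"])
#> test accuracy 0.970, ROC-AUC 0.997, F1 0.963

imp <- importance(fit)
feature_selection_metrics(sim$true_mask, imp$percentile_rank)
#> feature-selection ROC-AUC 0.615, PR-AUC 0.695
head(imp[order(imp$rank), ], 3)
#>    feature    if_ge    if_gg if_total percentile_rank rank
#> 2       f2 2.626654 1.357835 3.984489            1.00    1
#> 1       f1 2.320116 1.053297 3.373412            0.99    2
#> 11     f11 2.794751 0.004478 2.799229            0.98    3
```

The simulated cohort has 1000 samples, 100 features of which 54 are truly
informative (20 centrality-stratified seeds plus their one-hop
neighbours), and a 40% positive class. The fitted model classifies the
held-out 20% almost perfectly — the simulator's labels are a noiseless
monotone cut in the informative features, so high accuracy means the
pipeline recovered that signal — while the importance ranking recovers the
informative set well above chance (ROC-AUC 0.615), which is the genuinely
hard part of the task.

Real data enter through the same interfaces: `read_expression()` for a
TSV/CSV matrix with a label column and `read_edge_list()` for a
two-column edge list over the feature names, then `enggnn()`,
`predict()`, `importance()` as above. A thin command-line wrapper with
`simulate` / `train` / `predict` / `importance` / `benchmark` / `compare`
subcommands lives at `inst/cli/enggnn.R`.

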