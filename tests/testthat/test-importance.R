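test_that("connection-weight scores apply the masked row+column sum", {
  # isolated feature: self-loop only, W[j,j] = 0.5 -> row term + column term
  w <- matrix(0, 3, 3)
  w[1, 1] <- 0.5
  expect_equal(connection_weight_scores(w, diag(3)), c(1, 0, 0))

  # all-zero weights
  expect_equal(connection_weight_scores(matrix(0, 4, 4), matrix(1, 4, 4)),
               rep(0, 4))

  # score_j = rowsum_j + colsum_j, against a double-loop oracle, in both the
  # signed (printed-formula) and magnitude modes
  set.seed(8)
  w3 <- matrix(rnorm(9), 3, 3)
  mask3 <- add_self_loops(matrix(rbinom(9, 1, 0.5), 3, 3))
  for (ab in c(TRUE, FALSE)) {
    oracle <- numeric(3)
    for (j in 1:3) {
      for (u in 1:3) {
        wv <- if (ab) abs(w3) else w3
        if (mask3[j, u] == 1) oracle[j] <- oracle[j] + wv[j, u]
        if (mask3[u, j] == 1) oracle[j] <- oracle[j] + wv[u, j]
      }
    }
    expect_equal(connection_weight_scores(w3, mask3, abs_weights = ab),
                 oracle)
  }
  full <- matrix(1, 3, 3)
  expect_equal(connection_weight_scores(w3, full, abs_weights = FALSE),
               rowSums(w3) + colSums(w3))

  # identity-mask closed forms: signed 2 * diag(W), magnitude 2 * |diag(W)|
  set.seed(9)
  w5 <- matrix(rnorm(25), 5, 5)
  expect_equal(connection_weight_scores(w5, diag(5), abs_weights = FALSE),
               2 * diag(w5))
  expect_equal(connection_weight_scores(w5, diag(5)), 2 * abs(diag(w5)))
  expect_error(connection_weight_scores(w5, diag(4)), "dimensions")
})

test_that("scores are equivariant under feature permutation", {
  set.seed(10)
  p <- 6
  w <- matrix(rnorm(p * p), p, p)
  mask <- add_self_loops(matrix(rbinom(p * p, 1, 0.4), p, p))
  perm <- sample(p)
  sc <- connection_weight_scores(w, mask)
  sc_perm <- connection_weight_scores(w[perm, perm], mask[perm, perm])
  expect_equal(sc_perm, sc[perm])
})

test_that("percentile ranks follow the empirical-CDF convention", {
  expect_equal(percentile_ranks(c(10, 20, 30)), c(1, 2, 3) / 3)
  expect_equal(percentile_ranks(rep(4, 5)), rep(1, 5))
  set.seed(2)
  sc <- rnorm(17)
  pr <- percentile_ranks(sc)
  expect_equal(max(pr), 1)
  expect_equal(order(pr), order(sc))  # order-preserving
  expect_error(percentile_ranks(c(1, NA)), "finite")
})

test_that("model importance sums the two branch components", {
  toy <- toy_sim(p = 15, n = 120, seed = 4)
  fit <- enggnn(toy$train, graph = toy$sim$graph,
                config = fast_config(seed = 4, epochs = 2L))
  imp <- importance(fit)
  expect_equal(nrow(imp), 15L)
  expect_equal(imp$feature, fit$feature_names)
  expect_equal(imp$if_total, imp$if_ge + imp$if_gg)
  expect_equal(imp$if_ge,
               connection_weight_scores(fit$net$e[[1]]$W, fit$masks$e),
               ignore_attr = TRUE)

  # zeroing one branch collapses the total onto the other
  fit0 <- fit
  fit0$net$g[[1]]$W[] <- 0
  imp0 <- importance(fit0)
  expect_equal(imp0$if_total, imp0$if_ge)

  # percentile rank is monotone in the total
  expect_equal(order(imp$percentile_rank), order(imp$if_total))
})

test_that("hand-built two-feature model matches hand-applied scoring", {
  toy <- toy_sim(p = 10, n = 100, seed = 6)
  fit <- enggnn(toy$train, graph = toy$sim$graph,
                config = fast_config(seed = 6, epochs = 1L))
  we <- fit$net$e[[1]]$W * fit$masks$e
  wg <- fit$net$g[[1]]$W * fit$masks$g
  expect_equal(importance(fit, abs_weights = FALSE)$if_total,
               (rowSums(we) + colSums(we)) + (rowSums(wg) + colSums(wg)),
               ignore_attr = TRUE)
  expect_equal(importance(fit)$if_total,
               (rowSums(abs(we)) + colSums(abs(we))) +
                 (rowSums(abs(wg)) + colSums(abs(wg))),
               ignore_attr = TRUE)
})

test_that("single-branch and tree models fill the matching component", {
  toy <- toy_sim(p = 12, n = 100, seed = 7)
  fe <- gedfn(toy$train, graph = toy$sim$graph, kind = "external",
              config = fast_config(seed = 7, epochs = 1L))
  expect_true(all(importance(fe)$if_gg == 0))
  fx <- gedfn(toy$train, kind = "xgb", config = fast_config(seed = 7, epochs = 1L))
  expect_true(all(importance(fx)$if_ge == 0))
  fd <- gedfn(toy$train, kind = "dfn", config = fast_config(seed = 7, epochs = 1L))
  expect_true(all(fd$mask == 1))  # all-ones mask drives the scores

  bt <- fit_baseline("xgboost", toy$train, config = fast_config(seed = 7))
  impt <- importance(bt)
  expect_equal(nrow(impt), 12L)
  expect_true(all(impt$if_total >= 0))
})

test_that("tree-native importance singles out the only splitting feature", {
  set.seed(12)
  x <- matrix(rnorm(300 * 4), 300, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.integer(x[, 1] > 0)  # only feature 1 carries signal
  bt <- fit_baseline("xgboost", x, y, config = training_config(seed = 1))
  imp <- importance(bt)
  expect_equal(which.max(imp$if_total), 1L)
  expect_equal(imp$rank[1], 1L)
})
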