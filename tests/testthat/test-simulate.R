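test_that("preferential attachment yields reproducible scale-free trees", {
  g <- generate_ba_graph(5, m = 1, seed = 1)
  expect_equal(nrow(g$edges), 4L)  # m = 1 gives a tree with p - 1 edges
  expect_false(g$directed)
  g2 <- generate_ba_graph(100, m = 1, seed = 42)
  g3 <- generate_ba_graph(100, m = 1, seed = 42)
  expect_equal(g2, g3)
  expect_error(generate_ba_graph(5, m = 5), "m must")

  # right-skewed degree distribution at scale
  big <- generate_ba_graph(2000, m = 1, seed = 3)
  deg <- tabulate(big$edges, nbins = 2000)
  expect_gt(max(deg), 5 * stats::median(deg))
})

test_that("graph-induced covariance has its closed form and stays PD", {
  # p = 2, single edge with weight 0.5: (I - A*)^-1 = [[1, .5], [0, 1]]
  g2 <- feature_graph(c("f1", "f2"), rbind(c(1, 2)))
  cv <- build_covariance(g2, weight_range = c(0.5, 0.5))
  expect_equal(cv$sigma, rbind(c(1.25, 0.5), c(0.5, 1)))

  # no edges -> identity covariance
  g0 <- feature_graph(paste0("f", 1:3))
  expect_equal(build_covariance(g0)$sigma, diag(3))

  # random graphs: symmetric positive definite every draw
  set.seed(5)
  for (i in 1:5) {
    g <- generate_ba_graph(20, m = 1)
    cv <- build_covariance(g)
    expect_equal(cv$sigma, t(cv$sigma))
    expect_gt(min(eigen(cv$sigma, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
})

test_that("feature sampling matches the requested moments", {
  s1 <- sample_features(10, sigma = diag(10), seed = 1)
  s2 <- sample_features(10, sigma = diag(10), seed = 1)
  expect_identical(s1$x, s2$x)
  expect_true(all(s1$mu >= 7 & s1$mu <= 13))

  big <- sample_features(10000, sigma = diag(10), seed = 2)
  emp <- stats::cov(big$x)
  expect_lt(sqrt(sum((emp - diag(10))^2)), 0.1)
  # column means within a CLT band around the drawn means
  expect_true(all(abs(colMeans(big$x) - big$mu) < 4 / sqrt(10000)))

  expect_error(sample_features(5, sigma = matrix(c(1, 2, 2, 1), 2, 2)),
               "positive definite")
})

test_that("informative features are centrality-stratified and one-hop expanded", {
  # path a - b - c: closeness ranks b highest
  path <- feature_graph(c("a", "b", "c"), rbind(c(1, 2), c(2, 3)))
  sel <- select_true_features(path, pt = 1 / 3, seed = 1)
  expect_equal(sel$high_centrality, 2L)
  expect_equal(sel$seed_features, 2L)
  expect_equal(sel$mask, c(TRUE, TRUE, TRUE))  # one hop covers the path

  set.seed(4)
  for (i in 1:5) {
    g <- generate_ba_graph(40, m = 1)
    sel <- select_true_features(g, pt = 0.1)
    expect_true(all(sel$mask[sel$seed_features]))
    # every neighbor of a seed is informative
    adj <- to_adjacency(g)
    nb <- which(colSums(adj[sel$seed_features, , drop = FALSE]) > 0)
    expect_true(all(sel$mask[nb]))
  }
  expect_error(select_true_features(path, pt = 0.01), "at least 1")
})

test_that("labels are monotone in the linear predictor and shift-invariant", {
  set.seed(11)
  x <- matrix(rnorm(200 * 6), 200, 6)
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  beta <- runif(3, -5, 5)
  y <- generate_outcome(x, mask, beta0 = -5, beta = beta, s = 0.6)
  eta <- drop(x[, mask] %*% beta)
  expect_equal(y[which.max(eta)], 1L)
  expect_equal(y[which.min(eta)], 0L)
  expect_true(all(sort(unique(y)) == c(0L, 1L)))
  # positive labels occupy exactly the top tail of eta
  expect_true(min(eta[y == 1]) > max(eta[y == 0]))

  # adding a constant to eta (via beta0) never changes labels
  y_shift <- generate_outcome(x, mask, beta0 = 100, beta = beta, s = 0.6)
  expect_identical(y, y_shift)

  # boundary: s = 0 under the rescaled variant labels everything except the
  # minimum-eta sample positive
  y0 <- generate_outcome(x, mask, beta0 = 0, beta = beta, s = 1e-12,
                         threshold_mode = "rescaled")
  expect_equal(sum(y0 == 0L), 1L)
  expect_equal(which(y0 == 0L), which.min(eta))
})

test_that("the full generator is reproducible and records provenance", {
  cfg <- simulation_config(p = 60, pt = 0.1, n = 250, seed = 3)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_equal(d1$data$x, d2$data$x)
  expect_identical(d1$data$y, d2$data$y)
  expect_identical(d1$true_mask, d2$true_mask)
  expect_equal(ncol(d1$data$x), 60L)
  expect_equal(nrow(d1$data$x), 250L)
  expect_true(sum(d1$true_mask) >= length(d1$params$seed_features))
  expect_length(d1$params$beta, sum(d1$true_mask))
  # default quantile threshold at s = 0.6 gives the 40/60 split
  expect_equal(mean(d1$data$y), 0.4, tolerance = 0.01)

  # scenario grid: nine distinct configurations
  grid <- expand.grid(pn = c(0.05, 0.1, 0.2), pt = c(0.05, 0.1, 0.2))
  expect_equal(nrow(unique(grid)), 9L)
})

test_that("the informative mask carries the class signal", {
  # a linear classifier on the true features beats one on a random
  # uninformative set of the same size
  set.seed(21)
  accs <- replicate(10, {
    seed <- sample.int(1e6, 1)
    ds <- simulate_dataset(simulation_config(p = 40, pt = 0.2, n = 300,
                                             seed = seed))
    sp <- stratified_split(ds$data$y, 0.8)
    tr <- ds$data[sp$train]
    te <- ds$data[sp$test]
    true_idx <- which(ds$true_mask)
    noise_pool <- which(!ds$true_mask)
    rand_idx <- sample(noise_pool, min(length(true_idx), length(noise_pool)))
    acc_for <- function(idx) {
      df_tr <- data.frame(y = tr$y, tr$x[, idx, drop = FALSE])
      df_te <- data.frame(te$x[, idx, drop = FALSE])
      fit <- suppressWarnings(stats::glm(y ~ ., data = df_tr,
                                         family = stats::binomial()))
      pr <- suppressWarnings(stats::predict(fit, df_te, type = "response"))
      mean((pr > 0.5) == te$y)
    }
    c(acc_for(true_idx), acc_for(rand_idx))
  })
  expect_gt(mean(accs[1, ]), mean(accs[2, ]))
})
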