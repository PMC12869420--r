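test_that("masked dense forward matches hand-computed cases", {
  # identity mask = per-feature scaling
  w <- diag(c(3, 4))
  out <- masked_dense_forward(matrix(c(1, 2), 1), w, c(0, 0), diag(2),
                              activation = "identity")
  expect_equal(out, matrix(c(3, 8), 1))

  # all-ones mask equals the ordinary dense layer
  set.seed(1)
  x <- matrix(rnorm(6), 2, 3)
  w3 <- matrix(rnorm(9), 3, 3)
  b3 <- rnorm(3)
  dense <- pmax(sweep(x %*% w3, 2, b3, `+`), 0)
  expect_equal(masked_dense_forward(x, w3, b3, matrix(1, 3, 3)), dense)

  # hand matrix product with rectifier
  out2 <- masked_dense_forward(matrix(c(1, 1), 1),
                               rbind(c(1, 2), c(3, 4)), c(1, 1),
                               matrix(1, 2, 2))
  expect_equal(out2, matrix(c(5, 7), 1))

  expect_error(masked_dense_forward(x, w3, b3, matrix(1, 2, 2)), "mismatch")
})

test_that("vectorized masked layer agrees with a per-unit accumulation loop", {
  set.seed(7)
  for (rep in 1:5) {
    p <- 10
    x <- matrix(rnorm(p * p), p, p)
    w <- matrix(rnorm(p * p), p, p)
    b <- rnorm(p)
    mask <- add_self_loops(matrix(rbinom(p * p, 1, 0.3), p, p))
    fast <- masked_dense_forward(x, w, b, mask, activation = "identity")
    slow <- matrix(0, p, p)
    for (i in seq_len(p)) {
      for (u in seq_len(p)) {
        acc <- b[u]
        for (j in seq_len(p)) {
          if (mask[j, u] == 1) acc <- acc + x[i, j] * w[j, u] * mask[j, u]
        }
        slow[i, u] <- acc
      }
    }
    expect_equal(fast, slow, tolerance = 1e-6)
  }
})

test_that("cross-entropy has its closed-form values and guards its domain", {
  expect_equal(cross_entropy(c(1L, 0L), rbind(c(0, 1), c(1, 0))), 0)
  expect_equal(cross_entropy(c(0L), rbind(c(0.5, 0.5))), log(2))
  y <- sample(0:1, 20, replace = TRUE)
  expect_equal(cross_entropy(y, matrix(0.5, 20, 2)), log(2))
  expect_error(cross_entropy(c(0L), rbind(c(1.5, -0.5))), "\\[0, 1\\]")
  # one-hot targets accepted
  expect_equal(cross_entropy(rbind(c(1, 0)), rbind(c(0.5, 0.5))), log(2))
})

test_that("weights outside the mask support never affect predictions", {
  toy <- toy_sim(p = 20, n = 120, seed = 3)
  fit <- gedfn(toy$train, graph = toy$sim$graph, kind = "external",
               config = fast_config(seed = 3, epochs = 3L))
  base <- predict(fit, toy$test)
  off <- which(fit$mask == 0)
  expect_gt(length(off), 0)
  set.seed(99)
  for (rep in 1:10) {
    perturbed <- fit
    idx <- sample(off, 5)
    perturbed$net$net[[1]]$W[idx] <- perturbed$net$net[[1]]$W[idx] +
      rnorm(5, sd = 10)
    expect_equal(predict(perturbed, toy$test), base)
  }
  # sanity: perturbing a supported weight does change predictions
  on_idx <- which(fit$mask == 1)[1]
  perturbed <- fit
  perturbed$net$net[[1]]$W[on_idx] <- perturbed$net$net[[1]]$W[on_idx] + 10
  expect_false(isTRUE(all.equal(predict(perturbed, toy$test), base)))
})

test_that("branch embeddings are deterministic in evaluation mode", {
  toy <- toy_sim(p = 15, n = 100, seed = 5)
  fit <- enggnn(toy$train, graph = toy$sim$graph,
                config = fast_config(seed = 5, epochs = 2L))
  x <- zscore_normalize(toy$test$x, stats = fit$norm)$x
  e1 <- enggnn:::stack_forward(fit$net$e, x)$out
  e2 <- enggnn:::stack_forward(fit$net$e, x)$out
  expect_identical(e1, e2)
  expect_equal(ncol(e1), 16L)

  # oracle: independently coded sequence of matrix products
  h <- x
  for (ly in fit$net$e) {
    w <- if (is.null(ly$mask)) ly$W else ly$W * ly$mask
    h <- pmax(sweep(h %*% w, 2, ly$b, `+`), 0)
  }
  expect_equal(e1, h, tolerance = 1e-6)

  # all-zero parameters give an all-zero embedding
  zero <- fit$net$e
  for (k in seq_along(zero)) {
    zero[[k]]$W[] <- 0
    zero[[k]]$b[] <- 0
  }
  expect_equal(max(abs(enggnn:::stack_forward(zero, x)$out)), 0)
})

test_that("training learns a separable toy problem and stops early", {
  toy <- separable_toy(n = 200, seed = 2)
  fit <- gedfn(toy$x, toy$y, kind = "dfn",
               config = training_config(learning_rate = 0.01, epochs = 40L,
                                        seed = 2, validation_fraction = 0))
  acc <- mean(predict(fit, toy$x, type = "class") == toy$y)
  expect_gte(acc, 0.95)
  # the restored checkpoint is the best monitored epoch
  expect_equal(fit$best_loss, min(fit$trace))
  expect_lte(length(fit$trace), 40L)

  # patience bounds the run: with patience 1 the loss trace never contains
  # two consecutive non-improvements
  fit_p1 <- gedfn(toy$x, toy$y, kind = "dfn",
                  config = training_config(learning_rate = 0.01, epochs = 40L,
                                           patience = 1L, seed = 2,
                                           validation_fraction = 0))
  tr <- fit_p1$trace
  if (length(tr) < 40L) {
    expect_gte(tr[length(tr)], min(tr[-length(tr)]))
  }
})

test_that("training is reproducible under a fixed seed", {
  toy <- toy_sim(p = 12, n = 120, seed = 9)
  f1 <- gedfn(toy$train, graph = toy$sim$graph, kind = "external",
              config = fast_config(seed = 9, epochs = 4L))
  f2 <- gedfn(toy$train, graph = toy$sim$graph, kind = "external",
              config = fast_config(seed = 9, epochs = 4L))
  expect_identical(f1$trace, f2$trace)
  expect_identical(predict(f1, toy$test), predict(f2, toy$test))
})
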