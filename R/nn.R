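#' Training configuration for the network components
#'
#' Collects the optimizer and regularization settings shared by all neural
#' models in the package. Defaults follow the benchmarking protocol: Adam
#' with learning rate 1e-4, 50 epochs, mini-batches of 16, dropout 0.2 on
#' the fully connected hidden layers (never on the graph-masked layer), and
#' early stopping with patience 5 monitored on a validation split carved
#' from the training data, restoring the best-epoch weights.
#'
#' @param learning_rate Adam step size, in (0, 1].
#' @param epochs maximum number of passes over the training data.
#' @param batch_size mini-batch size.
#' @param dropout_rate dropout probability on hidden layers, in [0, 1).
#' @param patience epochs without monitored-loss improvement before stopping.
#' @param validation_fraction fraction of the training split held out to
#'   monitor early stopping; `0` monitors the training loss instead.
#' @param seed integer seed controlling initialization, shuffling, dropout.
#' @return list of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-4, epochs = 50L,
                            batch_size = 16L, dropout_rate = 0.2,
                            patience = 5L, validation_fraction = 0.1,
                            seed = 1L) {
  stopifnot(learning_rate > 0, learning_rate <= 1,
            epochs >= 1L, batch_size >= 1L, patience >= 1L,
            dropout_rate >= 0, dropout_rate < 1,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 dropout_rate = dropout_rate, patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Graph-masked dense layer forward pass
#'
#' Computes `activation(x %*% (w * mask) + b)`: the first-layer embedding of
#' a graph-embedded feedforward network, where the self-loop-augmented
#' adjacency acts as a structural mask on the weights. Hidden unit `u`
#' aggregates exactly the features `j` with `mask[j, u] == 1` (its graph
#' parents plus itself); weights outside the support have no effect and
#' receive zero gradient because the mask multiplies `w` at every pass.
#'
#' @param x batch matrix (n x p).
#' @param w weight matrix (p inputs x p units).
#' @param b bias vector (length p).
#' @param mask p x p 0/1 matrix with unit diagonal (see [add_self_loops()]).
#' @param activation `"relu"` or `"identity"`.
#' @return n x p activation matrix.
#' @export
masked_dense_forward <- function(x, w, b, mask,
                                 activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (ncol(x) != nrow(mask) || nrow(mask) != ncol(mask) ||
      !all(dim(w) == dim(mask))) {
    stop("dimension mismatch between x, w and mask")
  }
  z <- sweep(x %*% (w * mask), 2L, b, `+`)
  if (activation == "relu") pmax(z, 0) else z
}

#' Categorical cross-entropy
#'
#' Mean over the batch of `-sum_k y_k log p_k` with one-hot targets; for
#' binary labels this is `-log` of the predicted probability of the true
#' class. Zero iff every true class is predicted with probability 1.
#'
#' @param y integer 0/1 labels (or a one-hot matrix).
#' @param probs matrix of class probabilities, rows summing to 1.
#' @return nonnegative scalar.
#' @export
cross_entropy <- function(y, probs) {
  if (any(probs < -1e-9) || any(probs > 1 + 1e-9)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (is.matrix(y)) y <- max.col(y) - 1L
  p_true <- probs[cbind(seq_len(nrow(probs)), y + 1L)]
  -mean(log(pmax(p_true, 1e-12)))
}

softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

## ---- internal layer-stack machinery -------------------------------------
## A "stack" is a list of layers: list(W, b, mask = NULL, act = "relu" |
## "linear", dropout = 0). Dropout applies to the layer's output during
## training (inverted dropout) and is disabled at evaluation; the masked
## layer never carries dropout.

new_layer <- function(n_in, n_out, mask = NULL, act = "relu", dropout = 0) {
  w <- matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
  list(W = w, b = numeric(n_out), mask = mask, act = act, dropout = dropout)
}

stack_forward <- function(stack, x, training = FALSE) {
  hs <- vector("list", length(stack))
  zs <- vector("list", length(stack))
  dms <- vector("list", length(stack))
  h <- x
  for (k in seq_along(stack)) {
    ly <- stack[[k]]
    w <- if (is.null(ly$mask)) ly$W else ly$W * ly$mask
    z <- h %*% w
    z <- z + rep(ly$b, each = nrow(z))
    if (ly$act == "relu") h <- pmax(z, 0) else h <- z
    if (training && ly$dropout > 0) {
      dm <- matrix((stats::runif(length(h)) >= ly$dropout) / (1 - ly$dropout),
                   nrow(h), ncol(h))
      h <- h * dm
      dms[[k]] <- dm
    }
    zs[[k]] <- z
    hs[[k]] <- h
  }
  list(out = h, hs = hs, zs = zs, dms = dms)
}

stack_backward <- function(stack, x, cache, dout) {
  grads <- vector("list", length(stack))
  dh <- dout
  for (k in rev(seq_along(stack))) {
    ly <- stack[[k]]
    if (!is.null(cache$dms[[k]])) dh <- dh * cache$dms[[k]]
    dz <- if (ly$act == "relu") dh * (cache$zs[[k]] > 0) else dh
    h_in <- if (k == 1L) x else cache$hs[[k - 1L]]
    dw <- crossprod(h_in, dz)
    if (!is.null(ly$mask)) dw <- dw * ly$mask
    grads[[k]] <- list(W = dw, b = colSums(dz))
    w <- if (is.null(ly$mask)) ly$W else ly$W * ly$mask
    dh <- tcrossprod(dz, w)
  }
  list(grads = grads, dx = dh)
}

## Forward through a whole model (single stack, or two branches + head).
model_forward <- function(net, x, training = FALSE) {
  if (net$type == "single") {
    c1 <- stack_forward(net$net, x, training)
    list(logits = c1$out, caches = list(net = c1))
  } else {
    ce <- stack_forward(net$e, x, training)
    cg <- stack_forward(net$g, x, training)
    hc <- cbind(ce$out, cg$out)
    ch <- stack_forward(net$head, hc, training)
    list(logits = ch$out, caches = list(e = ce, g = cg, head = ch, hc = hc))
  }
}

model_backward <- function(net, x, fwd, dlogits) {
  if (net$type == "single") {
    bk <- stack_backward(net$net, x, fwd$caches$net, dlogits)
    list(net = bk$grads)
  } else {
    bh <- stack_backward(net$head, fwd$caches$hc, fwd$caches$head, dlogits)
    k <- ncol(fwd$caches$e$out)
    be <- stack_backward(net$e, x, fwd$caches$e,
                         bh$dx[, seq_len(k), drop = FALSE])
    bg <- stack_backward(net$g, x, fwd$caches$g,
                         bh$dx[, k + seq_len(k), drop = FALSE])
    list(e = be$grads, g = bg$grads, head = bh$grads)
  }
}

stack_names <- function(net) if (net$type == "single") "net" else c("e", "g", "head")

## Adam update applied in place over every layer of every stack.
adam_init <- function(net) {
  st <- list()
  for (s in stack_names(net)) {
    st[[s]] <- lapply(net[[s]], function(ly) {
      list(mW = ly$W * 0, vW = ly$W * 0,
           mb = ly$b * 0, vb = ly$b * 0)
    })
  }
  st
}

adam_step <- function(net, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (s in stack_names(net)) {
    for (k in seq_along(net[[s]])) {
      g <- grads[[s]][[k]]
      st <- state[[s]][[k]]
      st$mW <- beta1 * st$mW + (1 - beta1) * g$W
      st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
      st$mb <- beta1 * st$mb + (1 - beta1) * g$b
      st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
      net[[s]][[k]]$W <- net[[s]][[k]]$W -
        lr * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
      net[[s]][[k]]$b <- net[[s]][[k]]$b -
        lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
      state[[s]][[k]] <- st
    }
  }
  list(net = net, state = state)
}

model_params <- function(net) lapply(stack_names(net), function(s) net[[s]])

#' @keywords internal
#' @noRd
train_network <- function(net, x, y, config) {
  n <- nrow(x)
  y_onehot <- cbind(1 - y, y)
  monitor_val <- config$validation_fraction > 0 && n >= 20L
  if (monitor_val) {
    n_val <- max(1L, round(config$validation_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
  } else {
    val_idx <- integer(0)
    tr_idx <- seq_len(n)
  }
  x_val <- x[val_idx, , drop = FALSE]
  y_val <- y[val_idx]
  state <- adam_init(net)
  trace <- numeric(0)
  best_loss <- Inf
  best_net <- net
  wait <- 0L
  t_step <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    starts <- seq(1L, length(ord), by = config$batch_size)
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + config$batch_size - 1L, length(ord))]
      xb <- x[idx, , drop = FALSE]
      fwd <- model_forward(net, xb, training = TRUE)
      probs <- softmax(fwd$logits)
      dlogits <- (probs - y_onehot[idx, , drop = FALSE]) / length(idx)
      grads <- model_backward(net, xb, fwd, dlogits)
      t_step <- t_step + 1L
      upd <- adam_step(net, grads, state, config$learning_rate, t_step)
      net <- upd$net
      state <- upd$state
    }
    mon_x <- if (monitor_val) x_val else x
    mon_y <- if (monitor_val) y_val else y
    loss <- cross_entropy(mon_y, softmax(model_forward(net, mon_x)$logits))
    if (!is.finite(loss)) {
      stop("non-finite monitored loss at epoch ", epoch,
           "; training diverged (learning rate too high?)")
    }
    trace <- c(trace, loss)
    if (loss < best_loss - 1e-12) {
      best_loss <- loss
      best_net <- net
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  list(net = best_net, trace = trace, best_loss = best_loss,
       epochs_run = length(trace), monitored = if (monitor_val) "validation" else "training")
}
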