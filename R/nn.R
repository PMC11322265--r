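# Minimal single-hidden-layer perceptron with tanh activation, trained by
# mini-batch stochastic gradient descent (optional classical momentum).
# All heavy lifting is BLAS matrix products; everything is seeded.

mlp_init <- function(d_in, d_hidden, d_out, seed, scale = 1) {
  set.seed(seed)
  list(
    W1 = matrix(stats::runif(d_in * d_hidden, -1, 1) * scale / sqrt(d_in),
                d_in, d_hidden),
    b1 = stats::runif(d_hidden, -0.1, 0.1) * scale,
    W2 = matrix(stats::runif(d_hidden * d_out, -1, 1) * scale / sqrt(d_hidden),
                d_hidden, d_out),
    b2 = numeric(d_out)
  )
}

mlp_forward <- function(par, X) {
  H <- tanh(sweep(X %*% par$W1, 2, par$b1, "+"))
  sweep(H %*% par$W2, 2, par$b2, "+")
}

mlp_loss <- function(par, X, Y) mean((mlp_forward(par, X) - Y)^2)

# Trains `par` on (X, Y) minimizing mean squared error. A validation split is
# held out for early stopping; the best-validation weights are returned, which
# also guards against the occasional instability of momentum SGD near a good
# initialization.
mlp_train <- function(X, Y, par, epochs = 60, batch_size = 32, lr = 0.001,
                      momentum = 0.9, seed = 1, val_fraction = 0.05,
                      patience = 10, verbose = FALSE) {
  stopifnot(nrow(X) == nrow(Y))
  n <- nrow(X)
  d_out <- ncol(Y)
  set.seed(seed)
  n_val <- max(1L, min(n - 1L, round(n * val_fraction)))
  val_id <- sample(n, n_val)
  tr_id <- setdiff(seq_len(n), val_id)
  Xtr <- X[tr_id, , drop = FALSE]; Ytr <- Y[tr_id, , drop = FALSE]
  Xva <- X[val_id, , drop = FALSE]; Yva <- Y[val_id, , drop = FALSE]
  ntr <- nrow(Xtr)
  bs <- min(batch_size, ntr)
  nb <- ntr %/% bs
  v <- lapply(par, function(p) p * 0)
  best <- par
  best_val <- mlp_loss(par, Xva, Yva)
  best_epoch <- 0L
  history <- data.frame(epoch = integer(0), train_mse = numeric(0),
                        val_mse = numeric(0))
  wait <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(ntr)
    tr_loss <- 0
    for (k in seq_len(nb)) {
      id <- ord[((k - 1) * bs + 1):(k * bs)]
      Xb <- Xtr[id, , drop = FALSE]
      Yb <- Ytr[id, , drop = FALSE]
      H <- tanh(sweep(Xb %*% par$W1, 2, par$b1, "+"))
      P <- sweep(H %*% par$W2, 2, par$b2, "+")
      E <- P - Yb
      tr_loss <- tr_loss + mean(E^2)
      G <- 2 * E / (bs * d_out)
      gW2 <- crossprod(H, G)
      gb2 <- colSums(G)
      GH <- (G %*% t(par$W2)) * (1 - H^2)
      gW1 <- crossprod(Xb, GH)
      gb1 <- colSums(GH)
      v$W2 <- momentum * v$W2 + gW2; par$W2 <- par$W2 - lr * v$W2
      v$b2 <- momentum * v$b2 + gb2; par$b2 <- par$b2 - lr * v$b2
      v$W1 <- momentum * v$W1 + gW1; par$W1 <- par$W1 - lr * v$W1
      v$b1 <- momentum * v$b1 + gb1; par$b1 <- par$b1 - lr * v$b1
    }
    val <- mlp_loss(par, Xva, Yva)
    history <- rbind(history, data.frame(epoch = ep, train_mse = tr_loss / nb,
                                         val_mse = val))
    if (verbose) message(sprintf("epoch %3d  train %.5g  val %.5g", ep,
                                 tr_loss / nb, val))
    if (is.finite(val) && val < best_val) {
      best_val <- val
      best <- par
      best_epoch <- ep
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  list(par = best, history = history, best_val = best_val,
       best_epoch = best_epoch)
}
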