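# Minimal convolutional building blocks for the super-resolution stage.
# Tensors are 4-D arrays dim c(H, W, C, N); convolution is im2col + BLAS GEMM.
# Only what the SRGAN needs: same-padded 3x3 conv (stride 1 or 2), batch norm,
# leaky ReLU, 2x pixel shuffle, global average pooling and a dense head.

conv_par <- function(k, cin, cout, seed, scale = 1) {
  set.seed(seed)
  list(W = matrix(stats::rnorm(k * k * cin * cout,
                               sd = scale * sqrt(2 / (k * k * cin))),
                  k * k * cin, cout),
       b = numeric(cout), k = k, cin = cin, cout = cout)
}

pad_input <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  xp
}

out_size <- function(n, k, s, p) (n + 2 * p - k) %/% s + 1

# im2col: padded input -> matrix (k^2*Cin, Ho*Wo*N)
im2col <- function(xp, k, s, ho, wo) {
  d <- dim(xp)
  cin <- d[3]; n <- d[4]
  P <- array(0, c(k, k, cin, ho, wo, n))
  ry0 <- (seq_len(ho) - 1) * s
  rx0 <- (seq_len(wo) - 1) * s
  for (dy in seq_len(k)) {
    for (dx in seq_len(k)) {
      P[dy, dx, , , , ] <- aperm(xp[ry0 + dy, rx0 + dx, , , drop = FALSE],
                                 c(3, 1, 2, 4))
    }
  }
  dim(P) <- c(k * k * cin, ho * wo * n)
  P
}

conv_fwd <- function(par, x, stride = 1) {
  d <- dim(x)
  p <- (par$k - 1) %/% 2
  ho <- out_size(d[1], par$k, stride, p)
  wo <- out_size(d[2], par$k, stride, p)
  xp <- pad_input(x, p)
  P <- im2col(xp, par$k, stride, ho, wo)
  out <- crossprod(par$W, P) + par$b          # (Cout, Ho*Wo*N)
  dim(out) <- c(par$cout, ho, wo, d[4])
  list(y = aperm(out, c(2, 3, 1, 4)),
       cache = list(P = P, dimx = d, ho = ho, wo = wo, stride = stride, p = p))
}

conv_bwd <- function(par, cache, dy) {
  ho <- cache$ho; wo <- cache$wo; k <- par$k
  n <- cache$dimx[4]
  G <- aperm(dy, c(3, 1, 2, 4))
  dim(G) <- c(par$cout, ho * wo * n)
  dW <- cache$P %*% t(G)
  db <- rowSums(G)
  dP <- par$W %*% G                            # (k^2*Cin, Ho*Wo*N)
  dim(dP) <- c(k, k, par$cin, ho, wo, n)
  hp <- cache$dimx[1] + 2 * cache$p
  wp <- cache$dimx[2] + 2 * cache$p
  dxp <- array(0, c(hp, wp, par$cin, n))
  ry0 <- (seq_len(ho) - 1) * cache$stride
  rx0 <- (seq_len(wo) - 1) * cache$stride
  for (dy_ in seq_len(k)) {
    for (dx_ in seq_len(k)) {
      sl <- aperm(array(dP[dy_, dx_, , , , ], c(par$cin, ho, wo, n)),
                  c(2, 3, 1, 4))
      dxp[ry0 + dy_, rx0 + dx_, , ] <-
        dxp[ry0 + dy_, rx0 + dx_, , , drop = FALSE] + sl
    }
  }
  p <- cache$p
  dx <- if (p > 0) dxp[p + seq_len(cache$dimx[1]), p + seq_len(cache$dimx[2]), , ,
                       drop = FALSE] else dxp
  dim(dx) <- cache$dimx
  list(dx = dx, dW = dW, db = db)
}

bn_par <- function(c) list(gamma = rep(1, c), beta = numeric(c),
                           rm = numeric(c), rv = rep(1, c))

bn_fwd <- function(par, x, train = TRUE, eps = 1e-5, mom = 0.9) {
  d <- dim(x)
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(d[1] * d[2] * d[4], d[3])
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    par$rm <- mom * par$rm + (1 - mom) * mu
    par$rv <- mom * par$rv + (1 - mom) * v
  } else {
    mu <- par$rm
    v <- par$rv
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, istd, "*")
  ym <- sweep(sweep(xhat, 2, par$gamma, "*"), 2, par$beta, "+")
  dim(ym) <- c(d[1], d[2], d[4], d[3])
  list(y = aperm(ym, c(1, 2, 4, 3)), par = par,
       cache = list(xhat = xhat, istd = istd, d = d))
}

bn_bwd <- function(par, cache, dy) {
  d <- cache$d
  dym <- aperm(dy, c(1, 2, 4, 3))
  dim(dym) <- c(d[1] * d[2] * d[4], d[3])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  m <- nrow(dym)
  t1 <- sweep(dym, 2, dbeta / m)
  t2 <- sweep(cache$xhat, 2, dgamma / m, "*")
  dxm <- sweep(t1 - t2, 2, par$gamma * cache$istd, "*")
  dim(dxm) <- c(d[1], d[2], d[4], d[3])
  list(dx = aperm(dxm, c(1, 2, 4, 3)), dgamma = dgamma, dbeta = dbeta)
}

lrelu_fwd <- function(x, alpha = 0.2) {
  neg <- x < 0
  x[neg] <- x[neg] * alpha
  list(y = x, cache = list(neg = neg, alpha = alpha))
}

lrelu_bwd <- function(cache, dy) {
  dy[cache$neg] <- dy[cache$neg] * cache$alpha
  dy
}

# 2x pixel shuffle: (H, W, 4C, N) -> (2H, 2W, C, N)
pixel_shuffle_fwd <- function(x) {
  d <- dim(x)
  cout <- d[3] %/% 4
  y <- array(0, c(2 * d[1], 2 * d[2], cout, d[4]))
  for (dy_ in 0:1) {
    for (dx_ in 0:1) {
      ch <- (seq_len(cout) - 1) * 4 + dy_ * 2 + dx_ + 1
      y[seq_len(d[1]) * 2 - 1 + dy_, seq_len(d[2]) * 2 - 1 + dx_, , ] <-
        x[, , ch, , drop = FALSE]
    }
  }
  y
}

pixel_shuffle_bwd <- function(dy) {
  d <- dim(dy)
  h <- d[1] %/% 2; w <- d[2] %/% 2
  dx <- array(0, c(h, w, d[3] * 4, d[4]))
  for (dy_ in 0:1) {
    for (dx_ in 0:1) {
      ch <- (seq_len(d[3]) - 1) * 4 + dy_ * 2 + dx_ + 1
      dx[, , ch, ] <- dy[seq_len(h) * 2 - 1 + dy_, seq_len(w) * 2 - 1 + dx_, , ,
                         drop = FALSE]
    }
  }
  dx
}

# Adam optimizer over an arbitrarily nested list of numeric parameters
adam_state <- function(par) rapply(par, function(p) NULL, how = "replace")

adam_step <- function(par, grad, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p; out_s <- s
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        out_p[[nm]] <- r$p
        out_s[[nm]] <- r$s
      }
      list(p = out_p, s = out_s)
    } else if (is.numeric(p)) {
      if (is.null(s)) s <- list(m = p * 0, v = p * 0)
      s$m <- b1 * s$m + (1 - b1) * g
      s$v <- b2 * s$v + (1 - b2) * g^2
      mh <- s$m / (1 - b1^t)
      vh <- s$v / (1 - b2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), s = s)
    } else list(p = p, s = s)
  }
  walk(par, grad, st)
}
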