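test_that("MLP training is seeded-deterministic and reduces the loss", {
  set.seed(10)
  X <- matrix(runif(200 * 12), 200)
  W <- matrix(rnorm(12 * 3), 12)
  Y <- tanh(X %*% W)
  par <- deastrain:::mlp_init(12, 16, 3, seed = 4)
  f1 <- deastrain:::mlp_train(X, Y, par, epochs = 50, batch_size = 16,
                              lr = 0.05, momentum = 0.9, seed = 4)
  f2 <- deastrain:::mlp_train(X, Y, par, epochs = 50, batch_size = 16,
                              lr = 0.05, momentum = 0.9, seed = 4)
  expect_identical(f1$par, f2$par)
  expect_lt(f1$best_val, deastrain:::mlp_loss(par, X, Y))
  expect_true(all(is.finite(f1$history$train_mse)))
})

test_that("MLP backprop matches numeric gradients", {
  set.seed(11)
  X <- matrix(runif(8 * 5), 8)
  Y <- matrix(runif(8 * 2), 8)
  par <- deastrain:::mlp_init(5, 4, 2, seed = 1)
  # analytic gradient of the batch MSE, mirrored from the training update
  H <- tanh(sweep(X %*% par$W1, 2, par$b1, "+"))
  P <- sweep(H %*% par$W2, 2, par$b2, "+")
  G <- 2 * (P - Y) / (8 * 2)
  gW2 <- crossprod(H, G)
  GH <- (G %*% t(par$W2)) * (1 - H^2)
  gW1 <- crossprod(X, GH)
  num <- function(set_get, i) {
    e <- 1e-6
    p1 <- par; p1[[set_get]][i] <- p1[[set_get]][i] + e
    p2 <- par; p2[[set_get]][i] <- p2[[set_get]][i] - e
    (deastrain:::mlp_loss(p1, X, Y) - deastrain:::mlp_loss(p2, X, Y)) / (2 * e)
  }
  expect_equal(gW1[7], num("W1", 7), tolerance = 1e-6)
  expect_equal(gW2[3], num("W2", 3), tolerance = 1e-6)
})

test_that("conv/batchnorm/pixel-shuffle backprop matches numeric gradients", {
  set.seed(3)
  cfg <- sr_config(scale = 2L, nf = 3L, n_res = 1L, disc_blocks = 2L, seed = 5L)
  g <- deastrain:::sr_generator_init(cfg)
  x <- array(runif(6 * 6 * 1 * 2), c(6, 6, 1, 2))
  tgt <- array(runif(12 * 12 * 1 * 2), c(12, 12, 1, 2))
  fwd <- deastrain:::sr_generator_fwd(g, x, train = TRUE)
  g2 <- fwd$g
  gr <- deastrain:::sr_generator_bwd(g2, fwd$cache,
                                     2 * (fwd$y - tgt) / length(fwd$y))
  lossf <- function(gg) {
    fy <- deastrain:::sr_generator_fwd(gg, x, train = TRUE)$y
    mean((fy - tgt)^2)
  }
  numgrad <- function(get, set, i) {
    e <- 1e-6
    gp <- g2; p <- get(gp); p[i] <- p[i] + e; gp <- set(gp, p); l1 <- lossf(gp)
    p[i] <- p[i] - 2 * e; gp <- set(gp, p); l2 <- lossf(gp)
    (l1 - l2) / (2 * e)
  }
  expect_equal(gr$head$W[5],
               numgrad(function(g) g$head$W,
                       function(g, p) { g$head$W <- p; g }, 5),
               tolerance = 1e-5)
  expect_equal(gr$up[[1]]$W[7],
               numgrad(function(g) g$up[[1]]$W,
                       function(g, p) { g$up[[1]]$W <- p; g }, 7),
               tolerance = 1e-5)
  expect_equal(gr$tail$b[1],
               numgrad(function(g) g$tail$b,
                       function(g, p) { g$tail$b <- p; g }, 1),
               tolerance = 1e-5)
  # discriminator (exercises strided conv + batch norm + pooling + dense)
  d <- deastrain:::sr_discriminator_init(cfg)
  xf <- array(runif(12 * 12 * 1 * 2), c(12, 12, 1, 2))
  df <- deastrain:::sr_discriminator_fwd(d, xf, train = TRUE)
  d2 <- df$d
  bl <- deastrain:::bce_logits(df$logits, 1)
  db <- deastrain:::sr_discriminator_bwd(d2, df$cache, bl$dz)
  lossd <- function(dd) {
    o <- deastrain:::sr_discriminator_fwd(dd, xf, train = TRUE)
    deastrain:::bce_logits(o$logits, 1)$loss
  }
  e <- 1e-6
  dd <- d2; dd$blocks[[1]]$conv$W[3] <- dd$blocks[[1]]$conv$W[3] + e
  l1 <- lossd(dd)
  dd$blocks[[1]]$conv$W[3] <- dd$blocks[[1]]$conv$W[3] - 2 * e
  l2 <- lossd(dd)
  expect_equal(db$grad$blocks[[1]]$conv$W[3], (l1 - l2) / (2 * e),
               tolerance = 1e-5)
  dd <- d2; dd$blocks[[2]]$bn$gamma[2] <- dd$blocks[[2]]$bn$gamma[2] + e
  l1 <- lossd(dd)
  dd$blocks[[2]]$bn$gamma[2] <- dd$blocks[[2]]$bn$gamma[2] - 2 * e
  l2 <- lossd(dd)
  expect_equal(db$grad$blocks[[2]]$bn$gamma[2], (l1 - l2) / (2 * e),
               tolerance = 1e-5)
})

test_that("pixel shuffle is an invertible rearrangement", {
  set.seed(2)
  x <- array(runif(4 * 4 * 8 * 2), c(4, 4, 8, 2))
  y <- deastrain:::pixel_shuffle_fwd(x)
  expect_equal(dim(y), c(8, 8, 2, 2))
  expect_equal(deastrain:::pixel_shuffle_bwd(y), x)
})
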