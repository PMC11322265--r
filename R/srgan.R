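# Adversarial super-resolution stage (stage 2 of the forward controller):
# a residual generator upscales 8x from the low-resolution strain image to the
# high-resolution field; a convolutional discriminator with LeakyReLU and
# batch normalization provides the adversarial signal (binary cross-entropy).
# The generator predicts a residual on top of a fixed bicubic upscale, which
# makes short CPU trainings stable and monotone against the bicubic baseline.

#' Super-resolution model configuration
#'
#' @param scale integer upscaling factor; must be a power of two realized by
#'   `log2(scale)` pixel-shuffle blocks (8 for 60 -> 480).
#' @param nf base number of feature channels.
#' @param n_res number of residual blocks in the generator.
#' @param disc_blocks number of strided conv blocks in the discriminator.
#' @param lr_generator,lr_discriminator Adam learning rates.
#' @param batch_size,epochs adversarial training schedule.
#' @param adv_weight weight of the adversarial term in the generator loss;
#'   `NULL` calibrates it on the first batch so the adversarial term
#'   contributes ~1% of the content (mean-squared-error) term.
#' @param seed RNG seed.
#' @return List of class `sr_config`.
#' @export
sr_config <- function(scale = 8L, nf = 16L, n_res = 8L, disc_blocks = 4L,
                      lr_generator = 0.00025, lr_discriminator = 0.0001,
                      batch_size = 8L, epochs = 50L, adv_weight = NULL,
                      seed = 1L) {
  if (bitwAnd(scale, scale - 1L) != 0L || scale < 2L)
    stop("scale must be a power of two >= 2")
  structure(list(scale = as.integer(scale), nf = as.integer(nf),
                 n_res = as.integer(n_res), disc_blocks = as.integer(disc_blocks),
                 lr_generator = lr_generator,
                 lr_discriminator = lr_discriminator,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), adv_weight = adv_weight,
                 seed = as.integer(seed)),
            class = "sr_config")
}

#' Desk-scale super-resolution preset
#'
#' A reduced preset for CPU testing: fewer channels and residual blocks and a
#' few epochs, meant for datasets rendered with small image sizes at the same
#' 8x scale as the full device images (e.g. `dea_config(lr_size = 10, hr_size
#' = 80)`). Because the step budget is ~500x smaller than the full schedule,
#' the Adam learning rates are raised proportionately; the full-scale
#' [sr_config()] keeps the reference rates.
#'
#' @param epochs training epochs.
#' @param seed RNG seed.
#' @return An `sr_config`.
#' @export
sr_config_desk <- function(epochs = 12L, seed = 1L) {
  sr_config(scale = 8L, nf = 8L, n_res = 2L, disc_blocks = 4L,
            lr_generator = 0.005, lr_discriminator = 0.002,
            epochs = epochs, seed = seed)
}

# ---- generator --------------------------------------------------------------

sr_generator_init <- function(cfg) {
  nf <- cfg$nf
  n_up <- as.integer(log2(cfg$scale))
  sd <- cfg$seed * 1000L
  g <- list(
    head = conv_par(3, 1, nf, sd + 1),
    res = lapply(seq_len(cfg$n_res), function(i) list(
      c1 = conv_par(3, nf, nf, sd + 10 * i, scale = 0.5),
      c2 = conv_par(3, nf, nf, sd + 10 * i + 1, scale = 0.5))),
    post = conv_par(3, nf, nf, sd + 2, scale = 0.5),
    # ICNR-style init: the 4 channels of each pixel-shuffle group start
    # identical, so upsampling begins checkerboard-free (nearest-neighbour)
    up = lapply(seq_len(n_up), function(i) {
      p <- conv_par(3, nf, 4 * nf, sd + 100 + i, scale = 0.5)
      base <- p$W[, (seq_len(nf) - 1) * 4 + 1, drop = FALSE]
      for (o in 2:4) p$W[, (seq_len(nf) - 1) * 4 + o] <- base
      p
    }),
    # small tail init: the generator starts out as (almost exactly) the
    # bicubic global skip and learns a residual correction on top of it
    tail = conv_par(3, nf, 1, sd + 3, scale = 0.02)
  )
  g
}

sr_generator_fwd <- function(g, x, train = TRUE) {
  cc <- list()
  h <- conv_fwd(g$head, x); cc$head <- h$cache
  a <- lrelu_fwd(h$y); cc$head_act <- a$cache
  skip0 <- a$y
  z <- skip0
  cc$res <- vector("list", length(g$res))
  for (i in seq_along(g$res)) {
    rb <- g$res[[i]]
    c1 <- conv_fwd(rb$c1, z)
    a1 <- lrelu_fwd(c1$y)
    c2 <- conv_fwd(rb$c2, a1$y)
    cc$res[[i]] <- list(c1 = c1$cache, a1 = a1$cache, c2 = c2$cache)
    z <- z + c2$y
  }
  pc <- conv_fwd(g$post, z); cc$post <- pc$cache
  z <- pc$y + skip0
  cc$up <- vector("list", length(g$up))
  for (i in seq_along(g$up)) {
    uc <- conv_fwd(g$up[[i]], z)
    ps <- pixel_shuffle_fwd(uc$y)
    ua <- lrelu_fwd(ps)
    cc$up[[i]] <- list(conv = uc$cache, act = ua$cache)
    z <- ua$y
  }
  tc <- conv_fwd(g$tail, z); cc$tail <- tc$cache
  # global residual path: fixed bicubic upscale of the input
  d <- dim(x)
  hr <- d[1] * 2^length(g$up)
  Wb <- bicubic_weights(hr, d[1])
  base <- array(0, c(hr, hr, 1, d[4]))
  for (n in seq_len(d[4])) base[, , 1, n] <- Wb %*% x[, , 1, n] %*% t(Wb)
  list(y = tc$y + base, g = g, cache = cc)
}

sr_generator_bwd <- function(g, cache, dy) {
  gr <- list(res = vector("list", length(g$res)),
             up = vector("list", length(g$up)))
  tb <- conv_bwd(g$tail, cache$tail, dy)
  gr$tail <- list(W = tb$dW, b = tb$db)
  dz <- tb$dx
  for (i in rev(seq_along(g$up))) {
    da <- lrelu_bwd(cache$up[[i]]$act, dz)
    dps <- pixel_shuffle_bwd(da)
    ub <- conv_bwd(g$up[[i]], cache$up[[i]]$conv, dps)
    gr$up[[i]] <- list(W = ub$dW, b = ub$db)
    dz <- ub$dx
  }
  dskip0 <- dz
  pcb <- conv_bwd(g$post, cache$post, dz)
  gr$post <- list(W = pcb$dW, b = pcb$db)
  dz <- pcb$dx
  for (i in rev(seq_along(g$res))) {
    ci <- cache$res[[i]]
    c2b <- conv_bwd(g$res[[i]]$c2, ci$c2, dz)
    da1 <- lrelu_bwd(ci$a1, c2b$dx)
    c1b <- conv_bwd(g$res[[i]]$c1, ci$c1, da1)
    gr$res[[i]] <- list(c1 = list(W = c1b$dW, b = c1b$db),
                        c2 = list(W = c2b$dW, b = c2b$db))
    dz <- dz + c1b$dx     # residual skip
  }
  dhead_act <- dz + dskip0
  dh <- lrelu_bwd(cache$head_act, dhead_act)
  hb <- conv_bwd(g$head, cache$head, dh)
  gr$head <- list(W = hb$dW, b = hb$db)
  gr
}

# ---- discriminator ----------------------------------------------------------

sr_discriminator_init <- function(cfg) {
  nf <- cfg$nf
  sd <- cfg$seed * 2000L
  chans <- c(nf, pmin(nf * 2^(seq_len(cfg$disc_blocks) %/% 2 + 1), 4 * nf))
  blocks <- vector("list", cfg$disc_blocks)
  cin <- nf
  for (i in seq_len(cfg$disc_blocks)) {
    cout <- min(nf * 2^((i + 1) %/% 2), 4 * nf)
    blocks[[i]] <- list(conv = conv_par(3, cin, cout, sd + 10 * i),
                        bn = bn_par(cout))
    cin <- cout
  }
  list(head = conv_par(3, 1, nf, sd + 1), blocks = blocks,
       dense = list(W = matrix(stats::rnorm(cin, sd = 1 / sqrt(cin)), cin, 1),
                    b = 0))
}

sr_discriminator_fwd <- function(d, x, train = TRUE) {
  cc <- list()
  h <- conv_fwd(d$head, x); cc$head <- h$cache
  a <- lrelu_fwd(h$y); cc$head_act <- a$cache
  z <- a$y
  cc$blocks <- vector("list", length(d$blocks))
  for (i in seq_along(d$blocks)) {
    b <- d$blocks[[i]]
    cv <- conv_fwd(b$conv, z, stride = 2)
    bn <- bn_fwd(b$bn, cv$y, train); d$blocks[[i]]$bn <- bn$par
    ac <- lrelu_fwd(bn$y)
    cc$blocks[[i]] <- list(conv = cv$cache, bn = bn$cache, act = ac$cache)
    z <- ac$y
  }
  dm <- dim(z)
  zm <- z
  dim(zm) <- c(dm[1] * dm[2], dm[3] * dm[4])
  feats <- matrix(colMeans(zm), dm[3], dm[4])   # (C, N) global average pool
  logits <- as.vector(crossprod(feats, d$dense$W)) + d$dense$b
  cc$feats <- feats
  cc$zdim <- dm
  list(logits = logits, d = d, cache = cc)
}

sr_discriminator_bwd <- function(d, cache, dlogits) {
  gr <- list(blocks = vector("list", length(d$blocks)))
  n <- length(dlogits)
  gr$dense <- list(W = cache$feats %*% matrix(dlogits, n, 1),
                   b = sum(dlogits))
  dfeats <- d$dense$W %*% matrix(dlogits, 1, n)  # (C, N)
  dm <- cache$zdim
  sc <- 1 / (dm[1] * dm[2])
  dz <- array(rep(as.vector(dfeats) * sc, each = dm[1] * dm[2]), dm)
  for (i in rev(seq_along(d$blocks))) {
    ci <- cache$blocks[[i]]
    da <- lrelu_bwd(ci$act, dz)
    bnb <- bn_bwd(d$blocks[[i]]$bn, ci$bn, da)
    cvb <- conv_bwd(d$blocks[[i]]$conv, ci$conv, bnb$dx)
    gr$blocks[[i]] <- list(conv = list(W = cvb$dW, b = cvb$db),
                           bn = list(gamma = bnb$dgamma, beta = bnb$dbeta))
    dz <- cvb$dx
  }
  da <- lrelu_bwd(cache$head_act, dz)
  hb <- conv_bwd(d$head, cache$head, da)
  gr$head <- list(W = hb$dW, b = hb$db)
  list(grad = gr, dx = hb$dx)
}

# stable binary cross-entropy on logits; returns loss and dlogits (mean red.)
bce_logits <- function(z, target) {
  loss <- mean(ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z))) - target * z)
  list(loss = loss, dz = (stats::plogis(z) - target) / length(z))
}

#' Train the adversarial super-resolution stage
#'
#' Alternates discriminator and generator Adam steps on batches of paired
#' low/high-resolution images of one axis. The generator loss is pixel MSE
#' plus a weighted adversarial (binary cross-entropy) term; the discriminator
#' minimizes BCE on real-vs-generated high-resolution images. Axes are trained
#' separately.
#'
#' @param dataset a `dea_dataset` built with `include_hr = TRUE`.
#' @param axis `"x"` or `"y"`.
#' @param cfg an [sr_config()]; use [sr_config_desk()] with a reduced-size
#'   dataset for CPU-scale runs.
#' @param verbose print per-epoch losses.
#' @return An `sr_model` with the generator, discriminator and loss history.
#' @export
train_super_resolution <- function(dataset, axis = c("x", "y"),
                                   cfg = sr_config_desk(), verbose = FALSE) {
  axis <- match.arg(axis)
  config <- dataset$config
  if (is.null(dataset$hr_x)) stop("dataset lacks paired HR images; build with include_hr = TRUE")
  if (config$hr_size != cfg$scale * config$lr_size)
    stop("cfg$scale does not match the dataset's lr/hr sizes")
  tr <- which(dataset$split == "train")
  # model-space pairs: the active (non-taper) region at lr and hr resolution
  LR <- preprocess_batch(dataset_images(dataset, axis, "lr")[tr, , drop = FALSE],
                         config)
  HR <- preprocess_batch(dataset_images(dataset, axis, "hr")[tr, , drop = FALSE],
                         config, out_size = config$hr_size)
  lrs <- config$lr_size
  hrs <- config$hr_size
  g <- sr_generator_init(cfg)
  d <- sr_discriminator_init(cfg)
  sg <- adam_state(g)
  sd_ <- adam_state(d)
  adv_w <- cfg$adv_weight
  set.seed(cfg$seed)
  nb <- max(1L, length(tr) %/% cfg$batch_size)
  t_g <- 0L; t_d <- 0L
  history <- NULL
  to_tensor <- function(M, rows, size) {
    x <- array(0, c(size, size, 1, length(rows)))
    for (i in seq_along(rows)) x[, , 1, i] <- unflatten_rm(M[rows[i], ], size)
    x
  }
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(length(tr))
    ep_d <- ep_c <- ep_a <- 0
    for (k in seq_len(nb)) {
      id <- ord[((k - 1) * cfg$batch_size + 1):min(k * cfg$batch_size, length(tr))]
      xlr <- to_tensor(LR, id, lrs)
      xhr <- to_tensor(HR, id, hrs)
      gf <- sr_generator_fwd(g, xlr, train = TRUE); g <- gf$g
      fake <- gf$y
      # --- discriminator step
      dfr <- sr_discriminator_fwd(d, xhr, train = TRUE); d <- dfr$d
      lr_real <- bce_logits(dfr$logits, 1)
      gr_real <- sr_discriminator_bwd(d, dfr$cache, lr_real$dz)$grad
      dff <- sr_discriminator_fwd(d, fake, train = TRUE); d <- dff$d
      lr_fake <- bce_logits(dff$logits, 0)
      gr_fake <- sr_discriminator_bwd(d, dff$cache, lr_fake$dz)$grad
      gd <- rapply2(gr_real, gr_fake, `+`)
      t_d <- t_d + 1L
      ad <- adam_step(d, gd, sd_, cfg$lr_discriminator, t_d)
      d <- ad$p; sd_ <- ad$s
      # --- generator step (content MSE + adversarial)
      content <- mean((fake - xhr)^2)
      dcontent <- 2 * (fake - xhr) / length(fake)
      dfg <- sr_discriminator_fwd(d, fake, train = TRUE); d <- dfg$d
      ladv <- bce_logits(dfg$logits, 1)
      if (is.null(adv_w)) adv_w <- 0.01 * content / max(ladv$loss, 1e-8)
      dfake_adv <- sr_discriminator_bwd(d, dfg$cache, ladv$dz)$dx
      gg <- sr_generator_bwd(g, gf$cache, dcontent + adv_w * dfake_adv)
      t_g <- t_g + 1L
      ag <- adam_step(g, gg, sg, cfg$lr_generator, t_g)
      g <- ag$p; sg <- ag$s
      ep_d <- ep_d + lr_real$loss + lr_fake$loss
      ep_c <- ep_c + content
      ep_a <- ep_a + ladv$loss
    }
    history <- rbind(history, data.frame(epoch = ep, d_loss = ep_d / nb,
                                         content = ep_c / nb, adv = ep_a / nb))
    if (verbose)
      message(sprintf("epoch %2d  D %.4f  content %.6f  adv %.4f",
                      ep, ep_d / nb, ep_c / nb, ep_a / nb))
  }
  structure(list(axis = axis, generator = g, discriminator = d, cfg = cfg,
                 config = config, adv_weight = adv_w, history = history,
                 stamp = dataset$stamp),
            class = "sr_model")
}

# elementwise combination of two parallel nested gradient lists
rapply2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- rapply2(a[[nm]], b[[nm]], f)
    out
  } else f(a, b)
}

#' @export
print.sr_model <- function(x, ...) {
  cat(sprintf("<sr_model> axis %s, x%d upscale, nf %d, %d residual blocks\n",
              toupper(x$axis), x$cfg$scale, x$cfg$nf, x$cfg$n_res))
  invisible(x)
}

#' Apply the super-resolution generator to a low-resolution image
#'
#' @param model an `sr_model`.
#' @param lr_image grayscale matrix (`lr_size` x `lr_size`, values in [0, 1]).
#' @return Upscaled grayscale matrix, clipped to `[0, 1]`.
#' @export
predict_sr <- function(model, lr_image) {
  x <- array(lr_image, c(nrow(lr_image), ncol(lr_image), 1, 1))
  y <- sr_generator_fwd(model$generator, x, train = FALSE)$y[, , 1, 1]
  pmin(pmax(y, 0), 1)
}

#' Discriminator probability that an image is a real high-resolution field
#'
#' @param model an `sr_model`.
#' @param hr_image grayscale matrix at the model's high resolution.
#' @return Probability in `(0, 1)`.
#' @export
discriminator_prob <- function(model, hr_image) {
  x <- array(hr_image, c(nrow(hr_image), ncol(hr_image), 1, 1))
  stats::plogis(sr_discriminator_fwd(model$discriminator, x,
                                     train = FALSE)$logits)
}

#' Predict a high-resolution strain field from a voltage array
#'
#' Runs the two forward-control stages: the stage-1 MLP produces the
#' low-resolution field for the requested axis, which the super-resolution
#' generator upscales.
#'
#' @param lr_model a `forward_lr_model`.
#' @param sr_model an `sr_model` trained for the same axis.
#' @param voltages a [voltage_array()].
#' @param axis `"x"` or `"y"`; must match `sr_model$axis`.
#' @return A [strain_field] at the high resolution.
#' @export
predict_hr_field <- function(lr_model, sr_model, voltages, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (sr_model$axis != axis)
    stop(sprintf("sr_model is trained for axis %s, not %s",
                 toupper(sr_model$axis), toupper(axis)))
  lr <- predict_lr_fields(lr_model, voltages)[[axis]]
  hr <- predict_sr(sr_model, lr)
  strain_field(gray_to_strain(hr, sr_model$config), axis, sr_model$config)
}
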