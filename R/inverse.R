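# Inverse control: strain-field image -> 81-channel voltage array.

#' Inverse-control model configuration
#'
#' Architecture fixed to the reference design: `lr_size^2` inputs, one hidden
#' layer of 180 tanh units, `grid_n^2` linear outputs, trained with mini-batch
#' stochastic gradient descent at learning rate 0.001 on mean squared error
#' (voltage targets standardized per pixel during optimization). The hidden
#' layer is initialized calibration-aware: two units per actuator pixel
#' implement a tanh fit of the scalar inverse calibration applied to a bilinear
#' centre-extraction filter, the output layer is wired block-locally from the
#' same fit, and the remaining units start near zero. SGD then learns the
#' coupling corrections.
#'
#' @param hidden_units hidden layer width.
#' @param epochs,batch_size,learning_rate,momentum SGD settings.
#' @param val_fraction,patience early-stopping settings (best-validation
#'   weights are kept).
#' @param units_per_pixel hidden units devoted to each pixel's calibration at
#'   initialization.
#' @param seed RNG seed for initialization, the validation split and batch
#'   shuffling.
#' @return List of class `inverse_config`.
#' @export
inverse_config <- function(hidden_units = 180L, epochs = 60L, batch_size = 32L,
                           learning_rate = 0.001, momentum = 0.9,
                           val_fraction = 0.05, patience = 10L,
                           units_per_pixel = 2L, seed = 1L) {
  structure(list(hidden_units = as.integer(hidden_units),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 val_fraction = val_fraction, patience = as.integer(patience),
                 units_per_pixel = as.integer(units_per_pixel),
                 seed = as.integer(seed)),
            class = "inverse_config")
}

# preprocess every row of a flattened-image matrix (n x size^2, row-major)
preprocess_batch <- function(images, config, out_size = config$lr_size) {
  size <- as.integer(sqrt(ncol(images)))
  A <- frac_resize_weights(out_size, size, config$boundary_margin,
                           1 - config$boundary_margin)
  out <- matrix(0, nrow(images), out_size^2)
  for (i in seq_len(nrow(images))) {
    M <- unflatten_rm(images[i, ], size)
    out[i, ] <- flatten_rm(pmin(pmax(A %*% M %*% t(A), 0), 1))
  }
  out
}

# device-pixel centres in preprocessed-image continuous matrix indices
centers_in_preprocessed <- function(config) {
  p <- (seq_len(config$grid_n) - 0.5) / config$grid_n
  f <- (p - config$boundary_margin) / (1 - 2 * config$boundary_margin)
  f * config$lr_size + 0.5
}

# bilinear centre-extraction filters, one column per pixel (row-major order)
center_filters <- function(config) {
  lrs <- config$lr_size
  ctr <- centers_in_preprocessed(config)
  Fm <- matrix(0, lrs^2, config$grid_n^2)
  idx <- function(r, c) (r - 1) * lrs + c  # row-major flat index
  k <- 0
  for (i in seq_len(config$grid_n)) {
    for (j in seq_len(config$grid_n)) {
      k <- k + 1
      r0 <- min(floor(ctr[i]), lrs - 1); fr <- ctr[i] - r0
      c0 <- min(floor(ctr[j]), lrs - 1); fc <- ctr[j] - c0
      Fm[idx(r0, c0), k] <- (1 - fr) * (1 - fc)
      Fm[idx(r0 + 1, c0), k] <- fr * (1 - fc)
      Fm[idx(r0, c0 + 1), k] <- (1 - fr) * fc
      Fm[idx(r0 + 1, c0 + 1), k] <- fr * fc
    }
  }
  Fm
}

# calibration-aware initialization for the inverse MLP (see inverse_config)
inverse_init <- function(config, curve, cfg, y_mu, y_sd) {
  k <- config$grid_n^2
  J <- cfg$units_per_pixel
  if (cfg$hidden_units < J * k)
    stop(sprintf("hidden_units must be at least %d for %d units per pixel",
                 J * k, J))
  rng <- reachable_strain_range(curve, c(config$voltage_min, config$voltage_max))
  eg <- seq(rng[1], rng[2], length.out = 2000)
  fit <- fit_scalar_tanh(eg, voltage_from_strain(eg, curve,
                                                 c(config$voltage_min,
                                                   config$voltage_max)),
                         n_units = J)
  par <- mlp_init(config$lr_size^2, cfg$hidden_units, k, cfg$seed, scale = 0.1)
  Fm <- center_filters(config)
  span <- config$strain_display_max - config$strain_display_min
  for (j in seq_len(J)) {
    for (px in seq_len(k)) {
      u <- (j - 1) * k + px
      # gray input g maps to strain eps = dmin + span * g
      par$W1[, u] <- fit$a[j] * span * Fm[, px]
      par$b1[u] <- fit$c[j] + fit$a[j] * config$strain_display_min
      par$W2[u, ] <- 0
      par$W2[u, px] <- fit$w[j] / y_sd[px]
    }
  }
  par$b2 <- (fit$w0 - y_mu) / y_sd
  par
}

#' Train the inverse-control model
#'
#' Regresses preprocessed strain-field images of one axis against the voltage
#' arrays that produced them.
#'
#' @param dataset a `dea_dataset` from [build_dataset()].
#' @param axis `"x"` or `"y"`; models are trained separately per axis.
#' @param cfg an [inverse_config()].
#' @return An `inverse_model` carrying the trained weights, the target
#'   normalization statistics and the per-epoch loss history.
#' @export
train_inverse <- function(dataset, axis = c("x", "y"), cfg = inverse_config()) {
  axis <- match.arg(axis)
  tr <- dataset$split == "train"
  if (!any(tr)) stop("dataset has no training samples")
  X <- preprocess_batch(dataset_images(dataset, axis, "lr")[tr, , drop = FALSE],
                        dataset$config)
  Yv <- dataset$voltages[tr, , drop = FALSE]
  y_mu <- colMeans(Yv)
  y_sd <- pmax(apply(Yv, 2, stats::sd), 1e-8)
  Y <- sweep(sweep(Yv, 2, y_mu), 2, y_sd, "/")
  par0 <- inverse_init(dataset$config, dataset$curve, cfg, y_mu, y_sd)
  fit <- mlp_train(X, Y, par0, epochs = cfg$epochs,
                   batch_size = cfg$batch_size, lr = cfg$learning_rate,
                   momentum = cfg$momentum, seed = cfg$seed,
                   val_fraction = cfg$val_fraction, patience = cfg$patience)
  structure(list(axis = axis, par = fit$par, y_mu = y_mu, y_sd = y_sd,
                 cfg = cfg, config = dataset$config, curve = dataset$curve,
                 history = fit$history, best_epoch = fit$best_epoch,
                 stamp = dataset$stamp),
            class = "inverse_model")
}

#' @export
print.inverse_model <- function(x, ...) {
  cat(sprintf("<inverse_model> axis %s, %d->%d(tanh)->%d, best epoch %d\n",
              toupper(x$axis), nrow(x$par$W1), ncol(x$par$W1), ncol(x$par$W2),
              x$best_epoch))
  invisible(x)
}

#' Predict the voltage array reproducing a target strain image
#'
#' @param model an `inverse_model`.
#' @param image a [strain_field], a grayscale matrix (preprocessed internally),
#'   or an already-preprocessed vector of length `lr_size^2`.
#' @return A [voltage_array()] (predictions clipped to the operating range).
#' @export
predict_voltages <- function(model, image) {
  config <- model$config
  if (inherits(image, "strain_field") && image$axis != model$axis)
    warning(sprintf("image axis %s fed to a %s-axis inverse model",
                    toupper(image$axis), toupper(model$axis)))
  x <- if (is.numeric(image) && is.null(dim(image))) {
    if (length(image) != config$lr_size^2)
      stop("preprocessed vector has wrong length")
    image
  } else {
    preprocess_image(image, config)
  }
  p <- mlp_forward(model$par, matrix(x, 1))[1, ]
  v <- p * model$y_sd + model$y_mu
  v <- pmin(pmax(v, config$voltage_min), config$voltage_max)
  voltage_array(unflatten_rm(v, config$grid_n), config)
}

#' Evaluate an inverse model on a dataset split
#'
#' Reports the pooled mean squared error in kV^2, its square root in kV (the
#' kV-denominated reading), and the per-pixel 9 x 9 mean-absolute-error grid.
#'
#' @param model an `inverse_model`.
#' @param dataset a `dea_dataset`.
#' @param split `"test"` (default) or `"train"`.
#' @return List with `mse_kv2`, `rmse_kv`, `error_grid`, `n`.
#' @export
evaluate_inverse <- function(model, dataset, split = "test") {
  id <- dataset$split == split
  if (!any(id)) stop("empty split: ", split)
  config <- dataset$config
  X <- preprocess_batch(dataset_images(dataset, model$axis, "lr")[id, , drop = FALSE],
                        config)
  P <- mlp_forward(model$par, X)
  V <- sweep(sweep(P, 2, model$y_sd, "*"), 2, model$y_mu, "+")
  V <- pmin(pmax(V, config$voltage_min), config$voltage_max)
  truth <- dataset$voltages[id, , drop = FALSE]
  err <- V - truth
  list(mse_kv2 = mean(err^2), rmse_kv = sqrt(mean(err^2)),
       error_grid = unflatten_rm(colMeans(abs(err)), config$grid_n),
       n = sum(id))
}
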