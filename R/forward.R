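# Forward control, stage 1: voltage array -> concatenated low-resolution
# X/Y strain-image pair via a single MLP.

#' Stage-1 forward-model configuration
#'
#' One MLP maps the 81 voltages to the concatenated preprocessed X and Y
#' low-resolution images (a `2 * lr_size^2` vector), with settings mirroring
#' the inverse model: 180 tanh hidden units, stochastic gradient descent at
#' learning rate 0.001. Initialization is calibration-aware: two hidden units
#' per input pixel encode the forward scalar calibration; the per-actuator
#' image operator (footprint, coupling and taper) is estimated from the
#' training data by a well-conditioned 81-feature least squares and wired into
#' the output layer with the calibration-fit ratios held fixed. SGD refines
#' from there.
#'
#' @inheritParams inverse_config
#' @return List of class `forward_config`.
#' @export
forward_config <- function(hidden_units = 180L, epochs = 20L, batch_size = 32L,
                           learning_rate = 0.001, momentum = 0.9,
                           val_fraction = 0.05, patience = 8L,
                           units_per_pixel = 2L, seed = 1L) {
  structure(list(hidden_units = as.integer(hidden_units),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 val_fraction = val_fraction, patience = as.integer(patience),
                 units_per_pixel = as.integer(units_per_pixel),
                 seed = as.integer(seed)),
            class = "forward_config")
}

#' Train the stage-1 forward model
#'
#' @param dataset a `dea_dataset` with low-resolution images for both axes.
#' @param cfg a [forward_config()].
#' @return A `forward_lr_model`.
#' @export
train_forward_lr <- function(dataset, cfg = forward_config()) {
  config <- dataset$config
  tr <- dataset$split == "train"
  if (!any(tr)) stop("dataset has no training samples")
  X <- dataset$voltages[tr, , drop = FALSE]
  Y <- cbind(preprocess_batch(dataset$lr_x[tr, , drop = FALSE], config),
             preprocess_batch(dataset$lr_y[tr, , drop = FALSE], config))
  k <- config$grid_n^2
  J <- cfg$units_per_pixel
  if (cfg$hidden_units < J * k)
    stop("hidden_units too small for the per-pixel initialization")
  # scalar forward calibration in display-gray units
  vg <- seq(config$voltage_min, config$voltage_max, length.out = 2000)
  span <- config$strain_display_max - config$strain_display_min
  gg <- (strain_from_voltage(vg, dataset$curve,
                             c(config$voltage_min, config$voltage_max)) -
           config$strain_display_min) / span
  fit <- fit_scalar_tanh(vg, gg, n_units = J)
  par <- mlp_init(k, cfg$hidden_units, ncol(Y), cfg$seed, scale = 0.1)
  for (j in seq_len(J)) {
    for (px in seq_len(k)) {
      u <- (j - 1) * k + px
      par$W1[, u] <- 0
      par$W1[px, u] <- fit$a[j]
      par$b1[u] <- fit$c[j]
      par$W2[u, ] <- 0
    }
  }
  # per-pixel calibrated strain features f_k = ghat(V_k); the image operator B
  # (how each actuator's strain spreads into the preprocessed image, i.e. the
  # footprint plus coupling and taper) is estimated by a well-conditioned
  # 81-feature least squares on the training set and wired into the output
  # layer with the tanh-fit ratios held fixed. SGD refines from there.
  Fk <- matrix(fit$w0, nrow(X), k)
  for (j in seq_len(J))
    Fk <- Fk + fit$w[j] * tanh(fit$a[j] * X + fit$c[j])
  Fk1 <- cbind(Fk, 1)
  A <- crossprod(Fk1) + 1e-8 * mean(diag(crossprod(Fk1))) * diag(k + 1)
  B <- solve(A, crossprod(Fk1, Y))      # (k+1) x 7200
  for (j in seq_len(J)) {
    for (px in seq_len(k)) {
      par$W2[(j - 1) * k + px, ] <- fit$w[j] * B[px, ]
    }
  }
  par$b2 <- fit$w0 * colSums(B[seq_len(k), , drop = FALSE]) + B[k + 1, ]
  fitres <- mlp_train(X, Y, par, epochs = cfg$epochs,
                      batch_size = cfg$batch_size, lr = cfg$learning_rate,
                      momentum = cfg$momentum, seed = cfg$seed,
                      val_fraction = cfg$val_fraction, patience = cfg$patience)
  structure(list(par = fitres$par, cfg = cfg, config = config,
                 curve = dataset$curve, history = fitres$history,
                 best_epoch = fitres$best_epoch, stamp = dataset$stamp),
            class = "forward_lr_model")
}

#' @export
print.forward_lr_model <- function(x, ...) {
  cat(sprintf("<forward_lr_model> %d->%d(tanh)->%d, best epoch %d\n",
              nrow(x$par$W1), ncol(x$par$W1), ncol(x$par$W2), x$best_epoch))
  invisible(x)
}

#' Predict the low-resolution strain-field pair for a voltage array
#'
#' @param model a `forward_lr_model`.
#' @param voltages a [voltage_array()] (or matrix/row-major vector).
#' @return List with grayscale matrices `x` and `y` (`lr_size` x `lr_size`,
#'   values in `[0, 1]`) and their strain-unit versions `strain_x`, `strain_y`.
#' @export
predict_lr_fields <- function(model, voltages) {
  config <- model$config
  v <- flatten_rm(unclass(voltage_array(voltages, config)))
  p <- mlp_forward(model$par, matrix(v, 1))[1, ]
  p <- pmin(pmax(p, 0), 1)
  n2 <- config$lr_size^2
  gx <- unflatten_rm(p[seq_len(n2)], config$lr_size)
  gy <- unflatten_rm(p[n2 + seq_len(n2)], config$lr_size)
  list(x = gx, y = gy,
       strain_x = gray_to_strain(gx, config),
       strain_y = gray_to_strain(gy, config))
}

#' Evaluate stage-1 forward predictions by SSIM against ground truth
#'
#' For each sample of the split, computes the mean SSIM between the predicted
#' and ground-truth preprocessed low-resolution image of the requested axis.
#'
#' @param model a `forward_lr_model`.
#' @param dataset a `dea_dataset`.
#' @param axis `"x"` or `"y"`.
#' @param split `"test"` (default) or `"train"`.
#' @param params a [ssim_params()].
#' @return List with `mean_ssim` (average over the split) and `ssim` (per
#'   sample).
#' @export
evaluate_forward_lr <- function(model, dataset, axis = c("x", "y"),
                                split = "test", params = ssim_params()) {
  axis <- match.arg(axis)
  config <- dataset$config
  id <- dataset$split == split
  if (!any(id)) stop("empty split: ", split)
  truth <- preprocess_batch(dataset_images(dataset, axis, "lr")[id, , drop = FALSE],
                            config)
  P <- mlp_forward(model$par, dataset$voltages[id, , drop = FALSE])
  n2 <- config$lr_size^2
  off <- if (axis == "x") 0 else n2
  P <- pmin(pmax(P[, off + seq_len(n2), drop = FALSE], 0), 1)
  s <- vapply(seq_len(nrow(P)), function(i) {
    mean_ssim(unflatten_rm(P[i, ], config$lr_size),
              unflatten_rm(truth[i, ], config$lr_size), params)
  }, numeric(1))
  list(mean_ssim = mean(s), ssim = s, n = length(s))
}
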