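# Structural similarity (SSIM) with Gaussian-window local maps, and the
# per-pixel voltage error grid.

#' SSIM parameters
#'
#' Gaussian-window SSIM following the standard formulation: an 11-point
#' Gaussian window (sigma 1.5 by default) is slid over both images; within each
#' window the weighted mean luminance, variance and covariance feed the
#' luminance x contrast x structure product with stabilization constants
#' `C1 = (0.01 data_range)^2`, `C2 = (0.03 data_range)^2` and `C3 = C2 / 2`
#' (with which the three-term product reduces exactly to the common two-term
#' form). The local map is computed on valid (fully inside) windows only.
#'
#' @param window_size odd window side length.
#' @param gaussian_sigma window standard deviation in pixels.
#' @param data_range intensity span of the images (1 for `[0, 1]` grayscale).
#' @param K1,K2 stabilization coefficients.
#' @return List of class `ssim_params` (includes `C1`, `C2`, `C3`).
#' @export
ssim_params <- function(window_size = 11L, gaussian_sigma = 1.5,
                        data_range = 1, K1 = 0.01, K2 = 0.03) {
  if (window_size %% 2 != 1 || window_size < 3)
    stop("window_size must be an odd integer >= 3")
  C2 <- (K2 * data_range)^2
  structure(list(window_size = as.integer(window_size),
                 gaussian_sigma = gaussian_sigma, data_range = data_range,
                 C1 = (K1 * data_range)^2, C2 = C2, C3 = C2 / 2),
            class = "ssim_params")
}

#' Gaussian window weights
#'
#' Normalized 2-D Gaussian window (sum 1, centre weight maximal).
#'
#' @param params a [ssim_params()].
#' @return `window_size` x `window_size` weight matrix.
#' @export
ssim_window <- function(params = ssim_params()) {
  x <- seq(-(params$window_size - 1) / 2, (params$window_size - 1) / 2)
  w <- exp(-x^2 / (2 * params$gaussian_sigma^2))
  w <- w / sum(w)
  outer(w, w)
}

# valid-mode separable windowed filtering as a pair of band-matrix products
ssim_filter_ops <- function(n, params) {
  x <- seq(-(params$window_size - 1) / 2, (params$window_size - 1) / 2)
  w <- exp(-x^2 / (2 * params$gaussian_sigma^2))
  w <- w / sum(w)
  n_out <- n - params$window_size + 1
  if (n_out < 1) stop("image smaller than the SSIM window")
  W <- matrix(0, n_out, n)
  for (i in seq_len(n_out)) W[i, i:(i + params$window_size - 1)] <- w
  W
}

#' Local SSIM map of two images
#'
#' @param x,y single-channel numeric matrices of identical shape.
#' @param params a [ssim_params()].
#' @param two_term use the reduced two-term formula instead of the explicit
#'   luminance x contrast x structure product (they agree to ~1e-15 when
#'   `C3 = C2/2`).
#' @return Matrix of local SSIM values over valid window positions.
#' @export
local_ssim_map <- function(x, y, params = ssim_params(), two_term = FALSE) {
  if (inherits(x, "strain_field") || inherits(y, "strain_field"))
    stop("render strain fields to grayscale before computing SSIM")
  if (!is.matrix(x) || !is.matrix(y) || !all(dim(x) == dim(y)))
    stop("x and y must be matrices of identical shape")
  Wr <- ssim_filter_ops(nrow(x), params)
  Wc <- ssim_filter_ops(ncol(x), params)
  f <- function(m) Wr %*% m %*% t(Wc)
  mu_x <- f(x)
  mu_y <- f(y)
  var_x <- pmax(f(x * x) - mu_x^2, 0)
  var_y <- pmax(f(y * y) - mu_y^2, 0)
  cov_xy <- f(x * y) - mu_x * mu_y
  C1 <- params$C1; C2 <- params$C2; C3 <- params$C3
  if (two_term) {
    ((2 * mu_x * mu_y + C1) * (2 * cov_xy + C2)) /
      ((mu_x^2 + mu_y^2 + C1) * (var_x + var_y + C2))
  } else {
    sd_x <- sqrt(var_x)
    sd_y <- sqrt(var_y)
    l <- (2 * mu_x * mu_y + C1) / (mu_x^2 + mu_y^2 + C1)
    cc <- (2 * sd_x * sd_y + C2) / (var_x + var_y + C2)
    s <- (cov_xy + C3) / (sd_x * sd_y + C3)
    l * cc * s
  }
}

#' Mean SSIM of two images
#'
#' Average of the local SSIM map.
#'
#' @inheritParams local_ssim_map
#' @return Scalar in `(-1, 1]`.
#' @export
mean_ssim <- function(x, y, params = ssim_params()) {
  mean(local_ssim_map(x, y, params))
}

#' Full SSIM report (mean plus local map)
#'
#' @inheritParams local_ssim_map
#' @return List of class `ssim_report` with `mean_ssim`, `local_map`, `params`.
#' @export
ssim_report <- function(x, y, params = ssim_params()) {
  m <- local_ssim_map(x, y, params)
  structure(list(mean_ssim = mean(m), local_map = m, params = params),
            class = "ssim_report")
}

#' @export
print.ssim_report <- function(x, ...) {
  cat(sprintf("<ssim_report> mean SSIM %.4f over %d x %d valid windows\n",
              x$mean_ssim, nrow(x$local_map), ncol(x$local_map)))
  invisible(x)
}

#' Per-pixel voltage error grid
#'
#' Mean absolute voltage error per actuator pixel across aligned lists of
#' predicted and ground-truth voltage arrays (the 9 x 9 "error grid" view of
#' inverse-control performance).
#'
#' @param predicted,truth equal-length lists of [voltage_array()] objects (or
#'   matrices).
#' @return `grid_n` x `grid_n` matrix of mean absolute errors in kV.
#' @export
error_grid <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  if (length(predicted) == 0) stop("empty input")
  acc <- 0
  for (i in seq_along(predicted)) {
    p <- unclass(predicted[[i]])
    t_ <- unclass(truth[[i]])
    if (!all(dim(p) == dim(t_))) stop("shape mismatch at element ", i)
    acc <- acc + abs(p - t_)
  }
  acc / length(predicted)
}
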