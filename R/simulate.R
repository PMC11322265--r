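# Surrogate device simulator: voltage array -> coupled strain fields.

#' Strain-field container
#'
#' A 2-D scalar strain map for one axis (X strain or Y strain) together with
#' its size and the display range used for grayscale rendering.
#'
#' @param values numeric matrix (square) of strain values, finite and
#'   non-negative; rows run along y (image rows), columns along x.
#' @param axis `"x"` or `"y"` (the LE11 / LE22 direction the map describes).
#' @param config a [dea_config()] (supplies the display range).
#' @return An object of class `strain_field`.
#' @export
strain_field <- function(values, axis = c("x", "y"), config = dea_config()) {
  axis <- match.arg(axis)
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("strain field values must be a square matrix")
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0))
    stop("strain values must be finite and non-negative")
  structure(list(values = values, axis = axis, size = nrow(values),
                 display_range = c(config$strain_display_min,
                                   config$strain_display_max)),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("<strain_field> axis %s, %d x %d px, strain %.3g - %.3g\n",
              toupper(x$axis), x$size, x$size, min(x$values), max(x$values)))
  invisible(x)
}

# cache of smoothing band matrices and taper profiles, keyed by parameters
.sim_cache <- new.env(parent = emptyenv())

# row-normalized Gaussian smoothing matrix (size x size), sigma in image px.
# Row-normalization = truncated-and-renormalized convolution: a constant map
# stays exactly constant and interior kernel mass is conserved.
smoothing_matrix <- function(size, sigma) {
  key <- sprintf("K_%d_%.8g", size, sigma)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  d <- outer(seq_len(size), seq_len(size), "-")
  K <- exp(-d^2 / (2 * sigma^2))
  K <- K / rowSums(K)
  .sim_cache[[key]] <- K
  K
}

# smoothstep taper from 0 at the clamped frame to 1 at boundary_margin
taper_profile <- function(size, margin) {
  key <- sprintf("T_%d_%.8g", size, margin)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  p <- (seq_len(size) - 0.5) / size
  d <- pmin(p, 1 - p)
  t <- if (margin > 0) pmin(d / margin, 1) else rep(1, size)
  t <- t * t * (3 - 2 * t)
  .sim_cache[[key]] <- t
  t
}

# image pixel -> device pixel assignment (nearest-boundary rasterization:
# each image pixel belongs to the device pixel containing its centre)
pixel_index <- function(size, grid_n) {
  pmin(floor((seq_len(size) - 0.5) * grid_n / size) + 1L, grid_n)
}

# continuous image-pixel coordinates of device-pixel centres
pixel_centers <- function(size, grid_n) {
  (seq_len(grid_n) - 0.5) * size / grid_n + 0.5
}

#' Simulate the coupled strain fields of the DEA array
#'
#' Closed-form surrogate for the finite-element model of the device. Per-pixel
#' commanded strains follow the calibration curve; the commanded map is painted
#' piecewise-constant over the pixel footprints, convolved with an anisotropic
#' Gaussian coupling kernel (elongated *along* each field's strain axis, the
#' direction in which the clamped membrane equalizes strain between serially
#' coupled actuators), and multiplied by a smoothstep taper that ramps to the
#' undeformed clamped frame over `boundary_margin`. Deterministic.
#'
#' @param voltages a [voltage_array()] (or matrix acceptable to it).
#' @param config a [dea_config()].
#' @param curve a [dea_curve()].
#' @param resolution output image side in pixels; defaults to `config$hr_size`.
#'   Use `config$lr_size` for the directly rendered low-resolution field.
#' @return List with `strain_field` elements `x` and `y`.
#' @examples
#' sim <- dea_simulate(voltage_array(matrix(5, 9, 9)), resolution = 60)
#' range(sim$x$values)
#' @export
dea_simulate <- function(voltages, config = dea_config(), curve = dea_curve(),
                         resolution = config$hr_size) {
  voltages <- voltage_array(voltages, config)
  eps <- strain_from_voltage(unclass(voltages), curve,
                             c(config$voltage_min, config$voltage_max))
  fields <- simulate_strain(eps, config, resolution)
  list(x = strain_field(fields$x, "x", config),
       y = strain_field(fields$y, "y", config))
}

# core: commanded strain matrix -> smoothed, tapered fields (plain matrices)
simulate_strain <- function(eps, config, resolution) {
  size <- as.integer(resolution)
  if (size < config$grid_n) stop("resolution below the device grid size")
  px <- pixel_index(size, config$grid_n)
  painted <- eps[px, px, drop = FALSE]
  s_par <- config$coupling_sigma_parallel * size / config$grid_n
  s_perp <- config$coupling_sigma_perpendicular * size / config$grid_n
  Kpar <- smoothing_matrix(size, s_par)
  Kperp <- smoothing_matrix(size, s_perp)
  tp <- taper_profile(size, config$boundary_margin)
  taper <- outer(tp, tp)
  # X strain: smoothed along x (columns) with the parallel sigma, along y with
  # the perpendicular sigma; Y strain: the transpose arrangement.
  fx <- (Kperp %*% painted %*% t(Kpar)) * taper
  fy <- (Kpar %*% painted %*% t(Kperp)) * taper
  list(x = fx, y = fy)
}
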