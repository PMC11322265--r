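#' Virtual device configuration
#'
#' Geometry, prestretch, operating voltage range, inter-pixel coupling and
#' boundary parameters of the virtual DEA-array bioreactor, plus the image
#' resolutions used throughout the pipeline.
#'
#' The coupling kernel is an anisotropic Gaussian expressed in device-pixel
#' units (one unit = one actuator pitch). `coupling_sigma_parallel` acts
#' *along* the strain axis of a field (the direction in which a clamped
#' membrane redistributes strain between serially coupled actuators) and
#' `coupling_sigma_perpendicular` across it. Both are deliberately sub-pixel so
#' that the strain at a pixel's centre remains dominated by that pixel's own
#' actuation; the anisotropy is what makes gradients across the strain axis
#' harder to render than gradients along it.
#'
#' @param grid_n actuator pixels per side of the array.
#' @param membrane_side membrane edge length in mm.
#' @param prestretch_engineering biaxial engineering prestretch (1.0 = 100%).
#'   Applied before actuation to keep the membrane planar; it is not counted in
#'   the strain delivered to cultured cells and only enters reporting.
#' @param voltage_min,voltage_max operating voltage range in kV.
#' @param coupling_sigma_parallel,coupling_sigma_perpendicular Gaussian
#'   coupling scales in device-pixel units (see Details).
#' @param boundary_margin fraction of the field width over which the strain
#'   tapers to the undeformed clamped frame.
#' @param hr_size,lr_size high- and low-resolution image sides in pixels;
#'   `hr_size` must be an integer multiple of `lr_size`.
#' @param strain_display_min,strain_display_max strain values mapped linearly
#'   onto grayscale 0 and 1 when rendering fields as images.
#' @return An object of class `dea_config`.
#' @examples
#' cfg <- dea_config()
#' cfg$grid_n
#' @export
dea_config <- function(grid_n = 9L,
                       membrane_side = 100,
                       prestretch_engineering = 1.0,
                       voltage_min = 0,
                       voltage_max = 7.1,
                       coupling_sigma_parallel = 0.2,
                       coupling_sigma_perpendicular = 0.07,
                       boundary_margin = 0.04,
                       hr_size = 480L,
                       lr_size = 60L,
                       strain_display_min = 0,
                       strain_display_max = 70) {
  cfg <- list(
    grid_n = as.integer(grid_n),
    membrane_side = membrane_side,
    prestretch_engineering = prestretch_engineering,
    voltage_min = voltage_min,
    voltage_max = voltage_max,
    coupling_sigma_parallel = coupling_sigma_parallel,
    coupling_sigma_perpendicular = coupling_sigma_perpendicular,
    boundary_margin = boundary_margin,
    hr_size = as.integer(hr_size),
    lr_size = as.integer(lr_size),
    strain_display_min = strain_display_min,
    strain_display_max = strain_display_max
  )
  class(cfg) <- "dea_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$grid_n >= 1L)
  if (cfg$voltage_min >= cfg$voltage_max)
    stop("voltage_min must be strictly below voltage_max")
  if (cfg$boundary_margin < 0 || cfg$boundary_margin >= 0.5)
    stop("boundary_margin must lie in [0, 0.5)")
  if (cfg$hr_size %% cfg$lr_size != 0L)
    stop("hr_size must be an integer multiple of lr_size")
  if (cfg$coupling_sigma_parallel <= 0 || cfg$coupling_sigma_perpendicular <= 0)
    stop("coupling sigmas must be positive")
  if (cfg$strain_display_min >= cfg$strain_display_max)
    stop("strain display range is empty")
  invisible(cfg)
}

#' @export
print.dea_config <- function(x, ...) {
  cat(sprintf("<dea_config> %d x %d DEA array on %g mm membrane\n",
              x$grid_n, x$grid_n, x$membrane_side))
  cat(sprintf("  voltage range   : %g - %g kV\n", x$voltage_min, x$voltage_max))
  cat(sprintf("  prestretch      : %g (engineering), %.4f (true)\n",
              x$prestretch_engineering,
              engineering_to_true_strain(x$prestretch_engineering)))
  cat(sprintf("  coupling sigma  : %g (parallel) / %g (perpendicular) px\n",
              x$coupling_sigma_parallel, x$coupling_sigma_perpendicular))
  cat(sprintf("  boundary margin : %g, images %d / %d px\n",
              x$boundary_margin, x$lr_size, x$hr_size))
  invisible(x)
}

#' 9 x 9 voltage input array
#'
#' Wraps a `grid_n` x `grid_n` matrix of per-pixel voltages (kV) after range
#' validation. Vectors of length `grid_n^2` are interpreted in row-major pixel
#' order (the order used in voltage CSV files, columns `v00..v88`).
#'
#' @param values matrix `grid_n` x `grid_n`, or vector of length `grid_n^2`
#'   in row-major order.
#' @param config a [dea_config()].
#' @return A `voltage_array` (a matrix with class attribute).
#' @export
voltage_array <- function(values, config = dea_config()) {
  n <- config$grid_n
  if (is.null(dim(values))) {
    if (length(values) != n * n)
      stop(sprintf("expected %d voltages, got %d", n * n, length(values)))
    values <- matrix(values, n, n, byrow = TRUE)
  }
  if (!all(dim(values) == c(n, n)))
    stop(sprintf("voltage matrix must be %d x %d", n, n))
  if (anyNA(values) || any(!is.finite(values)))
    stop("voltages must be finite")
  if (any(values < config$voltage_min - 1e-9) ||
      any(values > config$voltage_max + 1e-9))
    stop(sprintf("voltages must lie in [%g, %g] kV",
                 config$voltage_min, config$voltage_max))
  structure(pmin(pmax(values, config$voltage_min), config$voltage_max),
            class = c("voltage_array", "matrix"))
}

#' @export
print.voltage_array <- function(x, ...) {
  cat(sprintf("<voltage_array> %d x %d, %.2f - %.2f kV\n",
              nrow(x), ncol(x), min(x), max(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Row-major flattening helpers
#'
#' The package-wide vector convention for images and voltage arrays is
#' row-major (matching the `v00..v88` CSV column order and the flattened
#' image vectors fed to the models).
#'
#' @param m matrix to flatten.
#' @param v vector to reshape.
#' @param n,ncol output dimensions (`ncol` defaults to `n`).
#' @return `flatten_rm` a vector; `unflatten_rm` an `n` x `ncol` matrix.
#' @export
flatten_rm <- function(m) as.vector(t(m))

#' @rdname flatten_rm
#' @export
unflatten_rm <- function(v, n, ncol = n) matrix(v, n, ncol, byrow = TRUE)
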