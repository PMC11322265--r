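# Demonstration targets (annuli, gradients, tumour-stroma interfaces) and the
# reproduce-and-score closed loop.

#' Demonstration target specification
#'
#' Three families of target strain fields:
#' * `annuli` — concentric rings of distinct strain levels (vessel-like
#'   circular tissue structures). `radii` are increasing radius fractions of
#'   the field width; `levels` are the display-scale strain levels inside each
#'   successive boundary, innermost first; outside the last ring the field sits
#'   at `background`.
#' * `gradient` — a unidirectional linear strain ramp (`horizontal` varies
#'   along x, `vertical` along y) between `levels[1]` and `levels[2]`.
#' * `interface` — a smooth closed tumour-stroma-like boundary: a
#'   Fourier-perturbed ellipse with seeded harmonic coefficients, `levels[1]`
#'   inside and `levels[2]` outside.
#'
#' Discrete-level targets are rendered with a boundary softening of `soften`
#' device pixels (default half the actuator pitch): physical strain fields are
#' continuous, and a hard discontinuity is not representable by the device at
#' any drive voltage.
#'
#' @param kind `"annuli"`, `"gradient"` or `"interface"`.
#' @param radii increasing radius fractions (annuli).
#' @param levels strain levels on the display scale (meaning depends on
#'   `kind`; defaults: annuli 65/45/25 inner to outer, gradient and interface
#'   span the reachable range).
#' @param background outside strain level for annuli/interface; defaults to
#'   the reachable minimum.
#' @param direction gradient direction.
#' @param seed seed for the interface harmonics.
#' @param n_harmonics,amplitude interface perturbation harmonics `2..n` and
#'   their relative amplitude.
#' @param soften boundary softening in device-pixel units (0 disables).
#' @param size render size in pixels.
#' @return List of class `target_spec`.
#' @export
target_spec <- function(kind = c("annuli", "gradient", "interface"),
                        radii = c(0.15, 0.30, 0.45),
                        levels = NULL, background = NULL,
                        direction = c("horizontal", "vertical"),
                        seed = 1L, n_harmonics = 4L, amplitude = 0.18,
                        soften = 0.5, size = NULL) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  if (kind == "annuli" && any(diff(radii) <= 0))
    stop("annuli radii must be strictly increasing")
  structure(list(kind = kind, radii = radii, levels = levels,
                 background = background, direction = direction,
                 seed = as.integer(seed), n_harmonics = as.integer(n_harmonics),
                 amplitude = amplitude, soften = soften, size = size),
            class = "target_spec")
}

#' Render a demonstration target as a grayscale strain image
#'
#' @param spec a [target_spec()].
#' @param config a [dea_config()].
#' @param curve a [dea_curve()] (supplies the reachable-range defaults).
#' @return Grayscale matrix in `[0, 1]` (`spec$size` or `lr_size` per side).
#' @examples
#' img <- make_target(target_spec("gradient"))
#' dim(img)
#' @export
make_target <- function(spec, config = dea_config(), curve = dea_curve()) {
  size <- if (is.null(spec$size)) config$lr_size else as.integer(spec$size)
  rng <- reachable_strain_range(curve, c(config$voltage_min, config$voltage_max))
  lv <- spec$levels
  bg <- if (is.null(spec$background)) rng[1] else spec$background
  check_levels <- function(x) {
    if (any(x < rng[1] - 1e-6) || any(x > rng[2] + 1e-6))
      stop(sprintf("strain levels must lie in the reachable range [%.4g, %.4g]",
                   rng[1], rng[2]))
    x
  }
  pos <- (seq_len(size) - 0.5) / size
  eps <- switch(spec$kind,
    gradient = {
      if (is.null(lv)) lv <- rng
      check_levels(lv)
      ramp <- seq(lv[1], lv[2], length.out = size)
      if (spec$direction == "horizontal") matrix(ramp, size, size, byrow = TRUE)
      else matrix(ramp, size, size)
    },
    annuli = {
      if (is.null(lv)) lv <- c(65, 45, 25)
      if (length(lv) != length(spec$radii))
        stop("need one strain level per annulus radius")
      check_levels(c(lv, bg))
      d <- sqrt(outer((pos - 0.5)^2, (pos - 0.5)^2, "+"))
      m <- matrix(bg, size, size)
      for (i in rev(seq_along(spec$radii))) m[d < spec$radii[i]] <- lv[i]
      m
    },
    interface = {
      if (is.null(lv)) lv <- c(0.8 * rng[2], rng[1] + 0.1 * diff(rng))
      check_levels(c(lv, bg))
      old <- get0(".Random.seed", globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(spec$seed)
      ks <- seq(2L, spec$n_harmonics)
      ak <- stats::runif(length(ks), -spec$amplitude, spec$amplitude) / sqrt(ks)
      ph <- stats::runif(length(ks), 0, 2 * pi)
      ecc <- stats::runif(1, 0.75, 1.3)
      r0 <- 0.28
      xg <- matrix(pos - 0.5, size, size, byrow = TRUE)
      yg <- matrix(pos - 0.5, size, size)
      th <- atan2(yg, xg * ecc)
      rb <- r0 * (1 + Reduce(`+`, Map(function(a, k, p) a * cos(k * th + p),
                                      ak, ks, ph)))
      rb <- pmax(rb, 0.05)  # keeps the closed curve star-shaped (no self-crossing)
      ifelse(sqrt((xg * ecc)^2 + yg^2) < rb, lv[1], lv[2])
    })
  if (spec$kind != "gradient" && spec$soften > 0) {
    K <- smoothing_matrix(size, spec$soften * size / config$grid_n)
    eps <- K %*% eps %*% t(K)
  }
  render_gray(eps, config)
}

#' Reproduce a target strain field through the inverse-control loop
#'
#' Predicts the voltage array for the target with the inverse model, applies it
#' to the surrogate device, and scores the reproduction against the target by
#' SSIM on preprocessed low-resolution grayscale images.
#'
#' @param target a grayscale matrix (values in `[0, 1]`) or a [target_spec()].
#' @param model a trained `inverse_model` for the requested axis.
#' @param params a [ssim_params()].
#' @return List with `voltages`, `field` (the reproduced [strain_field] of the
#'   model's axis), `report` (a `ssim_report`), and the two preprocessed
#'   images `target_prep`, `reproduced_prep`.
#' @export
reproduce <- function(target, model, params = ssim_params()) {
  config <- model$config
  if (inherits(target, "target_spec"))
    target <- make_target(target, config, model$curve)
  v <- predict_voltages(model, target)
  sim <- dea_simulate(v, config, model$curve, resolution = config$lr_size)
  field <- sim[[model$axis]]
  tp <- preprocess_image(target, config, flatten = FALSE)
  rp <- preprocess_image(field, config, flatten = FALSE)
  structure(list(voltages = v, field = field,
                 report = ssim_report(tp, rp, params),
                 target_prep = tp, reproduced_prep = rp),
            class = "reproduction")
}

#' @export
print.reproduction <- function(x, ...) {
  cat(sprintf("<reproduction> axis %s, SSIM %.4f\n",
              toupper(x$field$axis), x$report$mean_ssim))
  invisible(x)
}
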