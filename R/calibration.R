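#' Dual-Gaussian voltage-strain calibration curve
#'
#' The single-pixel actuation response of the DEA membrane is calibrated as a
#' sum of two Gaussians of the drive voltage,
#' \deqn{\epsilon(V) = a_1 e^{-((V-b_1)/c_1)^2} + a_2 e^{-((V-b_2)/c_2)^2},}
#' with both centres \eqn{b_1, b_2} beyond the operating voltage range so that
#' the curve is strictly increasing on it. The defaults are the calibration of
#' the reference device (strain in percent-like display units, voltage in kV).
#'
#' @param a1,b1,c1,a2,b2,c2 the six fit parameters.
#' @return An object of class `dea_curve`.
#' @examples
#' curve <- dea_curve()
#' strain_from_voltage(c(0, 7.1), curve)
#' @export
dea_curve <- function(a1 = 7.756e15, b1 = 24.1, c1 = 2.964,
                      a2 = 47.69, b2 = 10.18, c2 = 4.401) {
  if (c1 <= 0 || c2 <= 0) stop("Gaussian widths c1, c2 must be positive")
  structure(list(a1 = a1, b1 = b1, c1 = c1, a2 = a2, b2 = b2, c2 = c2),
            class = "dea_curve")
}

#' @export
print.dea_curve <- function(x, ...) {
  cat("<dea_curve> strain(V) = a1 exp(-((V-b1)/c1)^2) + a2 exp(-((V-b2)/c2)^2)\n")
  cat(sprintf("  a1 = %.4g  b1 = %.4g  c1 = %.4g\n", x$a1, x$b1, x$c1))
  cat(sprintf("  a2 = %.4g  b2 = %.4g  c2 = %.4g\n", x$a2, x$b2, x$c2))
  invisible(x)
}

#' Engineering to true (logarithmic) strain
#'
#' Converts an engineering strain `e` to the corresponding true strain
#' `ln(1 + e)`. A 100% biaxial engineering prestretch is a true strain of
#' `ln 2 = 0.6931` (69.31%).
#'
#' @param e engineering strain (dimensionless); must exceed -1.
#' @return True strain, same shape as `e`.
#' @examples
#' engineering_to_true_strain(1.0) # 0.6931
#' @export
engineering_to_true_strain <- function(e) {
  if (any(e <= -1)) stop("engineering strain must exceed -1")
  log(1 + e)
}

#' Strain produced by a drive voltage
#'
#' Evaluates the dual-Gaussian calibration at voltage `V` (kV).
#'
#' @param V voltage(s) in kV, inside `limits`.
#' @param curve a [dea_curve()].
#' @param limits operating voltage range; set to `NULL` to skip range checks
#'   (used internally when evaluating the raw curve outside the device range).
#' @return Strain in the calibration's output units.
#' @export
strain_from_voltage <- function(V, curve = dea_curve(), limits = c(0, 7.1)) {
  if (!is.null(limits) &&
      (any(V < limits[1] - 1e-9) || any(V > limits[2] + 1e-9)))
    stop(sprintf("voltage outside operating range [%g, %g] kV",
                 limits[1], limits[2]))
  curve$a1 * exp(-((V - curve$b1) / curve$c1)^2) +
    curve$a2 * exp(-((V - curve$b2) / curve$c2)^2)
}

#' Reachable strain interval of a calibration over the operating range
#'
#' @inheritParams strain_from_voltage
#' @return Numeric length-2 vector `c(min, max)`.
#' @export
reachable_strain_range <- function(curve = dea_curve(), limits = c(0, 7.1)) {
  strain_from_voltage(limits, curve, limits)
}

#' Voltage required to reach a target strain
#'
#' Inverts the (strictly increasing) calibration curve by vectorized bisection
#' on the operating range; the result is accurate to ~1e-12 kV.
#'
#' @param eps strain value(s) within the reachable range of the curve.
#' @param curve a [dea_curve()].
#' @param limits operating voltage range in kV.
#' @return Voltage(s) in kV.
#' @examples
#' voltage_from_strain(strain_from_voltage(3.5), dea_curve()) # 3.5
#' @export
voltage_from_strain <- function(eps, curve = dea_curve(), limits = c(0, 7.1)) {
  rng <- reachable_strain_range(curve, limits)
  if (any(eps < rng[1] - 1e-9) || any(eps > rng[2] + 1e-9))
    stop(sprintf("strain outside reachable interval [%.6g, %.6g]",
                 rng[1], rng[2]))
  lo <- rep(limits[1], length(eps))
  hi <- rep(limits[2], length(eps))
  for (i in seq_len(52)) {
    mid <- (lo + hi) / 2
    below <- strain_from_voltage(mid, curve, NULL) < eps
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  out <- (lo + hi) / 2
  attributes(out) <- attributes(eps)
  out
}

# ---- scalar tanh basis fit --------------------------------------------------
# Fits y ~ b0 + sum_j w_j tanh(a_j x + c_j) by BFGS over (a, c) with the
# amplitudes solved linearly (variable projection). Deterministic multistart.
# Used to seed MLP hidden layers with the calibration nonlinearity.
fit_scalar_tanh <- function(x, y, n_units = 2, n_starts = 8) {
  J <- n_units
  obj <- function(p) {
    B <- cbind(1, tanh(outer(x, p[1:J]) + rep(p[(J + 1):(2 * J)], each = length(x))))
    f <- tryCatch(stats::lm.fit(B, y), error = function(e) NULL)
    if (is.null(f) || anyNA(f$coefficients)) return(sum((y - mean(y))^2))
    sum(f$residuals^2)
  }
  sx <- stats::sd(x)
  best <- NULL
  best_v <- Inf
  for (s in seq_len(n_starts)) {
    set.seed(1000 + s)
    p0 <- c(stats::runif(J, 0.05, 2) / sx, stats::runif(J, -3, 1))
    r <- tryCatch(stats::optim(p0, obj, method = "BFGS",
                               control = list(maxit = 300)),
                  error = function(e) NULL)
    if (!is.null(r) && r$value < best_v) {
      best_v <- r$value
      best <- r$par
    }
  }
  a <- best[1:J]
  cc <- best[(J + 1):(2 * J)]
  B <- cbind(1, tanh(outer(x, a) + rep(cc, each = length(x))))
  w <- stats::lm.fit(B, y)$coefficients
  list(a = a, c = cc, w0 = w[1], w = w[-1],
       rmse = sqrt(best_v / length(x)))
}

#' Fit the dual-Gaussian calibration to voltage-strain samples
#'
#' Nonlinear least squares for the six parameters of the dual-Gaussian model.
#' Centres and log-widths are optimized by BFGS from a deterministic set of
#' neutral starting points (centres seeded in and beyond the upper half of the
#' sampled voltage range); amplitudes are profiled out by linear least squares
#' at each step (variable projection), with negative amplitudes penalized so
#' that the fitted curve keeps the physical form of two positive Gaussian
#' shoulders.
#'
#' @param V voltages (kV) of the calibration samples.
#' @param eps measured strains.
#' @return A list with elements `curve` (a [dea_curve()]), `r_squared`
#'   (coefficient of determination on the fitting data; `NA` with a warning for
#'   degenerate constant data) and `sse`.
#' @examples
#' V <- seq(0, 7.1, length.out = 50)
#' f <- fit_dual_gaussian(V, strain_from_voltage(V))
#' f$r_squared # >= 0.9998
#' @export
fit_dual_gaussian <- function(V, eps) {
  if (length(V) != length(eps)) stop("V and eps must have equal length")
  if (length(V) < 6) stop("need at least 6 calibration samples")
  sst <- sum((eps - mean(eps))^2)
  if (sst <= .Machine$double.eps * sum(eps^2)) {
    warning("calibration data are constant; R^2 undefined")
    return(list(curve = NULL, r_squared = NA_real_, sse = 0))
  }
  vmax <- max(V)
  vspan <- diff(range(V))
  basis <- function(b1, lc1, b2, lc2)
    cbind(exp(-((V - b1) / exp(lc1))^2), exp(-((V - b2) / exp(lc2))^2))
  obj <- function(p) {
    B <- basis(p[1], p[2], p[3], p[4])
    f <- tryCatch(stats::lm.fit(B, eps), error = function(e) NULL)
    if (is.null(f) || anyNA(f$coefficients)) return(sst)
    pen <- sum(pmin(f$coefficients, 0)^2) * 1e3
    sum(f$residuals^2) + pen
  }
  starts <- expand.grid(b1 = vmax * c(3.5, 2.5), b2 = vmax * c(1.45, 1.1),
                        lc1 = log(vspan * c(0.45)), lc2 = log(vspan * c(0.65, 0.35)))
  best <- NULL
  best_v <- Inf
  for (i in seq_len(nrow(starts))) {
    p0 <- c(starts$b1[i], starts$lc1[i], starts$b2[i], starts$lc2[i])
    r <- tryCatch(stats::optim(p0, obj, method = "BFGS",
                               control = list(maxit = 500, reltol = 1e-14)),
                  error = function(e) NULL)
    if (!is.null(r) && r$value < best_v) {
      best_v <- r$value
      best <- r$par
    }
  }
  B <- basis(best[1], best[2], best[3], best[4])
  f <- stats::lm.fit(B, eps)
  a <- pmax(f$coefficients, 0)
  sse <- sum((eps - B %*% a)^2)
  curve <- dea_curve(a1 = a[1], b1 = best[1], c1 = exp(best[2]),
                     a2 = a[2], b2 = best[3], c2 = exp(best[4]))
  list(curve = curve, r_squared = 1 - sse / sst, sse = sse)
}
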