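# Voltage-array sampling schemes and strain-distribution uniformity metrics.

#' Voltage sampling scheme
#'
#' `uniform_voltage` draws each of the 81 pixel voltages i.i.d. uniformly over
#' the operating range. `uniform_strain` draws per-pixel *strains* uniformly
#' over `[strain_lo, strain_hi]` and maps them through the inverse calibration
#' curve, so that the resulting simulated fields cover all strain levels evenly
#' (inverse-CDF sampling through the nonlinear calibration).
#'
#' @param kind `"uniform_strain"` (default) or `"uniform_voltage"`.
#' @param seed integer seed making the scheme reproducible.
#' @param strain_lo,strain_hi sampled-strain bounds; default to the reachable
#'   strain range of the curve over the operating voltages.
#' @return An object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(kind = c("uniform_strain", "uniform_voltage"),
                            seed = 1L, strain_lo = NULL, strain_hi = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, seed = as.integer(seed),
                 strain_lo = strain_lo, strain_hi = strain_hi),
            class = "sampling_scheme")
}

scheme_strain_bounds <- function(scheme, curve, config) {
  rng <- reachable_strain_range(curve, c(config$voltage_min, config$voltage_max))
  lo <- if (is.null(scheme$strain_lo)) rng[1] else scheme$strain_lo
  hi <- if (is.null(scheme$strain_hi)) rng[2] else scheme$strain_hi
  if (lo >= hi) stop("strain_lo must be below strain_hi")
  if (lo < rng[1] - 1e-9 || hi > rng[2] + 1e-9)
    stop(sprintf("strain bounds outside reachable interval [%.6g, %.6g]",
                 rng[1], rng[2]))
  c(lo, hi)
}

#' Sample voltage input arrays
#'
#' @param n number of arrays to draw.
#' @param scheme a [sampling_scheme()].
#' @param curve a [dea_curve()].
#' @param config a [dea_config()].
#' @return List of `n` [voltage_array()] objects.
#' @examples
#' v <- sample_voltage_arrays(2, sampling_scheme(seed = 7))
#' range(v[[1]])
#' @export
sample_voltage_arrays <- function(n, scheme = sampling_scheme(),
                                  curve = dea_curve(), config = dea_config()) {
  if (n < 1) stop("n must be at least 1")
  k <- config$grid_n^2
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(scheme$seed)
  if (scheme$kind == "uniform_voltage") {
    V <- matrix(stats::runif(n * k, config$voltage_min, config$voltage_max), n, k)
  } else {
    bounds <- scheme_strain_bounds(scheme, curve, config)
    eps <- matrix(stats::runif(n * k, bounds[1], bounds[2]), n, k)
    V <- matrix(voltage_from_strain(as.vector(eps), curve,
                                    c(config$voltage_min, config$voltage_max)),
                n, k)
  }
  lapply(seq_len(n), function(i) voltage_array(V[i, ], config))
}

#' Strain at the centre of each actuator pixel
#'
#' Bilinear interpolation of the field at the 81 pixel-centre points,
#' returned row-major.
#'
#' @param field a [strain_field] or square matrix of strain values.
#' @param config a [dea_config()].
#' @return Numeric vector of length `grid_n^2`.
#' @export
extract_center_strains <- function(field, config = dea_config()) {
  if (inherits(field, "strain_field")) field <- field$values
  size <- nrow(field)
  if (size < config$grid_n) stop("field smaller than the device grid")
  ctr <- pixel_centers(size, config$grid_n)
  r0 <- pmin(floor(ctr), size - 1)
  fr <- ctr - r0
  out <- matrix(0, config$grid_n, config$grid_n)
  for (i in seq_len(config$grid_n)) {
    for (j in seq_len(config$grid_n)) {
      out[i, j] <-
        field[r0[i], r0[j]] * (1 - fr[i]) * (1 - fr[j]) +
        field[r0[i] + 1, r0[j]] * fr[i] * (1 - fr[j]) +
        field[r0[i], r0[j] + 1] * (1 - fr[i]) * fr[j] +
        field[r0[i] + 1, r0[j] + 1] * fr[i] * fr[j]
    }
  }
  flatten_rm(out)
}

#' Uniformity metrics of a pooled strain distribution
#'
#' Histograms the pooled strain values into `n_bins` equal-width bins over
#' `range` and returns the sample standard deviation of the bin probabilities
#' and the Shannon entropy (natural log, with `0 log 0 = 0`). For a perfectly
#' uniform occupancy the standard deviation is 0 and the entropy is
#' `log(n_bins)`.
#'
#' @param strains pooled strain values (length at least 2).
#' @param n_bins number of histogram bins (default 7).
#' @param range length-2 bin range; defaults to the reachable strain range of
#'   the default calibration.
#' @return List with `std_of_probabilities`, `entropy`, and `probabilities`.
#' @export
strain_distribution_metrics <- function(strains, n_bins = 7,
                                        range = reachable_strain_range()) {
  if (length(strains) < 2) stop("need at least 2 strain values")
  if (n_bins < 2) stop("need at least 2 bins")
  if (diff(base::range(strains)) <= .Machine$double.eps * max(abs(strains), 1)) {
    warning("degenerate strain distribution: all values in one bin")
    p <- c(1, rep(0, n_bins - 1))
    return(list(std_of_probabilities = stats::sd(p), entropy = 0,
                probabilities = p))
  }
  breaks <- seq(range[1], range[2], length.out = n_bins + 1)
  clipped <- pmin(pmax(strains, range[1]), range[2])
  counts <- tabulate(findInterval(clipped, breaks, all.inside = TRUE), n_bins)
  p <- counts / sum(counts)
  ent <- -sum(ifelse(p > 0, p * log(p), 0))
  list(std_of_probabilities = stats::sd(p), entropy = ent, probabilities = p)
}
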