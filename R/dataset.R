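# Training/test dataset construction and on-disk persistence.

# tiny polynomial rolling hash for provenance stamps (no digest dependency)
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(format(x, digits = 15), collapse = "\x1f")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

config_stamp <- function(config, curve, scheme) {
  fnv1a(c(unlist(config, use.names = TRUE), unlist(curve),
          scheme$kind, scheme$seed,
          if (!is.null(scheme$strain_lo)) scheme$strain_lo,
          if (!is.null(scheme$strain_hi)) scheme$strain_hi))
}

#' Build a surrogate strain-field dataset
#'
#' Samples `n_train + n_test` voltage arrays with the given scheme, simulates
#' each with the surrogate device, and stores grayscale renderings of the X-
#' and Y-direction strain fields at low resolution (and optionally at high
#' resolution). Fully deterministic given the scheme's seed.
#'
#' @param n_train,n_test split sizes (the reference protocol is 10000 / 100).
#' @param scheme a [sampling_scheme()].
#' @param config a [dea_config()].
#' @param curve a [dea_curve()].
#' @param include_hr also render and keep the high-resolution fields (memory:
#'   `hr_size^2` doubles per sample and axis; meant for the super-resolution
#'   stage at desk scale, not for the 10k run).
#' @return A `dea_dataset`: list with matrices `voltages` (`n` x `grid_n^2`,
#'   row-major pixel order, kV), `lr_x`, `lr_y` (`n` x `lr_size^2` gray levels),
#'   optionally `hr_x`, `hr_y`, a `split` factor, and provenance fields.
#' @examples
#' ds <- build_dataset(4, 2, sampling_scheme(seed = 1),
#'                     config = dea_config(lr_size = 30L, hr_size = 240L))
#' table(ds$split)
#' @export
build_dataset <- function(n_train = 10000, n_test = 100,
                          scheme = sampling_scheme(),
                          config = dea_config(), curve = dea_curve(),
                          include_hr = FALSE) {
  if (n_train < 1 || n_test < 1) stop("split sizes must be at least 1")
  n <- n_train + n_test
  arrays <- sample_voltage_arrays(n, scheme, curve, config)
  k <- config$grid_n^2
  lr2 <- config$lr_size^2
  voltages <- matrix(0, n, k)
  lr_x <- matrix(0, n, lr2)
  lr_y <- matrix(0, n, lr2)
  hr_x <- if (include_hr) matrix(0, n, config$hr_size^2) else NULL
  hr_y <- if (include_hr) matrix(0, n, config$hr_size^2) else NULL
  vlim <- c(config$voltage_min, config$voltage_max)
  for (i in seq_len(n)) {
    voltages[i, ] <- flatten_rm(unclass(arrays[[i]]))
    eps <- strain_from_voltage(unclass(arrays[[i]]), curve, vlim)
    f <- simulate_strain(eps, config, config$lr_size)
    lr_x[i, ] <- flatten_rm(render_gray(f$x, config))
    lr_y[i, ] <- flatten_rm(render_gray(f$y, config))
    if (include_hr) {
      fh <- simulate_strain(eps, config, config$hr_size)
      hr_x[i, ] <- flatten_rm(render_gray(fh$x, config))
      hr_y[i, ] <- flatten_rm(render_gray(fh$y, config))
    }
  }
  ds <- list(voltages = voltages, lr_x = lr_x, lr_y = lr_y,
             hr_x = hr_x, hr_y = hr_y,
             split = factor(rep(c("train", "test"), c(n_train, n_test)),
                            levels = c("train", "test")),
             config = config, curve = curve, scheme = scheme,
             stamp = config_stamp(config, curve, scheme))
  class(ds) <- "dea_dataset"
  ds
}

#' @export
print.dea_dataset <- function(x, ...) {
  cat(sprintf("<dea_dataset> %d samples (%d train / %d test), lr %d px%s\n",
              nrow(x$voltages), sum(x$split == "train"), sum(x$split == "test"),
              x$config$lr_size,
              if (!is.null(x$hr_x)) sprintf(", hr %d px", x$config$hr_size) else ""))
  cat(sprintf("  scheme %s, seed %d, stamp %s\n",
              x$scheme$kind, x$scheme$seed, x$stamp))
  invisible(x)
}

# axis accessors ("x"/"y", "lr"/"hr") -> image matrix n x px^2
dataset_images <- function(ds, axis = c("x", "y"), res = c("lr", "hr")) {
  axis <- match.arg(axis)
  res <- match.arg(res)
  m <- ds[[paste0(res, "_", axis)]]
  if (is.null(m)) stop(sprintf("dataset has no %s %s images", res, axis))
  m
}

#' Persist a dataset to disk
#'
#' Writes `manifest.json`, `voltages.csv` (columns `v00..v88`, row-major pixel
#' order) and one 16-bit PGM image per sample and axis.
#'
#' @param ds a `dea_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly. `read_dataset` returns the reconstructed
#'   `dea_dataset`.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(ds$voltages)
  k <- sqrt(ncol(ds$voltages))
  cn <- as.vector(t(outer(seq_len(k) - 1, seq_len(k) - 1,
                          function(i, j) sprintf("v%d%d", i, j))))
  vf <- file.path(dir, "voltages.csv")
  utils::write.table(stats::setNames(as.data.frame(ds$voltages), cn), vf,
                     sep = ",", row.names = FALSE, quote = FALSE)
  lrs <- ds$config$lr_size
  for (i in seq_len(n)) {
    for (ax in c("x", "y")) {
      write_pgm(unflatten_rm(ds[[paste0("lr_", ax)]][i, ], lrs),
                file.path(dir, sprintf("lr_%s_%05d.pgm", ax, i)))
      if (!is.null(ds$hr_x))
        write_pgm(unflatten_rm(ds[[paste0("hr_", ax)]][i, ], ds$config$hr_size),
                  file.path(dir, sprintf("hr_%s_%05d.pgm", ax, i)))
    }
  }
  manifest <- list(
    n_train = sum(ds$split == "train"), n_test = sum(ds$split == "test"),
    scheme = ds$scheme$kind, seed = ds$scheme$seed, stamp = ds$stamp,
    include_hr = !is.null(ds$hr_x),
    config = unclass(ds$config), curve = unclass(ds$curve),
    units = "strain: calibration display units; voltage: kV",
    display_range = c(ds$config$strain_display_min, ds$config$strain_display_max))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  config <- do.call(dea_config, man$config[names(man$config) %in%
                                             names(formals(dea_config))])
  curve <- do.call(dea_curve, as.list(man$curve))
  scheme <- sampling_scheme(man$scheme, man$seed)
  n <- man$n_train + man$n_test
  voltages <- as.matrix(utils::read.csv(file.path(dir, "voltages.csv")))
  dimnames(voltages) <- NULL
  rd <- function(res, ax, size) {
    t(vapply(seq_len(n), function(i) {
      flatten_rm(read_pgm(file.path(dir, sprintf("%s_%s_%05d.pgm", res, ax, i))))
    }, numeric(size^2)))
  }
  ds <- list(voltages = voltages,
             lr_x = rd("lr", "x", config$lr_size),
             lr_y = rd("lr", "y", config$lr_size),
             hr_x = if (isTRUE(man$include_hr)) rd("hr", "x", config$hr_size),
             hr_y = if (isTRUE(man$include_hr)) rd("hr", "y", config$hr_size),
             split = factor(rep(c("train", "test"), c(man$n_train, man$n_test)),
                            levels = c("train", "test")),
             config = config, curve = curve, scheme = scheme, stamp = man$stamp)
  class(ds) <- "dea_dataset"
  ds
}
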