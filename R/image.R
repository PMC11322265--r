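# Grayscale rendering, resampling and portable-graymap I/O.

#' Render a strain map as a grayscale image
#'
#' Maps strain linearly from `[strain_display_min, strain_display_max]`
#' onto `[0, 1]`, clipping outside the range.
#'
#' @param values matrix of strain values (or a [strain_field]).
#' @param config a [dea_config()] supplying the display range.
#' @return Matrix of gray levels in `[0, 1]`.
#' @export
render_gray <- function(values, config = dea_config()) {
  if (inherits(values, "strain_field")) values <- values$values
  g <- (values - config$strain_display_min) /
    (config$strain_display_max - config$strain_display_min)
  pmin(pmax(g, 0), 1)
}

#' @rdname render_gray
#' @param gray matrix of gray levels in `[0, 1]`.
#' @export
gray_to_strain <- function(gray, config = dea_config()) {
  config$strain_display_min +
    gray * (config$strain_display_max - config$strain_display_min)
}

# 1-D area-overlap resampling weights (n_out x n_in, rows sum to 1).
# Exact box-average for downsampling; linear-overlap interpolation otherwise.
resize_weights <- function(n_out, n_in) {
  W <- matrix(0, n_out, n_in)
  r <- n_in / n_out
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * r
    hi <- i * r
    for (j in floor(lo):min(ceiling(hi) - 1, n_in - 1)) {
      W[i, j + 1] <- max(0, min(hi, j + 1) - max(lo, j))
    }
  }
  W / rowSums(W)
}

#' Resize a matrix by area-weighted averaging
#'
#' @param m input matrix.
#' @param size output side length (output is `size` x `size`).
#' @return Resized matrix.
#' @export
resize_area <- function(m, size) {
  Wr <- resize_weights(size, nrow(m))
  Wc <- resize_weights(size, ncol(m))
  Wr %*% m %*% t(Wc)
}

# Area-overlap weights resampling the *fractional* source interval
# [lo_frac, hi_frac] (in units of the full side) onto n_out cells. Used for
# the boundary-margin crop so that low- and high-resolution preprocessing are
# geometrically identical regardless of pixel counts.
frac_resize_weights <- function(n_out, n_in, lo_frac, hi_frac) {
  lo <- lo_frac * n_in
  hi <- hi_frac * n_in
  W <- matrix(0, n_out, n_in)
  r <- (hi - lo) / n_out
  for (i in seq_len(n_out)) {
    a <- lo + (i - 1) * r
    b <- lo + i * r
    for (j in max(0, floor(a)):min(ceiling(b) - 1, n_in - 1)) {
      W[i, j + 1] <- max(0, min(b, j + 1) - max(a, j))
    }
  }
  W / rowSums(W)
}

# Catmull-Rom bicubic interpolation weights for upscaling by integer factor.
bicubic_weights <- function(n_out, n_in) {
  kern <- function(x) {
    x <- abs(x)
    ifelse(x <= 1, 1.5 * x^3 - 2.5 * x^2 + 1,
           ifelse(x < 2, -0.5 * x^3 + 2.5 * x^2 - 4 * x + 2, 0))
  }
  W <- matrix(0, n_out, n_in)
  r <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * r + 0.5   # centre position in source pixel coords
    j0 <- floor(src) - 1
    js <- j0:(j0 + 3)
    w <- kern(src - js)
    js <- pmin(pmax(js, 1), n_in)  # clamp border samples
    for (k in 1:4) W[i, js[k]] <- W[i, js[k]] + w[k]
  }
  W / rowSums(W)
}

#' Bicubic upscaling (classical super-resolution baseline)
#'
#' @param m input matrix (grayscale).
#' @param size output side length.
#' @return Upscaled `size` x `size` matrix.
#' @export
bicubic_upscale <- function(m, size) {
  Wr <- bicubic_weights(size, nrow(m))
  Wc <- bicubic_weights(size, ncol(m))
  Wr %*% m %*% t(Wc)
}

#' Preprocess a strain-field image for model input
#'
#' Crops away the clamped boundary taper (the outer `boundary_margin` fraction
#' on each side), resizes the remaining active region to `lr_size` x `lr_size`
#' by area interpolation, clips intensities to `[0, 1]` and flattens row-major
#' into a `lr_size^2` vector.
#'
#' @param image a [strain_field], or a single-channel matrix of gray levels in
#'   `[0, 1]` with at least `lr_size` pixels per side.
#' @param config a [dea_config()].
#' @param flatten return the row-major vector (default) or the
#'   `lr_size` x `lr_size` matrix.
#' @param out_size output side length; defaults to `lr_size` (the model-input
#'   resolution). The super-resolution stage uses `hr_size` to obtain the
#'   geometrically identical high-resolution view of the active region.
#' @return Numeric vector of length `out_size^2` (or matrix).
#' @export
preprocess_image <- function(image, config = dea_config(), flatten = TRUE,
                             out_size = config$lr_size) {
  if (inherits(image, "strain_field")) image <- render_gray(image, config)
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a single-channel numeric matrix (grayscale)")
  size <- nrow(image)
  if (size != ncol(image)) stop("image must be square")
  if (size < out_size)
    stop(sprintf("image side %d below the output size %d", size, out_size))
  W <- frac_resize_weights(out_size, size, config$boundary_margin,
                           1 - config$boundary_margin)
  out <- pmin(pmax(W %*% image %*% t(W), 0), 1)
  if (flatten) flatten_rm(out) else out
}

#' Read and write portable graymap (PGM) images
#'
#' 16-bit binary (`P5`) portable graymaps are the package's on-disk image
#' format: lossless for display-scale data, plain, and readable by any
#' scientific imaging stack. Gray levels in `[0, 1]` map onto `0..65535`.
#'
#' @param path file path.
#' @param gray matrix of gray levels in `[0, 1]`; rows are image rows.
#' @return `read_pgm` returns the gray-level matrix.
#' @export
write_pgm <- function(gray, path) {
  g <- round(pmin(pmax(gray, 0), 1) * 65535)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(ncol(g), nrow(g)), "65535"), con)
  v <- as.integer(flatten_rm(g))
  writeBin(as.raw(rbind(v %/% 256L, v %% 256L)), con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, 1)
  if (!magic %in% c("P5", "P2")) stop("not a PGM file: ", path)
  toks <- character(0)
  while (length(toks) < 3) {
    ln <- readLines(con, 1)
    ln <- sub("#.*", "", ln)
    toks <- c(toks, strsplit(trimws(ln), "\\s+")[[1]])
  }
  dims <- as.integer(toks[1:2])
  maxv <- as.integer(toks[3])
  npx <- dims[1] * dims[2]
  if (magic == "P5") {
    raw <- readBin(con, "raw", n = npx * (1 + (maxv > 255)))
    v <- if (maxv > 255) {
      m <- matrix(as.integer(raw), 2)
      m[1, ] * 256L + m[2, ]
    } else as.integer(raw)
  } else {
    v <- scan(con, what = integer(), n = npx, quiet = TRUE)
  }
  unflatten_rm(v / maxv, dims[2], dims[1])
}
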