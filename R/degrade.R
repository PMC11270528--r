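#' Degradation configuration
#'
#' Parameters of the HR -> LR degradation: a truncated Gaussian blur with a
#' (5, 7) kernel (rows = F1, cols = F2) followed by x2 areal down-sampling.
#' Sigmas default to `(kernel - 1) / 4` pixels, placing +/- 2 sigma at the
#' kernel edge.
#'
#' @param kernel_rows,kernel_cols odd positive kernel dimensions.
#' @param sigma_rows,sigma_cols Gaussian standard deviations in pixels.
#' @param factor integer down-sampling factor (must divide both grid dims).
#' @return An object of class `jres_degrade_config`.
#' @export
degrade_config <- function(kernel_rows = 5, kernel_cols = 7,
                           sigma_rows = (kernel_rows - 1) / 4,
                           sigma_cols = (kernel_cols - 1) / 4,
                           factor = 2) {
  kernel_rows <- as.integer(kernel_rows); kernel_cols <- as.integer(kernel_cols)
  if (kernel_rows < 1 || kernel_cols < 1 ||
      kernel_rows %% 2 == 0 || kernel_cols %% 2 == 0)
    stop("kernel dimensions must be odd and positive", call. = FALSE)
  if (sigma_rows <= 0 || sigma_cols <= 0)
    stop("sigmas must be positive", call. = FALSE)
  if (factor < 1) stop("factor must be >= 1", call. = FALSE)
  structure(list(kernel_rows = kernel_rows, kernel_cols = kernel_cols,
                 sigma_rows = sigma_rows, sigma_cols = sigma_cols,
                 factor = as.integer(factor)),
            class = "jres_degrade_config")
}

# normalized truncated 1D Gaussian kernel
gaussian_kernel_1d <- function(n, sigma) {
  h <- (n - 1) / 2
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

# 1D convolution along the rows (margin = 1) or columns (margin = 2) of a
# matrix with reflect padding (edge pixel duplicated)
conv1d_reflect <- function(g, kernel, margin) {
  n <- if (margin == 1) nrow(g) else ncol(g)
  p <- (length(kernel) - 1) / 2
  idx <- c(rev(seq_len(p)), seq_len(n), n + 1 - seq_len(p))
  gp <- if (margin == 1) g[idx, , drop = FALSE] else g[, idx, drop = FALSE]
  out <- 0
  for (t in seq_along(kernel)) {
    out <- out + kernel[t] *
      (if (margin == 1) gp[t + seq_len(n) - 1, , drop = FALSE]
       else gp[, t + seq_len(n) - 1, drop = FALSE])
  }
  out
}

#' Gaussian blur of a spectrum
#'
#' Discrete convolution with a normalized truncated Gaussian kernel (outer
#' product of two 1D kernels, so the 2D kernel sums to 1 and the convolution
#' is applied separably). Boundaries use reflect padding (edge row/column
#' duplicated), so a constant grid is reproduced exactly and the grid total
#' is preserved for interior-supported signals.
#'
#' @param s a [jres_spectrum()].
#' @param cfg a [degrade_config()].
#' @return blurred [jres_spectrum()], same dimensions.
#' @export
gaussian_blur <- function(s, cfg = degrade_config()) {
  stopifnot(inherits(s, "jres_spectrum"), inherits(cfg, "jres_degrade_config"))
  if (nrow(s$grid) < cfg$kernel_rows || ncol(s$grid) < cfg$kernel_cols)
    stop("grid smaller than the blur kernel", call. = FALSE)
  g <- conv1d_reflect(s$grid, gaussian_kernel_1d(cfg$kernel_rows, cfg$sigma_rows), 1)
  g <- conv1d_reflect(g, gaussian_kernel_1d(cfg$kernel_cols, cfg$sigma_cols), 2)
  out <- s
  out$grid <- float32_quantize(g)
  out
}

#' Areal down-sampling
#'
#' Each output pixel is the exact mean of its `factor x factor` source
#' block (areal interpolation for an integer factor on divisible grids).
#' Axis ranges are unchanged; pixel counts are divided by `factor`. The
#' global grid mean is preserved exactly.
#'
#' @param s a [jres_spectrum()].
#' @param factor integer factor dividing both grid dimensions.
#' @return down-sampled [jres_spectrum()].
#' @export
areal_downsample <- function(s, factor = 2) {
  stopifnot(inherits(s, "jres_spectrum"))
  factor <- as.integer(factor)
  if (factor == 1L) return(s)
  n1 <- nrow(s$grid); n2 <- ncol(s$grid)
  if (n1 %% factor != 0 || n2 %% factor != 0)
    stop(sprintf("factor %d does not divide grid dims %d x %d",
                 factor, n1, n2), call. = FALSE)
  m1 <- n1 %/% factor; m2 <- n2 %/% factor
  # average factor rows, then factor columns
  a <- colMeans(array(s$grid, c(factor, m1, n2)))          # m1 x n2
  g <- t(colMeans(array(t(a), c(factor, m2, m1))))         # m1 x m2
  jres_spectrum(g,
                jres_axis(m1, s$f1_axis$start, s$f1_axis$end, "Hz"),
                jres_axis(m2, s$f2_axis$start, s$f2_axis$end, "ppm"),
                s$observe_frequency, s$label)
}

#' Degrade an HR spectrum to its LR counterpart
#'
#' Gaussian blur followed by areal down-sampling: the construction used to
#' pair every simulated HR spectrum with an LR input, effectively halving
#' the resolution along both axes at the default x2 factor (e.g.
#' 256 x 16384 -> 128 x 8192).
#'
#' @param s HR [jres_spectrum()].
#' @param cfg a [degrade_config()].
#' @return LR [jres_spectrum()].
#' @export
degrade <- function(s, cfg = degrade_config()) {
  areal_downsample(gaussian_blur(s, cfg), cfg$factor)
}
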