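#' 2D J-Res spectrum container
#'
#' The universal currency of the package: a matrix of intensities (rows
#' indexed by F1, columns by F2) plus explicit axes. Intensities are held at
#' 32-bit float precision (values are quantized on construction), matching
#' the dynamic-range convention of processed J-Res data; all grid/axis
#' invariants are checked here and nowhere else.
#'
#' Row 0 (R index 1) corresponds to the F1 axis start, column 0 to the F2
#' axis start; all pixel coordinates in this package are 0-based `(row, col)`.
#'
#' @param grid numeric matrix, `f1_axis$n_points` rows by
#'   `f2_axis$n_points` columns, all finite.
#' @param f1_axis Hz-unit [jres_axis()] (J-coupling dimension).
#' @param f2_axis ppm-unit [jres_axis()] (chemical shift dimension).
#' @param observe_frequency spectrometer frequency in MHz (default 600).
#' @param label free-text label.
#' @return An object of class `jres_spectrum`.
#' @export
jres_spectrum <- function(grid, f1_axis, f2_axis, observe_frequency = 600,
                          label = "") {
  stopifnot(inherits(f1_axis, "jres_axis"), inherits(f2_axis, "jres_axis"))
  if (f1_axis$unit != "Hz" || f2_axis$unit != "ppm")
    stop("f1_axis must be in Hz and f2_axis in ppm", call. = FALSE)
  grid <- as.matrix(grid)
  if (nrow(grid) != f1_axis$n_points || ncol(grid) != f2_axis$n_points)
    stop(sprintf("grid is %d x %d but axes demand %d x %d",
                 nrow(grid), ncol(grid), f1_axis$n_points, f2_axis$n_points),
         call. = FALSE)
  if (!all(is.finite(grid)))
    stop("grid intensities must all be finite", call. = FALSE)
  if (!is.numeric(observe_frequency) || observe_frequency <= 0)
    stop("observe_frequency must be positive", call. = FALSE)
  storage.mode(grid) <- "double"
  structure(
    list(grid = float32_quantize(grid), f1_axis = f1_axis, f2_axis = f2_axis,
         observe_frequency = observe_frequency, label = as.character(label)[1]),
    class = "jres_spectrum"
  )
}

#' Quantize doubles to 32-bit float precision
#'
#' R stores numerics as doubles; this rounds each value to its nearest
#' float32 representation so that grids survive the native float32 container
#' bit-exactly. Shape attributes are preserved.
#'
#' @param x numeric vector/matrix/array.
#' @export
float32_quantize <- function(x) {
  d <- dim(x)
  q <- readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
               n = length(x), size = 4L)
  dim(q) <- d
  q
}

#' @export
print.jres_spectrum <- function(x, ...) {
  cat(sprintf("<jres_spectrum> %d x %d '%s'\n", nrow(x$grid), ncol(x$grid),
              x$label))
  cat(sprintf("  F1: %.4f to %.4f Hz | F2: %.4f to %.4f ppm | %g MHz\n",
              x$f1_axis$start, x$f1_axis$end,
              x$f2_axis$start, x$f2_axis$end, x$observe_frequency))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
dim.jres_spectrum <- function(x) dim(x$grid)

#' Mirror a spectrum about the J = 0 line
#'
#' Reverses the row (F1) order of the grid. Processed J-Res spectra are
#' symmetric about J = 0; with an even row count and a symmetric F1 range the
#' mirror plane lies between the two middle rows, so `flip_f1` is an exact
#' involution and leaves an ideally symmetric spectrum unchanged.
#'
#' @param spectrum a [jres_spectrum()].
#' @return the mirrored spectrum (axes unchanged).
#' @export
flip_f1 <- function(spectrum) {
  stopifnot(inherits(spectrum, "jres_spectrum"))
  out <- spectrum
  out$grid <- spectrum$grid[rev(seq_len(nrow(spectrum$grid))), , drop = FALSE]
  out
}

#' Image plot of a spectrum
#'
#' @param x a [jres_spectrum()].
#' @param ... passed to [graphics::image()].
#' @export
plot.jres_spectrum <- function(x, ...) {
  graphics::image(axis_coords(x$f2_axis), axis_coords(x$f1_axis),
                  t(x$grid), xlab = "F2 (ppm)", ylab = "F1 (Hz)",
                  main = x$label,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

# internal: relative asymmetry of a grid about the between-row mirror plane
grid_asymmetry <- function(grid) {
  m <- max(abs(grid))
  if (m == 0) return(0)
  max(abs(grid - grid[rev(seq_len(nrow(grid))), , drop = FALSE])) / m
}
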