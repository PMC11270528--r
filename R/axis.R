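#' Spectral axis descriptor
#'
#' An axis of a 2D J-Res spectrum: a uniformly sampled physical coordinate
#' range with an explicit unit. The F1 (indirect, J-coupling) axis is in Hz,
#' the F2 (direct, chemical shift) axis in ppm. Pixel `i` (0-based) is
#' centred at `start + (i + 0.5) * pixel_width`, so an even number of rows on
#' a symmetric F1 range places the J = 0 mirror plane exactly between the two
#' middle rows.
#'
#' @param n_points number of pixels along the axis (>= 1).
#' @param start physical coordinate of the left/top edge.
#' @param end physical coordinate of the right/bottom edge (must differ from
#'   `start`).
#' @param unit `"Hz"` (F1) or `"ppm"` (F2).
#' @return An object of class `jres_axis`.
#' @examples
#' f2 <- jres_axis(16384, -3.560, 13.129, "ppm")
#' pixel_width(f2)
#' @export
jres_axis <- function(n_points, start, end, unit = c("Hz", "ppm")) {
  unit <- match.arg(unit)
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 1L)
    stop("axis needs at least 1 point", call. = FALSE)
  if (!is.finite(start) || !is.finite(end) || start == end)
    stop("axis start and end must be finite and distinct", call. = FALSE)
  structure(
    list(n_points = n_points, start = start, end = end, unit = unit),
    class = "jres_axis"
  )
}

#' @export
print.jres_axis <- function(x, ...) {
  cat(sprintf("<jres_axis> %d points, %.6g to %.6g %s (%.6g %s/px)\n",
              x$n_points, x$start, x$end, x$unit, pixel_width(x), x$unit))
  invisible(x)
}

#' Signed physical width of one pixel
#'
#' @param axis a [jres_axis()].
#' @return `(end - start) / n_points`, in the axis unit per pixel.
#' @export
pixel_width <- function(axis) {
  stopifnot(inherits(axis, "jres_axis"))
  (axis$end - axis$start) / axis$n_points
}

#' Physical coordinates of pixel centres
#'
#' @param axis a [jres_axis()].
#' @return numeric vector of length `n_points`.
#' @export
axis_coords <- function(axis) {
  w <- pixel_width(axis)
  axis$start + (seq_len(axis$n_points) - 0.5) * w
}

#' Convert a pixel distance to a ppm distance
#'
#' @param d_pixels non-negative pixel distance.
#' @param axis a ppm-unit [jres_axis()] (typically the F2 axis).
#' @return distance in ppm (`d_pixels * |pixel width|`).
#' @examples
#' f2 <- jres_axis(16384, -3.560, 13.129, "ppm")
#' round_half_away(pixels_to_ppm(30, f2), 3) # 0.031
#' @export
pixels_to_ppm <- function(d_pixels, axis) {
  stopifnot(inherits(axis, "jres_axis"))
  if (axis$unit != "ppm")
    stop("pixels_to_ppm needs a ppm-unit axis, got unit '", axis$unit, "'",
         call. = FALSE)
  if (any(d_pixels < 0)) stop("pixel distance must be non-negative", call. = FALSE)
  d_pixels * abs(pixel_width(axis))
}

#' Convert a ppm distance to Hz
#'
#' One ppm corresponds to the observe frequency expressed in Hz, so the
#' conversion is simply `d_ppm * observe_frequency` (MHz).
#'
#' @param d_ppm distance in ppm.
#' @param observe_frequency spectrometer observe frequency in MHz (default 600).
#' @return distance in Hz.
#' @examples
#' ppm_to_hz(0.031, 600) # 18.6
#' @export
ppm_to_hz <- function(d_ppm, observe_frequency = 600) {
  if (!is.numeric(observe_frequency) || observe_frequency <= 0)
    stop("observe_frequency must be positive", call. = FALSE)
  d_ppm * observe_frequency
}

#' Round half away from zero
#'
#' Rounding convention used when comparing computed distances with printed
#' values (base R `round` rounds half to even, which does not reproduce
#' conventionally printed figures such as 0.031 ppm from 0.0305...).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
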