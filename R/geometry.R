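#' Detector geometry: the pixel-to-angle map
#'
#' A wedge-shaped incident beam maps incidence angle linearly onto detector
#' columns. The geometry holds the column count, the total angular window and
#' the incidence angle of column 0; the per-pixel step is
#' `span_deg / n_pixels`.
#'
#' The reference instrument images a 7.296 degree window onto 1280 columns,
#' i.e. 0.0057 degrees per pixel.
#'
#' @param n_pixels integer number of detector columns (>= 2).
#' @param span_deg total angular window in degrees (> 0).
#' @param start_deg incidence angle of pixel 0, in degrees. The absolute
#'   offset is an instrument calibration; curves can also be processed on a
#'   raw pixel axis by choosing `start_deg = 0` and `span_deg = n_pixels`.
#' @return An object of class `detector_geometry`.
#' @examples
#' geom <- detector_geometry(1280, 7.296, 60)
#' pixel_resolution(geom) # 0.0057
#' @export
detector_geometry <- function(n_pixels = 1280L, span_deg = 7.296,
                              start_deg = 60) {
  n_pixels <- as.integer(n_pixels)
  if (is.na(n_pixels) || n_pixels < 2L)
    stop_input("n_pixels must be an integer >= 2")
  if (!is.finite(span_deg) || span_deg <= 0)
    stop_input("span_deg must be > 0")
  if (!is.finite(start_deg))
    stop_input("start_deg must be finite")
  structure(list(n_pixels = n_pixels, span_deg = span_deg,
                 start_deg = start_deg),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf("<detector_geometry> %d px, %.4f deg span from %.4f deg (%.6f deg/px)\n",
              x$n_pixels, x$span_deg, x$start_deg, pixel_resolution(x)))
  invisible(x)
}

#' Angular resolution of a detector geometry
#'
#' @param geometry a [detector_geometry()].
#' @return degrees per pixel, `span_deg / n_pixels`.
#' @export
pixel_resolution <- function(geometry) {
  stopifnot(inherits(geometry, "detector_geometry"))
  geometry$span_deg / geometry$n_pixels
}

#' Convert pixel index to incidence angle
#'
#' Pixel indices are 0-based, matching detector column numbering: pixel 0 is
#' at `start_deg` and pixel `i` at `start_deg + i * span_deg / n_pixels`.
#'
#' @param geometry a [detector_geometry()].
#' @param pixel_index integer vector of 0-based column indices in
#'   `[0, n_pixels - 1]`.
#' @return incidence angle(s) in degrees.
#' @examples
#' pixel_to_angle(detector_geometry(1280, 7.296, 35), 640) # 38.648
#' @export
pixel_to_angle <- function(geometry, pixel_index) {
  stopifnot(inherits(geometry, "detector_geometry"))
  if (any(!is.finite(pixel_index)) ||
      any(pixel_index < 0) || any(pixel_index > geometry$n_pixels - 1))
    stop_input("pixel_index out of range [0, ", geometry$n_pixels - 1, "]")
  geometry$start_deg + pixel_index * pixel_resolution(geometry)
}

#' All pixel-centre angles of a geometry
#'
#' @param geometry a [detector_geometry()].
#' @return numeric vector of length `n_pixels`.
#' @export
geometry_angles <- function(geometry) {
  pixel_to_angle(geometry, seq_len(geometry$n_pixels) - 1L)
}
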