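#' Detector noise specification
#'
#' The three-frame acquisition (dark / TE / TM) is emulated with an additive
#' Gaussian dark term and a multiplicative Gaussian shot-like term on the
#' illuminated frames. Identical seeds give bit-identical frames.
#'
#' Defaults emulate a 16-bit CMOS sensor: a dark pedestal of 400 counts with
#' 8 counts of read noise, and 1\% multiplicative intensity noise.
#'
#' @param dark_offset mean dark level in counts (>= 0).
#' @param dark_sd standard deviation of the additive dark noise (>= 0).
#' @param shot_sd standard deviation of the multiplicative intensity noise,
#'   as a fraction of the signal (>= 0).
#' @param seed integer random seed; `NULL` leaves the RNG stream alone.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(dark_offset = 400, dark_sd = 8, shot_sd = 0.01,
                       seed = 1L) {
  if (!is.finite(dark_offset) || dark_offset < 0)
    stop_input("dark_offset must be >= 0")
  if (!is.finite(dark_sd) || dark_sd < 0) stop_input("dark_sd must be >= 0")
  if (!is.finite(shot_sd) || shot_sd < 0) stop_input("shot_sd must be >= 0")
  structure(list(dark_offset = dark_offset, dark_sd = dark_sd,
                 shot_sd = shot_sd,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "noise_spec")
}

#' Zero-noise specification
#' @return a [noise_spec()] with all noise terms zero and no dark pedestal.
#' @export
noise_free <- function() noise_spec(0, 0, 0, seed = NULL)

#' Raw detector image triplet
#'
#' @param dark,te,tm numeric matrices of identical shape holding the dark,
#'   TE-mode and TM-mode intensity frames (rows x detector columns).
#' @return An object of class `raw_image_set`.
#' @export
raw_image_set <- function(dark, te, tm) {
  for (m in list(dark, te, tm))
    if (!is.matrix(m) || !all(is.finite(m)))
      stop_input("frames must be finite numeric matrices")
  if (!identical(dim(dark), dim(te)) || !identical(dim(dark), dim(tm)))
    stop_input("dark, TE and TM frames must share one shape")
  if (min(dark, te, tm) < 0)
    stop_input("intensities must be >= 0")
  structure(list(dark = dark, te = te, tm = tm), class = "raw_image_set")
}

#' @export
print.raw_image_set <- function(x, ...) {
  cat(sprintf("<raw_image_set> %d x %d px, TM mean %.1f counts\n",
              nrow(x$tm), ncol(x$tm), mean(x$tm)))
  invisible(x)
}

#' Synthesize a dark/TE/TM detector image triplet
#'
#' Builds the three frames an angular-interrogation instrument records:
#' each detector column sees the stack's reflectance at its pixel angle,
#' scaled by `signal_level` counts of illumination, on top of the dark
#' pedestal. With zero noise, [normalize_images()] followed by
#' [extract_curve()] recovers [simulate_spr_curve()] exactly.
#'
#' @param stack an [optical_stack()].
#' @param geometry a [detector_geometry()].
#' @param n_rows number of detector rows (>= 1).
#' @param noise a [noise_spec()].
#' @param signal_level illumination scale in counts (TE plateau level).
#' @return a [raw_image_set()] of shape `n_rows x n_pixels`.
#' @export
synthesize_image_set <- function(stack, geometry, n_rows = 1024L,
                                 noise = noise_spec(),
                                 signal_level = 30000) {
  stopifnot(inherits(noise, "noise_spec"))
  n_rows <- as.integer(n_rows)
  if (is.na(n_rows) || n_rows < 1L) stop_input("n_rows must be >= 1")
  ang <- geometry_angles(geometry)
  if (min(ang) <= 0 || max(ang) >= 90)
    stop_input("geometry window must lie inside (0, 90) degrees")
  rtm <- fresnel_reflectance(stack, ang, "TM")
  rte <- fresnel_reflectance(stack, ang, "TE")
  np <- geometry$n_pixels
  with_seed(noise$seed, {
    gauss <- function(sd) {
      if (sd > 0) matrix(rnorm(n_rows * np, sd = sd), n_rows, np)
      else matrix(0, n_rows, np)
    }
    row_of <- function(v) matrix(v, n_rows, np, byrow = TRUE)
    dark <- noise$dark_offset + gauss(noise$dark_sd)
    te <- noise$dark_offset + gauss(noise$dark_sd) +
      row_of(signal_level * rte) * (1 + gauss(noise$shot_sd))
    tm <- noise$dark_offset + gauss(noise$dark_sd) +
      row_of(signal_level * rtm) * (1 + gauss(noise$shot_sd))
    raw_image_set(pmax(dark, 0), pmax(te, 0), pmax(tm, 0))
  })
}

#' Normalize a detector image triplet to a reflectance-ratio image
#'
#' Subtracts the dark frame from the TE and TM frames and divides:
#' `(TM - dark) / (TE - dark)`. Pixels whose TE - dark denominator falls at
#' or below `denom_floor` are marked `NA` and excluded from downstream
#' column averaging.
#'
#' @param raw a [raw_image_set()].
#' @param denom_floor smallest acceptable denominator; default is 1e-6 of
#'   the TE - dark dynamic range.
#' @return numeric matrix of ratio values with `NA` at invalid pixels.
#' @export
normalize_images <- function(raw, denom_floor = NULL) {
  stopifnot(inherits(raw, "raw_image_set"))
  den <- raw$te - raw$dark
  num <- raw$tm - raw$dark
  if (is.null(denom_floor)) {
    rng <- max(den) - min(den)
    denom_floor <- 1e-6 * if (rng > 0) rng else max(abs(den), 1)
  }
  if (!is.finite(denom_floor) || denom_floor <= 0)
    stop_input("denom_floor must be a small positive intensity")
  ratio <- num / den
  ratio[den <= denom_floor] <- NA_real_
  ratio
}

#' Extract an SPR curve from a ratio image
#'
#' Averages a horizontal band of rows per detector column and attaches the
#' pixel-to-angle map, mirroring the instrument protocol of averaging 100
#' rows of the final image. The default band is a 100-row stripe centred
#' vertically (or all rows for short images). Invalid (`NA`) pixels are
#' excluded from the mean; a column with no valid pixel is an error.
#'
#' @param ratio_image numeric matrix from [normalize_images()].
#' @param row_band inclusive 1-based row interval `c(first, last)`, or
#'   `NULL` for the default centred band.
#' @param geometry a [detector_geometry()] with `n_pixels == ncol(ratio_image)`.
#' @return an [spr_curve()] with one point per column.
#' @export
extract_curve <- function(ratio_image, row_band = NULL, geometry) {
  if (!is.matrix(ratio_image)) stop_input("ratio_image must be a matrix")
  stopifnot(inherits(geometry, "detector_geometry"))
  if (ncol(ratio_image) != geometry$n_pixels)
    stop_input("geometry n_pixels (", geometry$n_pixels,
               ") does not match image columns (", ncol(ratio_image), ")")
  nr <- nrow(ratio_image)
  if (is.null(row_band)) row_band <- default_row_band(nr)
  row_band <- as.integer(row_band)
  if (length(row_band) != 2L || any(is.na(row_band)) ||
      row_band[1] < 1L || row_band[2] > nr || row_band[1] > row_band[2])
    stop_input("row_band must be an inclusive row interval inside the image")
  band <- ratio_image[row_band[1]:row_band[2], , drop = FALSE]
  n_valid <- colSums(!is.na(band))
  if (any(n_valid == 0L))
    stop_input("column(s) with no valid pixel in the band: ",
               paste(which(n_valid == 0L), collapse = ", "))
  vals <- colMeans(band, na.rm = TRUE)
  spr_curve(geometry_angles(geometry), vals)
}

# Centred band of 100 rows (1-based, inclusive); whole image if shorter.
default_row_band <- function(n_rows, height = 100L) {
  if (n_rows <= height) return(c(1L, n_rows))
  first <- (n_rows - height) %/% 2L + 1L
  c(first, first + height - 1L)
}
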