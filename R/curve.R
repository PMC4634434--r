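#' SPR curve container
#'
#' An SPR curve is the universal exchange object of the package: a strictly
#' increasing angle grid (degrees of incidence at the prism base) paired with
#' the reflectance ratio measured or simulated at each angle.
#'
#' @param angles_deg numeric vector of incidence angles in degrees, strictly
#'   increasing, length >= 3.
#' @param values numeric vector of reflectance (TM/TE ratio) values, same
#'   length as `angles_deg`, finite.
#' @return An object of class `spr_curve`: a list with elements `angles_deg`
#'   and `values`.
#' @examples
#' cv <- spr_curve(seq(60, 67, by = 0.1), runif(71))
#' @export
spr_curve <- function(angles_deg, values) {
  angles_deg <- as.numeric(angles_deg)
  values <- as.numeric(values)
  if (length(angles_deg) != length(values))
    stop_input("angles_deg and values must have equal length")
  if (length(angles_deg) < 3)
    stop_input("an SPR curve needs at least 3 points")
  if (!all(is.finite(angles_deg)) || !all(is.finite(values)))
    stop_input("angles and values must be finite")
  if (any(diff(angles_deg) <= 0))
    stop_input("angles_deg must be strictly increasing")
  structure(list(angles_deg = angles_deg, values = values),
            class = "spr_curve")
}

#' @export
length.spr_curve <- function(x) length(x$angles_deg)

#' @export
as.data.frame.spr_curve <- function(x, ...) {
  data.frame(angle_deg = x$angles_deg, reflectance = x$values)
}

#' @export
print.spr_curve <- function(x, ...) {
  cat(sprintf("<spr_curve> %d points, %.4f to %.4f deg, values in [%.4g, %.4g]\n",
              length(x), min(x$angles_deg), max(x$angles_deg),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.spr_curve <- function(x, ...) {
  graphics::plot(x$angles_deg, x$values, type = "l",
                 xlab = "incidence angle (deg)", ylab = "reflectance ratio", ...)
  invisible(x)
}

angular_step <- function(curve) stats::median(diff(curve$angles_deg))
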