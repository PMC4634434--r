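#' Resonance angle from a fitted curve
#'
#' The incidence angle of minimum model reflectance inside the resonance
#' region (right of the criterion). Located by a dense scan at 10x pixel
#' resolution followed by local scalar minimisation, so the estimate is
#' sub-pixel and insensitive to the scan grid.
#'
#' For the sigmoid-asymmetric model the dip block (centre, width and the
#' linear coefficients) is first re-solved against the resonance-region
#' points with the step position and steepness held (`refine = TRUE`,
#' the default): the asymmetric term is the part of the model that
#' describes the resonance side, and polishing it locally removes the
#' leverage that residuals elsewhere on the curve exert on the minimum
#' position. With `refine = FALSE` the minimum of the fitted model is
#' used as-is.
#'
#' @param fit a [fit_result] from [fit_curve()] or [fit_polynomial()].
#' @param split a [region_split()]; default [default_region_split()].
#' @param refine polish the dip block on the resonance region before
#'   locating the minimum (sigmoid-asymmetric fits only).
#' @return resonance angle in degrees.
#' @export
resonance_angle <- function(fit, split = default_region_split(fit),
                            refine = TRUE) {
  stopifnot(inherits(fit, "fit_result"))
  idx <- split_regions(fit$curve, split)
  x <- fit$curve$angles_deg
  params <- fit$params
  if (isTRUE(refine) && fit$model_id == "sigmoid_asymmetric")
    params <- polish_dip_params(fit, split)
  f <- function(X) eval_model(fit$model_id, params, X)
  refine_extremum(f, lo = split$criterion_deg, hi = max(x),
                  pixel_step = angular_step(fit$curve),
                  maximum = FALSE,
                  boundary_msg = "no interior resonance minimum in the resonance region")
}

# Region-polished copy of a sigmoid-asymmetric fit's parameters, used only
# for reading the resonance minimum.
polish_dip_params <- function(fit, split) {
  p <- param_vector(fit$params)
  th <- params_to_th(p)
  cf <- c(P1 = p[["A"]] * (1 - p[["B"]]), P2 = -p[["A"]] * p[["C"]],
          P3 = p[["F"]], P4 = p[["I"]])
  guess <- fit$init
  if (is.null(guess) || is.null(attr(guess, "morphology")))
    guess <- tryCatch(initial_guess(fit$curve), error = function(e) NULL)
  bb <- default_sa_bounds(fit$curve, guess %||% fit$params)
  ref <- tryCatch(
    refine_dip_region(th, cf, fit$curve$angles_deg, fit$curve$values,
                      guess %||% fit$params, bb,
                      boundary = split$criterion_deg),
    error = function(e) NULL)
  if (is.null(ref)) return(fit$params)
  th_to_params(ref$th, ref$sol$cf, p[["B"]])
}

#' Critical angle from a fitted curve
#'
#' The maximiser of the analytic first derivative of the fitted
#' sigmoid-asymmetric model inside the critical-angle region (left of the
#' criterion): the steepest point of the total-internal-reflection step.
#' Only the sigmoid-asymmetric model carries the step term, so other models
#' are rejected.
#'
#' @inheritParams resonance_angle
#' @return critical angle in degrees.
#' @export
critical_angle <- function(fit, split = default_region_split(fit)) {
  stopifnot(inherits(fit, "fit_result"))
  if (fit$model_id != "sigmoid_asymmetric")
    stop_input("critical angle requires the sigmoid-asymmetric model ",
               "(analytic derivative); got '", fit$model_id, "'")
  idx <- split_regions(fit$curve, split)
  x <- fit$curve$angles_deg
  d <- function(X) eval_sigmoid_asymmetric_derivative(fit$params, X)
  refine_extremum(d, lo = min(x), hi = split$criterion_deg,
                  pixel_step = angular_step(fit$curve),
                  maximum = TRUE,
                  boundary_msg = "derivative maximum sits on the region boundary; no critical-angle feature")
}

# Dense scan at pixel_step/10 resolution, then stats::optimize inside the
# bracketing cell. Errors when the extremum is on (within one coarse cell
# of) the region boundary.
refine_extremum <- function(f, lo, hi, pixel_step, maximum, boundary_msg) {
  grid_step <- pixel_step / 10
  xs <- seq(lo, hi, by = grid_step)
  if (length(xs) < 3L) stop_input("region too narrow to search")
  fx <- f(xs)
  i <- if (maximum) which.max(fx) else which.min(fx)
  if (i <= 1L || i >= length(xs)) stop_input(boundary_msg)
  obj <- if (maximum) function(X) -f(X) else f
  stats::optimize(obj, lower = xs[i - 1L], upper = xs[i + 1L],
                  tol = 1e-9)$minimum
}

#' Both angle estimates from one fit
#'
#' @inheritParams resonance_angle
#' @return list of class `angle_estimates` with `theta_RA` and `theta_CA`
#'   (degrees).
#' @export
angle_estimates <- function(fit, split = default_region_split(fit)) {
  est <- list(theta_RA = resonance_angle(fit, split),
              theta_CA = critical_angle(fit, split))
  structure(est, class = "angle_estimates")
}

#' @export
print.angle_estimates <- function(x, ...) {
  cat(sprintf("theta_CA = %.4f deg, theta_RA = %.4f deg\n",
              x$theta_CA, x$theta_RA))
  invisible(x)
}

#' Calibrate the bulk-response slope k
#'
#' Ordinary least squares of the resonance angle against the critical angle
#' over a bulk refractive-index ladder (e.g. a glycerol dilution series).
#' The slope becomes the normalisation constant `k` of the specific
#' adsorption angle; the reference instrument reported k = 0.97 with
#' r-squared 0.999 on a 0-5\% glycerol ladder. In `"changes"` mode (the
#' default) both angle series are first baselined to their first element,
#' matching sensorgram usage; the slope is identical either way, only the
#' intercept differs.
#'
#' @param theta_CA,theta_RA numeric vectors (degrees), length >= 3.
#' @param mode `"changes"` or `"absolute"`.
#' @return object of class `calibration_model` with fields `k`,
#'   `intercept`, `r_squared`, `mode`.
#' @export
calibrate_bulk_response <- function(theta_CA, theta_RA,
                                    mode = c("changes", "absolute")) {
  mode <- match.arg(mode)
  if (length(theta_CA) != length(theta_RA) || length(theta_CA) < 3L)
    stop_input("need >= 3 paired (theta_CA, theta_RA) observations")
  if (!all(is.finite(theta_CA)) || !all(is.finite(theta_RA)))
    stop_input("angles must be finite")
  ca <- theta_CA; ra <- theta_RA
  if (mode == "changes") { ca <- ca - ca[1]; ra <- ra - ra[1] }
  if (max(ca) - min(ca) == 0)
    stop_input("theta_CA values are all equal; slope undefined")
  ft <- lm(ra ~ ca)
  ss_tot <- sum((ra - mean(ra))^2)
  r2 <- if (ss_tot > 0) 1 - sum(ft$residuals^2) / ss_tot else 1
  calibration_model(k = unname(coef(ft)[2]),
                    intercept = unname(coef(ft)[1]),
                    r_squared = r2, mode = mode)
}

#' Calibration model for bulk-index referencing
#'
#' @param k slope of the resonance-angle response per unit critical-angle
#'   response; instrument-specific. 0.97 is the reference instrument's
#'   value and must not be assumed universal for quantitative work.
#' @param intercept regression intercept in degrees (unused by
#'   [specific_adsorption_angle()]).
#' @param r_squared goodness of the linear trend, in `[0, 1]` (or `NA`).
#' @param mode how the calibration was regressed ("changes" or "absolute").
#' @return an object of class `calibration_model`.
#' @export
calibration_model <- function(k = 0.97, intercept = 0, r_squared = NA_real_,
                              mode = "changes") {
  if (!is.finite(k)) stop_input("k must be finite")
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop_input("r_squared must lie in [0, 1]")
  structure(list(k = k, intercept = intercept, r_squared = r_squared,
                 mode = mode),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> k = %.4f (r^2 = %s, %s mode)\n",
              x$k, ifelse(is.na(x$r_squared), "NA",
                          sprintf("%.4f", x$r_squared)), x$mode))
  invisible(x)
}

#' Specific adsorption angle
#'
#' Removes the bulk refractive-index contribution from the resonance angle
#' by subtracting the scaled critical-angle response:
#' `theta_SAA = theta_RA - k * theta_CA`. With the instrument-calibrated
#' `k`, bulk-only events cancel and the remainder tracks surface binding.
#'
#' @param theta_RA,theta_CA angles in degrees.
#' @param k calibration slope, or a [calibration_model()]; default 0.97
#'   (reference-instrument value).
#' @return `theta_SAA` in degrees.
#' @export
specific_adsorption_angle <- function(theta_RA, theta_CA, k = 0.97) {
  if (inherits(k, "calibration_model")) k <- k$k
  if (!is.finite(k)) stop_input("k must be finite")
  theta_RA - k * theta_CA
}

#' Build a sensorgram from a time series of SPR curves
#'
#' Fits every frame with the sigmoid-asymmetric model (warm-starting each
#' fit from the previous frame's parameters, falling back to a fresh
#' morphological guess when the warm start fails), extracts both angles,
#' and forms the bulk-corrected specific adsorption angle. Frames that fail
#' to fit are kept in the output flagged `converged = FALSE` (angles `NA`);
#' an unfittable first frame aborts.
#'
#' Absolute angles and baseline-subtracted changes (`delta_*`, value minus
#' first-frame value) are both reported, since sensorgrams are read as
#' changes from baseline while the subtraction itself applies to absolute
#' angles.
#'
#' @param frames list of [spr_curve()] objects, time-ordered.
#' @param times numeric vector of acquisition times in seconds
#'   (non-decreasing); default `0, 1, 2, ...`.
#' @param calibration a [calibration_model()], or the string `"self"` to
#'   regress k from this very series (appropriate for bulk-only runs).
#' @param split optional [region_split()] used for every frame; default is
#'   each frame's own morphological split.
#' @return data.frame of class `sensorgram_series` with columns `time_s`,
#'   `theta_RA_deg`, `theta_CA_deg`, `theta_SAA_deg`, `delta_RA`,
#'   `delta_CA`, `delta_SAA`, `converged`, and attribute `calibration`.
#' @export
build_sensorgram <- function(frames, times = NULL,
                             calibration = calibration_model(),
                             split = NULL) {
  if (!length(frames)) stop_input("need at least one frame")
  if (!all(vapply(frames, inherits, TRUE, "spr_curve")))
    stop_input("frames must be a list of spr_curve objects")
  n <- length(frames)
  if (is.null(times)) times <- seq_len(n) - 1
  if (length(times) != n || any(diff(times) < 0))
    stop_input("times must be non-decreasing, one per frame")

  ra <- ca <- rep(NA_real_, n)
  ok <- rep(FALSE, n)
  prev_params <- NULL
  for (i in seq_len(n)) {
    res <- tryCatch({
      ft <- NULL
      if (!is.null(prev_params))
        ft <- tryCatch(fit_curve(frames[[i]], init = prev_params),
                       error = function(e) NULL)
      if (is.null(ft)) ft <- fit_curve(frames[[i]])
      sp <- if (is.null(split)) default_region_split(ft) else split
      list(fit = ft, est = angle_estimates(ft, sp))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (i == 1L)
        stop_input("first frame unfittable: ", conditionMessage(res))
      next
    }
    ra[i] <- res$est$theta_RA
    ca[i] <- res$est$theta_CA
    ok[i] <- res$fit$converged
    prev_params <- res$fit$params
  }

  if (identical(calibration, "self")) {
    good <- which(is.finite(ra) & is.finite(ca))
    if (length(good) < 3L)
      stop_input("self-calibration needs >= 3 fitted frames")
    calibration <- calibrate_bulk_response(ca[good], ra[good])
  }
  stopifnot(inherits(calibration, "calibration_model"))
  saa <- specific_adsorption_angle(ra, ca, calibration)
  base <- function(v) v - v[which(is.finite(v))[1]]
  out <- data.frame(time_s = times, theta_RA_deg = ra, theta_CA_deg = ca,
                    theta_SAA_deg = saa, delta_RA = base(ra),
                    delta_CA = base(ca), delta_SAA = base(saa),
                    converged = ok)
  attr(out, "calibration") <- calibration
  class(out) <- c("sensorgram_series", "data.frame")
  out
}
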