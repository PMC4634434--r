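#' Morphological initial guess for the sigmoid-asymmetric model
#'
#' Reads the SPR morphology straight off the samples: the dip centre `D`
#' from the global minimum, the step centre `H` from the steepest rise left
#' of the dip, the step amplitude `F` from the level difference across the
#' step, the dip half-width `E` from the half-depth width, `A` from depth
#' times `E^2`, and the step steepness `G` from the measured rise width.
#' `B`, `C` and the tilt `I` start at zero. A lightly smoothed copy of the
#' curve is used so single-pixel noise cannot hijack the landmarks.
#'
#' Curves without SPR morphology (no interior minimum, or no rising edge
#' left of the dip) are rejected.
#'
#' @param curve an [spr_curve()].
#' @return an [sa_params()] vector with attributes `morphology` (landmark
#'   table used for the default fit bounds) retained.
#' @export
initial_guess <- function(curve) {
  stopifnot(inherits(curve, "spr_curve"))
  x <- curve$angles_deg
  n <- length(x)
  step <- angular_step(curve)
  # smoothing support fixed in angle (~0.03 deg), not in pixels, so the
  # landmark estimates do not move when the curve is resampled
  w <- max(3L, min(9L, as.integer(round(0.0285 / step / 2)) * 2L + 1L))
  y <- smooth_values(curve$values, width = w)

  i0 <- which.min(y)
  if (i0 <= 2L || i0 >= n - 1L)
    stop_input("curve lacks SPR morphology: no interior reflectance minimum")
  D <- x[i0]

  dy <- diff(y)
  left <- which(x[-1] < D)
  if (!length(left) || max(dy[left]) <= 0)
    stop_input("curve lacks SPR morphology: no steep rise left of the dip")
  ih <- left[which.max(dy[left])]
  # sub-pixel vertex of the derivative peak (3-point parabola), so the
  # step-centre estimate does not inherit the pixel quantisation
  H <- x[ih]
  if (ih > 1L && ih < length(dy)) {
    den <- dy[ih - 1L] - 2 * dy[ih] + dy[ih + 1L]
    if (den < 0) {
      off <- 0.5 * (dy[ih - 1L] - dy[ih + 1L]) / den
      if (abs(off) <= 1) H <- H + off * step
    }
  }

  # 50%-of-max-slope width of the rising edge around ih
  half_slope <- dy[ih] / 2
  wl <- ih
  while (wl > 1L && dy[wl - 1L] > half_slope) wl <- wl - 1L
  wr <- ih
  while (wr < length(dy) && dy[wr + 1L] > half_slope) wr <- wr + 1L
  rise_width <- max((wr - wl + 1L) * step, 2 * step)

  # step amplitude from median levels on either side of the edge
  lo_i <- max(1L, ih - 18L):max(1L, ih - 3L)
  hi_i <- min(ih + 3L, i0):min(ih + 18L, i0)
  F <- max(median(y[hi_i]) - median(y[lo_i]), 0)

  between <- y[seq(ih, i0)]
  plateau <- max(between)
  depth <- plateau - y[i0]
  half <- y[i0] + depth / 2
  iL <- if (any(y[1:i0] > half)) max(which(y[1:i0] > half)) else 1L
  right_above <- which(y[i0:n] > half)
  iR <- if (length(right_above)) i0 + min(right_above) - 1L else n
  E <- max(min(x[iR] - x[i0], x[i0] - x[iL]), 2 * step)

  p <- sa_params(A = -depth * E^2, B = 0, C = 0, D = D, E = E,
                 F = F, G = -4.39 / rise_width, H = H, I = 0)
  attr(p, "morphology") <- list(step_deg = step, rise_width = rise_width,
                                H0 = H, D0 = D, F0 = F, i_dip = i0,
                                i_step = ih)
  p
}

# 5-point running mean with reflected ends; width small enough to keep
# landmark positions within a pixel or two.
smooth_values <- function(y, width = 5L) {
  n <- length(y)
  if (n < width) return(y)
  k <- rep(1 / width, width)
  pad <- (width - 1L) %/% 2L
  yy <- c(rev(y[seq_len(pad)]), y, rev(y[n - seq_len(pad) + 1L]))
  as.numeric(stats::filter(yy, k, sides = 2)[(pad + 1L):(pad + n)])
}

# Default constraints on the nonlinear block (D, log E, log -G, H) of the
# sigmoid-asymmetric fit, derived from the measured morphology. They pin
# each model term to the feature it is meant to describe: the logistic term
# must remain a resolvable rising step (steepness window set by the
# measured 50%-slope rise width) near the observed edge (trust window
# around the morphological step-centre estimate), and the dip centre must
# stay inside the curve. On data actually generated from the model the
# measured morphology reproduces the generating parameters, so none of
# these constraints bind there; on instrument-like curves they prevent the
# step term from degenerating into a background ramp, the dominant failure
# mode of an unconstrained fit of overlapping components.
default_sa_bounds <- function(curve, init) {
  x <- curve$angles_deg
  mor <- attr(init, "morphology")
  step <- if (!is.null(mor)) mor$step_deg else angular_step(curve)
  span <- diff(range(x))
  if (is.null(mor)) {
    return(list(lower = c(D = min(x), logE = log(step / 2),
                          logmG = log(4.39 / span), H = min(x)),
                upper = c(D = max(x), logE = log(span),
                          logmG = log(4.39 / (step / 4)), H = max(x)),
                f_min = 0))
  }
  h_win <- max(2 * step, mor$rise_width / 2)
  list(lower = c(D = min(x), logE = log(step / 2),
                 logmG = log(4.39 / (8 * mor$rise_width)),
                 H = max(min(x), mor$H0 - h_win)),
       upper = c(D = max(x), logE = log(span),
                 logmG = log(4.39 / (step / 4)),
                 H = min(max(x), mor$H0 + h_win)),
       f_min = mor$F0 / 4)
}

#' Fit result container
#'
#' Returned by [fit_curve()] and [fit_polynomial()]. Holds the model
#' identity, the fitted parameter record, per-point residuals
#' (fitted - observed), the residual sum of squares, convergence metadata,
#' and the data the model was fitted to (needed by the angle extractors).
#'
#' @name fit_result
NULL

new_fit_result <- function(model_id, params, curve, converged, n_iter,
                           init = NULL) {
  fitted <- eval_model(model_id, params, curve$angles_deg)
  residuals <- fitted - curve$values
  structure(list(model_id = model_id, params = params,
                 curve = curve, fitted = fitted, residuals = residuals,
                 sse = sum(residuals^2), converged = converged,
                 n_iter = n_iter, init = init, region_stats = NULL),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> model=%s  n=%d  SSE=%.4g  converged=%s (%d iter)\n",
              x$model_id, length(x$curve), x$sse, x$converged, x$n_iter))
  if (x$model_id != "polynomial")
    print(signif(unclass(x$params), 6))
  invisible(x)
}

run_lm <- function(par, fn, jac = NULL, lower = NULL, upper = NULL,
                   maxiter = 1024L) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-12,
                                     ptol = 1e-12, gtol = 0)
  args <- list(par = par, fn = fn, control = ctrl)
  if (!is.null(jac)) args$jac <- jac
  if (!is.null(lower)) args$lower <- lower
  if (!is.null(upper)) args$upper <- upper
  do.call(minpack.lm::nls.lm, args)
}

# Variable-projection machinery: for fixed nonlinear block
# th = (D, logE, logmG, H) the model is linear in
# (P1, P2, P3, P4) = (A(1-B), -A C, F, I) through the design
# [1/v, t/v, s, X]. The linear block is solved exactly by QR at every
# LM step, with the step amplitude floored at f_min.
sa_design <- function(th, X) {
  t <- X - th[["D"]]
  v <- t^2 + exp(2 * th[["logE"]])
  s <- plogis(exp(th[["logmG"]]) * (X - th[["H"]]))
  cbind(P1 = 1 / v, P2 = t / v, P3 = s, P4 = X)
}

sa_lin_solve <- function(th, X, y, f_min) {
  M <- sa_design(th, X)
  cf <- qr.coef(qr(M), y)
  cf[is.na(cf)] <- 0
  if (cf[["P3"]] < f_min) {
    cf2 <- qr.coef(qr(M[, c(1, 2, 4), drop = FALSE]), y - f_min * M[, 3])
    cf2[is.na(cf2)] <- 0
    cf <- c(cf2[1:2], P3 = f_min, P4 = cf2[[3]])
  }
  list(cf = cf, fitted = drop(M %*% cf))
}

th_to_params <- function(th, cf, B) {
  A <- cf[["P1"]] / (1 - B)
  sa_params(A = A, B = B, C = if (A != 0) -cf[["P2"]] / A else 0,
            D = th[["D"]], E = exp(th[["logE"]]), F = cf[["P3"]],
            G = -exp(th[["logmG"]]), H = th[["H"]], I = cf[["P4"]])
}

params_to_th <- function(p) {
  p <- param_vector(p)
  if (p[["G"]] >= 0 || p[["E"]] <= 0)
    stop_input("sigmoid-asymmetric fitting needs E > 0 and G < 0 ",
               "(rising step); supply an init in that convention")
  c(D = p[["D"]], logE = log(p[["E"]]), logmG = log(-p[["G"]]),
    H = p[["H"]])
}

#' Fit an SPR curve with the sigmoid-asymmetric or asymmetric model
#'
#' Nonlinear least squares over the full curve. The sigmoid-asymmetric fit
#' uses variable projection: the model is linear in the combinations
#' `A(1-B)`, `A*C`, `F` and `I`, so Levenberg-Marquardt runs over the four
#' nonlinear parameters `(D, log E, log(-G), H)` with an exact linear
#' least-squares solve at every step. The gauge parameter `B` is held at
#' its initial value (only `A(1-B)` and `A*C` are identifiable).
#' [resonance_angle()] optionally polishes the dip block on the resonance
#' region before locating the minimum; the fit itself is the joint
#' full-curve optimum.
#'
#' Default constraints derive from the curve's own morphology (see
#' [initial_guess()]) and keep the logistic term a resolvable step near the
#' observed total-internal-reflection edge; they do not bind on data
#' generated from the model itself.
#'
#' @param curve an [spr_curve()].
#' @param model_id `"sigmoid_asymmetric"` or `"asymmetric"`; see
#'   [fit_polynomial()] for the polynomial comparison model.
#' @param init optional [sa_params()] / [asym_params()] starting point;
#'   default [initial_guess()] (its A-E fields for the asymmetric model).
#' @param bounds optional `list(lower =, upper =, f_min =)` over the
#'   nonlinear block `(D, logE, logmG, H)` for the sigmoid-asymmetric
#'   model (or over `(A, C, D, E)` for the asymmetric model); `NULL` for
#'   morphology-derived defaults.
#' @return a [fit_result].
#' @export
fit_curve <- function(curve, model_id = c("sigmoid_asymmetric", "asymmetric"),
                      init = NULL, bounds = NULL) {
  stopifnot(inherits(curve, "spr_curve"))
  model_id <- match.arg(model_id)
  n_par <- if (model_id == "sigmoid_asymmetric") 9L else 5L
  if (length(curve) <= n_par)
    stop_input("curve has fewer points than model parameters")

  guess <- if (is.null(init) || is.null(attr(init, "morphology")))
    tryCatch(initial_guess(curve), error = function(e) NULL) else init
  if (is.null(init)) {
    if (is.null(guess)) stop_input("no usable initial guess: ",
                                   "supply `init` for curves without SPR morphology")
    init <- guess
  }

  if (model_id == "asymmetric")
    return(fit_asymmetric(curve, init, bounds))

  x <- curve$angles_deg
  y <- curve$values
  B <- param_vector(init)[["B"]]
  bb <- if (is.null(bounds)) default_sa_bounds(curve, guess %||% init)
        else bounds
  th0 <- pmin(pmax(params_to_th(init), bb$lower), bb$upper)

  resid_fn <- function(th) sa_lin_solve(th, x, y, bb$f_min)$fitted - y

  # deterministic multi-start over the step steepness: the steepness basin
  # is the one landscape direction with genuinely separated local minima
  starts <- list(th0)
  for (dg in c(-log(4), log(4))) {
    ths <- th0; ths[["logmG"]] <- ths[["logmG"]] + dg
    starts <- c(starts, list(pmin(pmax(ths, bb$lower), bb$upper)))
  }
  th <- NULL; best_sse <- Inf; n_iter <- 0L; converged <- FALSE
  for (ths in starts) {
    ftk <- run_lm(ths, resid_fn, lower = bb$lower, upper = bb$upper)
    n_iter <- n_iter + ftk$niter
    sse_k <- sum(ftk$fvec^2)
    if (sse_k < best_sse) {
      best_sse <- sse_k; th <- coef(ftk); converged <- lm_converged(ftk)
    }
  }
  if (!converged) {
    # one seeded multi-start retry from a perturbed start
    thr <- with_seed(20731L, th0 + c(0.1, 0.2, 0.2, 0.01) *
                       runif(4L, -1, 1))
    thr <- pmin(pmax(thr, bb$lower), bb$upper)
    fit2 <- run_lm(thr, resid_fn, lower = bb$lower, upper = bb$upper)
    n_iter <- n_iter + fit2$niter
    if (sum(fit2$fvec^2) < best_sse) {
      th <- coef(fit2)
      converged <- lm_converged(fit2)
    }
  }
  sol <- sa_lin_solve(th, x, y, bb$f_min)

  # monotonicity contract: never report worse than the initial guess
  if (sum((eval_sigmoid_asymmetric(init, x) - y)^2) <
      sum((sol$fitted - y)^2)) {
    th <- params_to_th(init)
    sol <- sa_lin_solve(th, x, y, bb$f_min)
  }

  params <- th_to_params(th, sol$cf, B)
  new_fit_result("sigmoid_asymmetric", params, curve,
                 converged = converged, n_iter = n_iter, init = init)
}

# Polish the dip block (D, log E) together with the linear coefficients
# on the resonance region (right of `boundary`), holding the step position
# and steepness from the joint fit. Used by resonance_angle() to read the
# dip minimum free of out-of-region residual leverage; multi-started over
# the dip width, which has separated local basins when the dip is deep
# and asymmetric.
refine_dip_region <- function(th, cf, x, y, init, bb, boundary = NULL) {
  mor <- attr(init, "morphology")
  mid <- if (!is.null(boundary)) boundary
         else if (!is.null(mor)) (mor$H0 + mor$D0) / 2
         else (th[["H"]] + th[["D"]]) / 2
  idx <- which(x >= mid)
  if (length(idx) < 8L)
    return(list(th = th, sol = sa_lin_solve(th, x, y, bb$f_min), n_iter = 0L))
  xr <- x[idx]
  sr <- plogis(exp(th[["logmG"]]) * (xr - th[["H"]]))
  dip_solve <- function(de) {
    t <- xr - de[1]; v <- t^2 + exp(2 * de[2])
    M <- cbind(1 / v, t / v, sr, xr)
    c2 <- qr.coef(qr(M), y[idx])
    c2[is.na(c2)] <- 0
    if (c2[3] < bb$f_min) {
      c22 <- qr.coef(qr(M[, c(1, 2, 4), drop = FALSE]),
                     y[idx] - bb$f_min * sr)
      c22[is.na(c22)] <- 0
      c2 <- c(c22[1:2], bb$f_min, c22[3])
    }
    list(cf = c2, fitted = drop(M %*% c2))
  }
  starts <- list(c(th[["D"]], th[["logE"]]),
                 c(th[["D"]], th[["logE"]] - log(2)))
  if (!is.null(mor)) {
    e_mor <- param_vector(init)[["E"]]
    if (is.finite(e_mor) && e_mor > 0)
      starts <- c(starts, list(c(mor$D0, log(e_mor))))
  }
  best <- NULL; n_iter <- 0L
  for (de0 in starts) {
    de0 <- pmin(pmax(de0, c(bb$lower[["D"]], bb$lower[["logE"]])),
                c(bb$upper[["D"]], bb$upper[["logE"]]))
    fitr <- run_lm(de0, function(de) dip_solve(de)$fitted - y[idx],
                   lower = c(bb$lower[["D"]], bb$lower[["logE"]]),
                   upper = c(bb$upper[["D"]], bb$upper[["logE"]]))
    n_iter <- n_iter + fitr$niter
    sse <- sum(fitr$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(de = coef(fitr), sse = sse)
  }
  th2 <- th; th2[["D"]] <- best$de[1]; th2[["logE"]] <- best$de[2]
  c2 <- dip_solve(best$de)$cf
  cf2 <- c(P1 = unname(c2[1]), P2 = unname(c2[2]),
           P3 = unname(c2[3]), P4 = unname(c2[4]))
  M <- sa_design(th2, x)
  list(th = th2,
       sol = list(cf = cf2, fitted = drop(M %*% cf2)),
       n_iter = n_iter)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

lm_converged <- function(fit) fit$info %in% 1:4

fit_asymmetric <- function(curve, init, bounds) {
  x <- curve$angles_deg; y <- curve$values
  p0 <- param_vector(init)
  if (length(p0) == 9L) p0 <- p0[c("A", "B", "C", "D", "E")]
  B <- p0[["B"]]
  free <- c("A", "C", "D", "E")
  q0 <- p0[free]
  if (is.null(bounds)) {
    step <- angular_step(curve)
    lo <- c(A = -Inf, C = -Inf, D = min(x), E = step)
    hi <- c(A = 0, C = Inf, D = max(x), E = diff(range(x)))
  } else { lo <- bounds$lower[free]; hi <- bounds$upper[free] }
  q0 <- pmin(pmax(q0, lo), hi)
  resid_fn <- function(q) {
    p <- c(A = q[["A"]], B = B, C = q[["C"]], D = q[["D"]], E = q[["E"]])
    eval_asymmetric(p, x) - y
  }
  jac_fn <- function(q) {
    t <- x - q[["D"]]; v <- t^2 + q[["E"]]^2; u <- 1 - B - q[["C"]] * t
    cbind(A = u / v, C = -q[["A"]] * t / v,
          D = (q[["A"]] * q[["C"]] * v + 2 * t * q[["A"]] * u) / v^2,
          E = -2 * q[["A"]] * u * q[["E"]] / v^2)
  }
  ft <- run_lm(q0, resid_fn, jac_fn, lower = lo, upper = hi)
  qb <- coef(ft)
  if (sum(resid_fn(qb)^2) > sum(resid_fn(q0)^2)) qb <- q0
  params <- asym_params(A = qb[["A"]], B = B, C = qb[["C"]],
                        D = qb[["D"]], E = qb[["E"]])
  new_fit_result("asymmetric", params, curve,
                 converged = lm_converged(ft), n_iter = ft$niter,
                 init = init)
}

#' Fit a high-order polynomial to an SPR curve
#'
#' Ordinary least squares for a polynomial of the given order, evaluated in
#' the rescaled variable `z = 2(X - a)/(b - a) - 1` so the order-24 design
#' matrix stays numerically workable (raw-degree normal equations are
#' singular at this order). Solved by QR.
#'
#' @param curve an [spr_curve()].
#' @param order polynomial order; the comparison protocol uses 24.
#' @return a [fit_result] with [poly_params()].
#' @export
fit_polynomial <- function(curve, order = 24L) {
  stopifnot(inherits(curve, "spr_curve"))
  order <- as.integer(order)
  if (is.na(order) || order < 0L) stop_input("order must be >= 0")
  if (length(curve) <= order)
    stop_input("curve length must exceed the polynomial order")
  x <- curve$angles_deg
  dom <- range(x)
  z <- 2 * (x - dom[1]) / (dom[2] - dom[1]) - 1
  design <- outer(z, 0:order, `^`)
  cf <- qr.coef(qr(design, LAPACK = TRUE), curve$values)
  cf[is.na(cf)] <- 0
  params <- poly_params(cf, dom)
  new_fit_result("polynomial", params, curve, converged = TRUE,
                 n_iter = 1L)
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, the usual R-squared fit-quality measure; may be
#' negative for fits worse than the mean.
#'
#' @param observed,fitted numeric vectors of equal length >= 2.
#' @return CD in `(-Inf, 1]`.
#' @export
coefficient_of_determination <- function(observed, fitted) {
  check_pair(observed, fitted, 2L)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop_input("observed values have zero variance; CD undefined")
  1 - sum((observed - fitted)^2) / ss_tot
}

#' Error variance of a fit
#'
#' The population variance of the residuals `E_i = fitted_i - observed_i`:
#' `mean((E - mean(E))^2)`. Mean-centring makes it invariant to a constant
#' offset between fit and data.
#'
#' @param observed,fitted numeric vectors of equal length >= 1.
#' @return EV >= 0.
#' @export
error_variance <- function(observed, fitted) {
  check_pair(observed, fitted, 1L)
  e <- fitted - observed
  mean((e - mean(e))^2)
}

check_pair <- function(observed, fitted, min_len) {
  if (length(observed) != length(fitted))
    stop_input("observed and fitted must have equal length")
  if (length(observed) < min_len)
    stop_input("need at least ", min_len, " points")
  if (!all(is.finite(observed)) || !all(is.finite(fitted)))
    stop_input("inputs must be finite")
  invisible(TRUE)
}

#' Region split at a criterion angle
#'
#' Divides a full SPR curve into the critical-angle region (left of the
#' criterion) and the resonance-angle region (right of it) for per-region
#' fit-quality reporting and for the angle extractors.
#'
#' @param criterion_deg the splitting angle in degrees.
#' @return an object of class `region_split`.
#' @seealso [region_split_at_pixel()] for the fixed-pixel protocol,
#'   [default_region_split()] for the morphological default.
#' @export
region_split <- function(criterion_deg) {
  if (!is.finite(criterion_deg)) stop_input("criterion must be finite")
  structure(list(criterion_deg = criterion_deg), class = "region_split")
}

#' Region split at a fixed detector pixel
#'
#' Replicates protocols that split at a fixed column (e.g. pixel 600 for
#' water, 550 for air on the reference instrument).
#'
#' @param geometry a [detector_geometry()].
#' @param pixel 0-based column index.
#' @return a [region_split()].
#' @export
region_split_at_pixel <- function(geometry, pixel) {
  region_split(pixel_to_angle(geometry, pixel))
}

#' Default region split for a fit
#'
#' The midpoint between the initial-guess step centre `H` and dip centre
#' `D`, which separates the critical-angle edge from the resonance dip
#' without any instrument-specific pixel convention.
#'
#' @param fit a [fit_result] from [fit_curve()].
#' @return a [region_split()].
#' @export
default_region_split <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  init <- fit$init
  if (!is.null(init) && !is.null(attr(init, "morphology"))) {
    mor <- attr(init, "morphology")
    return(region_split((mor$H0 + mor$D0) / 2))
  }
  p <- param_vector(fit$params)
  if (all(c("H", "D") %in% names(p)))
    return(region_split((p[["H"]] + p[["D"]]) / 2))
  stop_input("cannot derive a default split for this fit; supply one")
}

split_regions <- function(curve, split) {
  stopifnot(inherits(split, "region_split"))
  crit <- split$criterion_deg
  x <- curve$angles_deg
  if (crit <= min(x) || crit >= max(x))
    stop_input("criterion angle must lie strictly inside the curve range")
  left <- which(x < crit)
  right <- which(x >= crit)
  if (length(left) < 3L || length(right) < 3L)
    stop_input("each region needs at least 3 points")
  list(left = left, right = right)
}

#' Per-region fit quality (critical-angle vs resonance-angle region)
#'
#' Computes the coefficient of determination and error variance separately
#' on the two sides of the criterion angle, mirroring the standard
#' comparison-table layout for full-curve fitting methods.
#'
#' @param curve the fitted [spr_curve()] (defaults to the one in `fit`).
#' @param fit a [fit_result].
#' @param split a [region_split()].
#' @return data.frame with columns `region`, `n`, `cd`, `ev`, `sse`.
#' @export
region_quality <- function(curve = NULL, fit, split) {
  stopifnot(inherits(fit, "fit_result"))
  if (is.null(curve)) curve <- fit$curve
  idx <- split_regions(curve, split)
  fitted <- eval_model(fit$model_id, fit$params, curve$angles_deg)
  one <- function(name, i) data.frame(
    region = name, n = length(i),
    cd = coefficient_of_determination(curve$values[i], fitted[i]),
    ev = error_variance(curve$values[i], fitted[i]),
    sse = sum((fitted[i] - curve$values[i])^2))
  rbind(one("critical", idx$left), one("resonance", idx$right))
}
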