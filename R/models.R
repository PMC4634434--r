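#' Sigmoid-asymmetric model parameters
#'
#' The nine-parameter model for a full SPR curve,
#' \deqn{R(X) = \frac{A[1-(B + C(X-D))]}{(X-D)^2+E^2}
#'       + \frac{F}{1+e^{G(X-H)}} + IX,}
#' combining an asymmetric Lorentzian resonance dip (A-E), a logistic step
#' for the total-internal-reflection transition (F-H) and a linear tilt (I).
#' `D` is the dip-centre angle, `E` the dip half-width, `H` the step-centre
#' angle and `G` the step steepness (negative for a rising step); all angles
#' in degrees.
#'
#' Only the combinations `A(1-B)` and `A*C` enter the model value, so
#' `(A, B, C)` carries one redundant degree of freedom; fitting holds `B`
#' fixed (see [fit_curve()]).
#'
#' @param A,B,C,D,E,F,G,H,I finite real parameters; `E != 0`.
#' @return a named numeric vector of class `sa_params`.
#' @export
sa_params <- function(A, B, C, D, E, F, G, H, I) {
  p <- c(A = A, B = B, C = C, D = D, E = E, F = F, G = G, H = H, I = I)
  if (!all(is.finite(p))) stop_input("all parameters must be finite")
  if (p[["E"]] == 0) stop_input("E must be nonzero (pole at X = D otherwise)")
  structure(p, class = "sa_params")
}

#' Asymmetric (resonance-dip only) model parameters
#'
#' The first term of the sigmoid-asymmetric model on its own: the classic
#' asymmetric dip equation used to locate the resonance angle from a short
#' angular window.
#'
#' @param A,B,C,D,E finite real parameters; `E != 0`.
#' @return a named numeric vector of class `asym_params`.
#' @export
asym_params <- function(A, B, C, D, E) {
  p <- c(A = A, B = B, C = C, D = D, E = E)
  if (!all(is.finite(p))) stop_input("all parameters must be finite")
  if (p[["E"]] == 0) stop_input("E must be nonzero (pole at X = D otherwise)")
  structure(p, class = "asym_params")
}

#' Polynomial model in a rescaled basis
#'
#' High-order polynomial regression (the comparison method uses order 24)
#' is numerically hopeless in raw degrees, so coefficients are stored for
#' the variable `z = 2 (X - a) / (b - a) - 1` mapping the fitted domain
#' `[a, b]` onto `[-1, 1]`.
#'
#' @param coefficients numeric vector `c0, c1, ..., c_order` in the scaled
#'   basis.
#' @param domain numeric length-2 interval `c(a, b)`, `a < b`.
#' @return an object of class `poly_params`.
#' @export
poly_params <- function(coefficients, domain) {
  if (!all(is.finite(coefficients)) || length(coefficients) < 1)
    stop_input("coefficients must be a non-empty finite vector")
  if (length(domain) != 2 || !all(is.finite(domain)) || domain[1] >= domain[2])
    stop_input("domain must be a non-degenerate interval c(a, b)")
  structure(list(order = length(coefficients) - 1L,
                 coefficients = as.numeric(coefficients),
                 domain = as.numeric(domain)),
            class = "poly_params")
}

param_vector <- function(p) {
  if (inherits(p, c("sa_params", "asym_params"))) unclass(p)
  else if (is.numeric(p)) p
  else stop_input("expected a parameter vector")
}

#' Evaluate the sigmoid-asymmetric model
#'
#' @param p an [sa_params()] vector.
#' @param X incidence angle(s), degrees; finite.
#' @return model reflectance at each `X`.
#' @examples
#' p <- sa_params(1, 0, 0, 0, 1, 0, 1, 0, 0)
#' eval_sigmoid_asymmetric(p, 1) # Lorentzian: 1/(1+1) = 0.5
#' @export
eval_sigmoid_asymmetric <- function(p, X) {
  p <- param_vector(p)
  if (any(!is.finite(X))) stop_input("X must be finite")
  t <- X - p[["D"]]
  # logistic term written through plogis for overflow-safe evaluation
  s <- plogis(-p[["G"]] * (X - p[["H"]]))
  p[["A"]] * (1 - (p[["B"]] + p[["C"]] * t)) / (t^2 + p[["E"]]^2) +
    p[["F"]] * s + p[["I"]] * X
}

#' Analytic first derivative of the sigmoid-asymmetric model
#'
#' The critical angle is read off as the maximiser of this derivative in the
#' critical-angle region, so the derivative is provided in closed form
#' rather than by differencing.
#'
#' @inheritParams eval_sigmoid_asymmetric
#' @return `dR/dX` at each `X`.
#' @export
eval_sigmoid_asymmetric_derivative <- function(p, X) {
  p <- param_vector(p)
  if (any(!is.finite(X))) stop_input("X must be finite")
  t <- X - p[["D"]]
  v <- t^2 + p[["E"]]^2
  u <- 1 - p[["B"]] - p[["C"]] * t
  s <- plogis(-p[["G"]] * (X - p[["H"]]))
  p[["A"]] * (-p[["C"]] * v - 2 * t * u) / v^2 -
    p[["F"]] * p[["G"]] * s * (1 - s) + p[["I"]]
}

#' Evaluate the asymmetric dip model
#'
#' @param p an [asym_params()] vector (fields A-E).
#' @param X incidence angle(s), degrees.
#' @return model reflectance at each `X`.
#' @export
eval_asymmetric <- function(p, X) {
  p <- param_vector(p)
  if (any(!is.finite(X))) stop_input("X must be finite")
  t <- X - p[["D"]]
  p[["A"]] * (1 - (p[["B"]] + p[["C"]] * t)) / (t^2 + p[["E"]]^2)
}

#' Evaluate a rescaled-basis polynomial
#'
#' Horner evaluation in the scaled variable `z in [-1, 1]`.
#'
#' @param p a [poly_params()].
#' @param X incidence angle(s), degrees; sensible only on or near the
#'   fitted domain.
#' @return polynomial value at each `X`.
#' @export
eval_polynomial <- function(p, X) {
  stopifnot(inherits(p, "poly_params"))
  if (any(!is.finite(X))) stop_input("X must be finite")
  z <- 2 * (X - p$domain[1]) / (p$domain[2] - p$domain[1]) - 1
  cf <- p$coefficients
  out <- rep(cf[length(cf)], length(z))
  if (length(cf) > 1)
    for (k in (length(cf) - 1):1) out <- out * z + cf[k]
  out
}

# Dispatch model evaluation for a fit result's parameter record.
eval_model <- function(model_id, params, X) {
  switch(model_id,
         sigmoid_asymmetric = eval_sigmoid_asymmetric(params, X),
         asymmetric = eval_asymmetric(params, X),
         polynomial = eval_polynomial(params, X),
         stop_input("unknown model '", model_id, "'"))
}
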