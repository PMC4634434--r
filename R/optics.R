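#' Optical stack for the Kretschmann configuration
#'
#' Describes a prism-coupled multilayer: a semi-infinite prism, an ordered
#' list of thin layers (complex refractive index + thickness), and a
#' semi-infinite bulk medium. Incidence angles are measured inside the prism
#' at its base.
#'
#' @param prism_index real refractive index of the prism (default BK7,
#'   1.5125 at 770 nm).
#' @param layers list of layers, each a `list(index = <complex>,
#'   thickness_nm = <positive>)`, ordered from prism to bulk. May be empty
#'   (bare interface).
#' @param bulk_index real refractive index of the bulk medium.
#' @param wavelength_nm vacuum wavelength in nm (> 0).
#' @return An object of class `optical_stack`.
#' @seealso [kretschmann_stack()] for the default chromium/gold sensor chip.
#' @export
optical_stack <- function(prism_index = 1.5125, layers = list(),
                          bulk_index = 1.333, wavelength_nm = 770) {
  if (!is.finite(prism_index) || prism_index <= 0)
    stop_input("prism_index must be a positive real number")
  if (!is.finite(bulk_index) || bulk_index <= 0)
    stop_input("bulk_index must be a positive real number")
  if (prism_index <= bulk_index)
    stop_input("prism_index must exceed bulk_index (total internal reflection unreachable)")
  if (!is.finite(wavelength_nm) || wavelength_nm <= 0)
    stop_input("wavelength_nm must be > 0")
  for (l in layers) {
    if (!is.list(l) || is.null(l$index) || is.null(l$thickness_nm))
      stop_input("each layer needs fields 'index' and 'thickness_nm'")
    if (!is.finite(Re(l$index)) || !is.finite(Im(l$index)))
      stop_input("layer index must be a finite complex number")
    if (Im(l$index) < 0)
      stop_input("layer index must have non-negative imaginary part (passive medium)")
    if (!is.finite(l$thickness_nm) || l$thickness_nm <= 0)
      stop_input("layer thickness must be > 0 nm")
  }
  structure(list(prism_index = prism_index, layers = layers,
                 bulk_index = bulk_index, wavelength_nm = wavelength_nm),
            class = "optical_stack")
}

#' @export
print.optical_stack <- function(x, ...) {
  cat(sprintf("<optical_stack> prism n=%.4f | %d layer(s) | bulk n=%.4f @ %g nm\n",
              x$prism_index, length(x$layers), x$bulk_index, x$wavelength_nm))
  for (l in x$layers)
    cat(sprintf("  layer n=%.4f%+.4fi  d=%.1f nm\n",
                Re(l$index), Im(l$index), l$thickness_nm))
  invisible(x)
}

# Handbook optical constants at 770 nm used for the default sensor chip.
# Gold: permittivity about -23.6 + 1.7i (Johnson & Christy tabulation),
# i.e. n = 0.1749 + 4.8625i. Chromium: n = 3.08 + 3.34i.
# Both are configurable through `kretschmann_stack()`.
gold_index_770 <- function() sqrt(cplx(-23.6 + 1.7i))
chromium_index_770 <- function() 3.08 + 3.34i

#' Default chromium/gold Kretschmann sensor stack
#'
#' BK7 prism (n = 1.5125 at 770 nm), 2 nm chromium adhesion layer, 50 nm
#' gold film, bulk medium. Gold/chromium optical constants default to
#' handbook tabulations at 770 nm (see source for provenance) and can be
#' overridden.
#'
#' @param bulk_index bulk medium index (1.333 water, 1.000 air).
#' @param gold_thickness_nm gold film thickness (default 50).
#' @param cr_thickness_nm chromium thickness (default 2).
#' @param gold_index,cr_index complex layer indices.
#' @param prism_index,wavelength_nm see [optical_stack()].
#' @param adlayer optional adsorbed layer on top of the gold, as
#'   `list(index =, thickness_nm =)`, e.g. a growing protein film.
#' @return an [optical_stack()].
#' @export
kretschmann_stack <- function(bulk_index = 1.333,
                              gold_thickness_nm = 50,
                              cr_thickness_nm = 2,
                              gold_index = gold_index_770(),
                              cr_index = chromium_index_770(),
                              prism_index = 1.5125,
                              wavelength_nm = 770,
                              adlayer = NULL) {
  layers <- list(
    list(index = cr_index, thickness_nm = cr_thickness_nm),
    list(index = gold_index, thickness_nm = gold_thickness_nm))
  if (!is.null(adlayer)) layers <- c(layers, list(adlayer))
  optical_stack(prism_index = prism_index, layers = layers,
                bulk_index = bulk_index, wavelength_nm = wavelength_nm)
}

cplx <- function(x) x + 0i

# Normal component of the wavevector in a medium, principal branch with
# Im(kz) >= 0 so evanescent/absorbed waves decay into the layer.
kz_component <- function(k0, n, kx) {
  kz <- sqrt(cplx((k0 * n)^2 - kx^2))
  flip <- Im(kz) < 0 | (Im(kz) == 0 & Re(kz) < 0)
  kz[flip] <- -kz[flip]
  kz
}

#' Multilayer Fresnel reflectance (transfer-matrix method)
#'
#' Reflectance `|r|^2` of the full stack for a plane wave incident from the
#' prism at the given internal angle, computed with the standard 2x2
#' characteristic-matrix method. Vectorised over `angle_deg`.
#'
#' @param stack an [optical_stack()].
#' @param angle_deg incidence angle(s) in the prism, strictly inside
#'   (0, 90) degrees.
#' @param polarization `"TM"` (p, plasmon-active) or `"TE"` (s).
#' @return reflectance value(s) in `[0, 1]`.
#' @examples
#' fresnel_reflectance(optical_stack(1.5, list(), 1.0), 45, "TM")
#' @export
fresnel_reflectance <- function(stack, angle_deg, polarization = c("TM", "TE")) {
  stopifnot(inherits(stack, "optical_stack"))
  polarization <- match.arg(polarization)
  if (length(angle_deg) == 0 || any(!is.finite(angle_deg)) ||
      any(angle_deg <= 0) || any(angle_deg >= 90))
    stop_input("angle_deg must lie strictly inside (0, 90) degrees")

  k0 <- 2 * pi / stack$wavelength_nm
  th <- angle_deg * pi / 180
  kx <- k0 * stack$prism_index * sin(th)

  q_of <- function(n, kz) if (polarization == "TM") kz / (k0 * n^2) else kz / k0

  # 2x2 characteristic matrix accumulated across the finite layers,
  # element-wise over the angle vector.
  m11 <- m22 <- rep(1 + 0i, length(kx))
  m12 <- m21 <- rep(0 + 0i, length(kx))
  for (l in stack$layers) {
    n <- cplx(l$index)
    kz <- kz_component(k0, n, kx)
    q <- q_of(n, kz)
    ph <- kz * l$thickness_nm
    cph <- cos(ph); sph <- sin(ph)
    a11 <- cph;            a12 <- -1i * sph / q
    a21 <- -1i * q * sph;  a22 <- cph
    t11 <- m11 * a11 + m12 * a21
    t12 <- m11 * a12 + m12 * a22
    t21 <- m21 * a11 + m22 * a21
    t22 <- m21 * a12 + m22 * a22
    m11 <- t11; m12 <- t12; m21 <- t21; m22 <- t22
  }
  q1 <- q_of(cplx(stack$prism_index),
             kz_component(k0, cplx(stack$prism_index), kx))
  qN <- q_of(cplx(stack$bulk_index),
             kz_component(k0, cplx(stack$bulk_index), kx))
  num <- q1 * (m11 + m12 * qN) - (m21 + m22 * qN)
  den <- q1 * (m11 + m12 * qN) + (m21 + m22 * qN)
  R <- Mod(num / den)^2
  if (any(!is.finite(R)))
    stop_input("non-finite reflectance; stack is nonphysical at the given angle")
  # Clamp sub-epsilon overshoot from rounding; passive media cannot exceed 1.
  pmin(pmax(R, 0), 1)
}

#' Critical angle of total internal reflection
#'
#' `asin(n_bulk / n_prism)` in degrees: the angle beyond which light incident
#' from the prism is totally reflected at an interface with the bulk medium.
#' Tracks the bulk refractive index only, which is what makes it usable as a
#' built-in bulk reference for sensorgrams.
#'
#' @param n_bulk bulk refractive index, `0 < n_bulk < n_prism`.
#' @param n_prism prism refractive index.
#' @return critical angle in degrees.
#' @examples
#' theoretical_critical_angle(1.0, 2.0)      # 30
#' theoretical_critical_angle(1.333, 1.5125) # ~61.80
#' @export
theoretical_critical_angle <- function(n_bulk, n_prism) {
  if (any(!is.finite(n_bulk)) || any(!is.finite(n_prism)) ||
      any(n_bulk <= 0) || any(n_bulk >= n_prism))
    stop_input("need 0 < n_bulk < n_prism for a critical angle to exist")
  asin(n_bulk / n_prism) * 180 / pi
}

#' Simulate a full SPR curve
#'
#' Evaluates the TM/TE reflectance ratio of the stack at every pixel-centre
#' angle of the geometry. This is the noiseless ground truth that
#' [synthesize_image_set()] wraps in detector frames, and the oracle used
#' throughout the test-suite.
#'
#' @param stack an [optical_stack()].
#' @param geometry a [detector_geometry()]; its window must lie inside
#'   (0, 90) degrees.
#' @return an [spr_curve()] with one point per pixel.
#' @export
simulate_spr_curve <- function(stack, geometry) {
  stopifnot(inherits(geometry, "detector_geometry"))
  ang <- geometry_angles(geometry)
  if (min(ang) <= 0 || max(ang) >= 90)
    stop_input("geometry window must lie inside (0, 90) degrees")
  rtm <- fresnel_reflectance(stack, ang, "TM")
  rte <- fresnel_reflectance(stack, ang, "TE")
  if (any(rte <= 0))
    stop_input("TE reflectance vanishes inside the window; ratio undefined")
  spr_curve(ang, rtm / rte)
}
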