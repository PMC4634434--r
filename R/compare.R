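#' Three-method fit comparison table
#'
#' Fits the asymmetric, high-order polynomial and sigmoid-asymmetric models
#' to one full SPR curve and tabulates per-region coefficient of
#' determination and error variance, plus the angle estimates each method
#' supports (the asymmetric and polynomial methods cannot deliver a
#' critical angle). Mirrors the standard comparison layout used to argue
#' for full-curve fitting.
#'
#' @param curve an [spr_curve()].
#' @param split a [region_split()]; default from the sigmoid-asymmetric fit.
#' @param order polynomial order (default 24).
#' @return data.frame with one row per (method, region), columns `method`,
#'   `region`, `n`, `cd`, `ev`, `theta_RA_deg`, `theta_CA_deg`; the fits
#'   themselves in attribute `fits`.
#' @export
compare_fit_methods <- function(curve, split = NULL, order = 24L) {
  stopifnot(inherits(curve, "spr_curve"))
  fits <- list(
    asymmetric = fit_curve(curve, "asymmetric"),
    polynomial = fit_polynomial(curve, order),
    sigmoid_asymmetric = fit_curve(curve, "sigmoid_asymmetric"))
  if (is.null(split)) split <- default_region_split(fits$sigmoid_asymmetric)
  rows <- lapply(names(fits), function(m) {
    ft <- fits[[m]]
    rq <- region_quality(curve, ft, split)
    ra <- tryCatch(resonance_angle(ft, split), error = function(e) NA_real_)
    ca <- if (m == "sigmoid_asymmetric")
      tryCatch(critical_angle(ft, split), error = function(e) NA_real_)
    else NA_real_
    data.frame(method = m, rq,
               theta_RA_deg = ifelse(rq$region == "resonance", ra, NA),
               theta_CA_deg = ifelse(rq$region == "critical", ca, NA))
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  attr(out, "split") <- split
  out
}
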