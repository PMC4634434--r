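---
title: "Full-curve fitting of angular-interrogation SPR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full-curve fitting of angular-interrogation SPR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprfit)
```

## The measurement and the problem

In a Kretschmann-configuration surface plasmon resonance (SPR) instrument a
p-polarised wedge-shaped beam is totally internally reflected at the base of
a prism carrying a thin gold film. A 2-D detector placed behind the prism
images reflected intensity against incidence angle — here 1280 columns
covering a 7.296 degree window, i.e. 0.0057 degrees per pixel. Two angular
landmarks carry the sensing information:

* the **resonance angle** `theta_RA`, the reflectance minimum where the
  evanescent field drives the surface plasmon; it shifts with *everything*
  near the gold surface — adsorbed mass and the bulk refractive index alike;
* the **critical angle** `theta_CA`, the onset of total internal reflection
  at `asin(n_bulk / n_prism)`; it responds to the bulk index only.

Conventional fitting methods (asymmetric dip equations, local polynomials)
work on a narrow window around the dip and deliver only `theta_RA`, so a
bulk refractive-index step — a buffer change, a glycerol gradient — is
indistinguishable from binding. Fitting the *full* curve, step and dip
together, yields both angles from a single channel, and the bulk
contribution can be subtracted without a reference channel:

$$\theta_{SAA} = \theta_{RA} - k\,\theta_{CA},$$

where `k` is the instrument's bulk-response slope, calibrated from a bulk
index ladder by regressing `theta_RA` against `theta_CA`
(`calibrate_bulk_response()`). `theta_SAA`, the specific adsorption angle,
then tracks surface binding only.

## The sigmoid-asymmetric model

`fit_curve()` fits the nine-parameter model

$$R(X) = \frac{A\left[1 - \{B + C(X-D)\}\right]}{(X-D)^2 + E^2}
  + \frac{F}{1 + e^{G(X-H)}} + I\,X$$

to the full reflectance-ratio curve. The first term is an asymmetric
Lorentzian: `D` is the dip-centre angle (degrees), `E` the half-width
(degrees), `A` scales the depth, and `C` (per degree) skews the profile the
way a radiatively damped plasmon resonance is skewed. The second term is a
logistic step for the total-internal-reflection transition: `H` is the step
centre (degrees), `G` its steepness (per degree; negative for a rising
step; the 10–90% width is `4.39/|G|`), `F` the step amplitude. `I` is a
linear tilt for residual illumination trends. The resonance angle is read
off as the model minimum in the resonance region; the critical angle as the
maximum of the model's analytic first derivative
(`eval_sigmoid_asymmetric_derivative()`) in the critical-angle region.

Two structural properties of this model shape the whole fitting design:

* **Gauge freedom.** Only the combinations `A(1-B)` and `A·C` enter the
  model value, so `(A, B, C)` carries one redundant degree of freedom. An
  unconstrained optimiser drifts along this null direction. `fit_curve()`
  therefore holds `B` at its initial value (0 by default) — a gauge choice,
  not a restriction of the function family.
* **Term swapping.** The logistic term can imitate a constant (`G -> 0`),
  a global ramp (`|G|` small, `H` far outside the window) or its own mirror
  image (`F, G` sign flip plus offset). On curves the model does not
  describe perfectly, plain least squares readily abandons the
  critical-angle step for one of these degenerate readings — and with it
  any ability to report a critical angle.

## Fitting algorithm

`initial_guess()` reads the morphology directly off a lightly smoothed copy
of the samples (smoothing support is fixed at about 0.03 degrees of angle,
not a fixed pixel count, so landmarks do not move under resampling): dip
centre from the global minimum, step centre from the steepest rise left of
the dip with a sub-pixel parabolic correction, step amplitude from median
levels on either side of the edge, dip half-width at half depth, and step
width from the 50%-of-maximum-slope extent of the rising edge. Curves
without this morphology (no interior minimum, no rising edge) are rejected
rather than fitted.

The model is linear in `(A(1-B), A·C, F, I)` once `(D, E, G, H)` are fixed,
so the fit uses **variable projection**: Levenberg–Marquardt
(`minpack.lm::nls.lm`, `ftol = ptol = 1e-12`, up to 1024 iterations per
stage) runs over the four nonlinear parameters only — with `E` and `-G` in
log space, which keeps both positive and pushes the `G -> 0` degeneracy
infinitely far away — and the linear block is re-solved exactly by QR at
every step. The nonlinear search is multi-started over the step steepness
(the one direction with genuinely separated basins) and retried once from a
seeded perturbation on non-convergence; the reported solution never has a
larger SSE than the initial guess.

Morphology-derived box constraints pin each term to the feature it models:
the step centre stays in a trust window around the morphological edge
estimate (two pixels or half the measured rise width, whichever is larger),
the steepness stays between "resolvable within the window" and "a quarter
pixel wide", the step amplitude is floored at a quarter of the measured
edge amplitude, and the dip keeps `A <= 0` (in the `B = 0` gauge) with its
centre inside the curve. On data actually generated from the model none of
these constraints bind — the morphological estimates then reproduce the
generating parameters, which is why self-recovery is exact to machine
precision — while on instrument-like curves they are what keeps the
logistic term on the TIR step.

### Reading the angles

`critical_angle()` maximises the analytic derivative over the critical-angle
region by a dense scan at one tenth of a pixel followed by
`stats::optimize` in the bracketing cell (`1e-9` tolerance), so the
estimate is sub-pixel and grid-independent. `resonance_angle()` does the
same with the model minimum, but first re-solves the dip block —
`(D, E)` plus the linear coefficients — against the resonance-region points
with the step position and steepness held. The reason is mild model
misspecification: on realistic curves the joint least-squares optimum
carries residual structure outside the dip, and that structure levers the
global-fit minimum by a few pixels. Re-solving the dip locally removes the
lever; on model-generated data the polish is a no-op. `refine = FALSE`
restores the raw fitted-model minimum.

The two regions are separated at a **criterion angle**. The default
(`default_region_split()`) is the midpoint between the morphological step
and dip centres, which follows the features wherever the instrument puts
them; fixed-pixel protocols (600 for water-like, 550 for air-like runs on
the reference instrument) are available through `region_split_at_pixel()`.
`region_quality()` reports the coefficient of determination and the error
variance — the population variance of the residuals, offset-invariant by
construction — separately per region, which is the standard way these
fitting methods are compared.

## The simulator

`fresnel_reflectance()` implements the standard 2×2 characteristic-matrix
(transfer-matrix) method for the layered stack, vectorised over angle, with
the `Im(k_z) >= 0` branch so evanescent and absorbed waves decay into each
layer. `simulate_spr_curve()` evaluates the TM/TE reflectance ratio at
every pixel angle — the same normalisation an instrument reaches by
dividing dark-subtracted TM by TE frames — and
`synthesize_image_set()` wraps it in synthetic detector frames (dark
pedestal 400 counts, read noise 8 counts, 1% multiplicative intensity
noise on a 30000-count illumination by default, all seeded), so the whole
image pipeline (`normalize_images()`, `extract_curve()`, 100-row centred
band averaging) can be exercised without hardware.

The default chip is BK7 (n = 1.5125 at 770 nm) / 2 nm chromium / 50 nm
gold / bulk medium. Gold uses a handbook permittivity of about
−23.6 + 1.7i at 770 nm (Johnson & Christy tabulation; n ≈ 0.175 + 4.861i)
and chromium n ≈ 3.08 + 3.34i; both are arguments of
`kretschmann_stack()`. With these constants the simulated water dip sits
near 66.54° and the air dip near 42.57°, close to the reference
instrument's published working points. The default windows are
60.5–67.796° for water-like and 38.8–46.096° for air-like runs: both keep
the fixed-pixel criteria between the two landmarks, and the water window
leaves room for the bulk ramps used in validation (a bulk step from 1.3330
to 1.3402 moves the dip by about +0.77°).

What the generator emulates — and what it does not: the curves are *ideal*
Fresnel ratios plus simple detector noise. Real wedge-beam instruments add
angular smearing from beam divergence and the LED's spectral width,
illumination non-uniformity, and polariser leakage, which in practice
flatten the below-critical region and round the TIR kink. Two consequences
matter for interpreting the validation suite. First, the ideal TIR
transition is a one-sided cusp, not a logistic: its least-squares step
centre sits slightly below the true critical angle, so the critical-angle
estimate carries a small negative bias (about −0.03° for water, −0.02° for
air under the defaults) that would largely be absorbed into the instrument
calibration in practice. Second, the ideal below-critical TM/TE ratio of
an air-backed gold film has a pseudo-Brewster hump of ~0.07 amplitude that
*no* term of the nine-parameter model can represent; the best
step-faithful fit of the ideal air curve therefore plateaus near a
full-curve CD of 0.95, and in that left region the order-24 polynomial —
free of any structural commitment — scores better than the
sigmoid-asymmetric model. On instrument data, where the left region is
nearly flat, the full-curve model dominates; passing the simulation suite
therefore validates the algorithmic chain, not the claim that every ideal
Fresnel curve is inside the model family.

## Bulk referencing in practice

```{r ramp, eval = FALSE}
geom <- detector_geometry(1280, 7.296, 60.5)
frames <- lapply(seq(1.3330, 1.3402, length.out = 6), function(nb)
  simulate_spr_curve(kretschmann_stack(nb), geom))
sg <- build_sensorgram(frames, calibration = "self")
attr(sg, "calibration")   # slope k and r-squared of the ladder
max(abs(sg$delta_SAA)) / max(abs(sg$delta_RA))
```

On the simulated bulk-only ladder the two angles are collinear
(r² > 0.999) and self-calibrated referencing suppresses the bulk excursion
in `theta_SAA` to below 1% of the `theta_RA` excursion, while a growing
n = 1.45 adlayer at fixed bulk moves `theta_SAA` monotonically with the
critical angle steady to well under 0.01°. Note that the simulated chip's
slope is k ≈ 1.33, not the reference instrument's 0.97: `k` is
instrument-specific (wedge optics, pixel-angle nonlinearity), which is why
`build_sensorgram()` takes an explicit `calibration_model()` — the 0.97
default in `specific_adsorption_angle()` is the published reference value,
not a universal constant — and why sensorgrams report both absolute and
baseline-subtracted columns (`delta_*`), the latter being what sensorgram
figures conventionally show.

`build_sensorgram()` warm-starts each frame's fit from the previous
frame's parameters and falls back to a fresh morphological guess when the
warm start fails; frames that still fail are kept, flagged
`converged = FALSE`, rather than silently dropped.

## Numerical choices and degenerate inputs

* Polynomial comparison fits (`fit_polynomial()`, default order 24) are
  solved by QR in the variable `z = 2(X-a)/(b-a) - 1`; raw-degree normal
  equations are numerically singular at this order.
* The logistic term is evaluated through `plogis`, so it cannot overflow
  far from its centre.
* A step steeper than a pixel saturates the likelihood in `G`; its fitted
  value is then only meaningful up to the saturation plateau.
* Curves must have at least 3 points, strictly increasing angles, finite
  values, and more points than model parameters; region splits must leave
  at least 3 points on each side; an extremum landing on a region boundary
  is an error, not a value.
* All validation problem sizes: 1280-point curves for single-fit checks,
  six-frame series for ramps and adlayers, 100-row bands for the image
  pipeline — one fit takes a few tens of milliseconds.

## Known limitations

* The critical-angle estimate inherits a small negative bias from the
  asymmetry of an ideal TIR cusp (see above); on hardware this folds into
  the angle calibration.
* The model has no additive offset term (the tilt `I·X` doubles as one
  across a narrow window); data with a genuinely offset baseline should be
  normalised first.
* `k` calibration assumes the bulk ladder spans a linear range of both
  responses; strongly absorbing or dispersive bulk media are out of scope,
  as is any kinetic (rate-constant) modelling of binding curves.
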