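test_that("a symmetric dip puts the resonance angle exactly at its centre", {
  # C = 0 makes the asymmetric term an even Lorentzian about D
  p <- sa_params(A = -0.09, B = 0, C = 0, D = 64.2, E = 0.3,
                 F = 0.4, G = -60, H = 61.5, I = 0)
  x <- seq(60, 67.296, by = 0.0057)
  ft <- fit_curve(spr_curve(x, eval_sigmoid_asymmetric(p, x)))
  ra <- resonance_angle(ft)
  expect_equal(ra, 64.2, tolerance = 1e-4)
})

test_that("a pure logistic step puts the critical angle at its centre", {
  # negligible dip far to the right so the morphology is detectable;
  # the derivative maximum of the logistic sits exactly at H
  p <- sa_params(A = -0.02, B = 0, C = 0, D = 66.9, E = 0.1,
                 F = 0.5, G = -50, H = 61.5, I = 0)
  x <- seq(60, 67.296, by = 0.0057)
  ft <- fit_curve(spr_curve(x, eval_sigmoid_asymmetric(p, x)))
  ca <- critical_angle(ft)
  expect_equal(ca, 61.5, tolerance = 1e-3)
})

test_that("angle extraction rejects unsupported models and bad regions", {
  pf <- fit_polynomial(water_curve())
  expect_error(critical_angle(pf, default_region_split(water_fit())),
               "sigmoid-asymmetric")
  # criterion right of the dip leaves no interior resonance minimum
  expect_error(resonance_angle(water_fit(), region_split(67.2)),
               "minimum|points")
})

test_that("simulated water physics is recovered within instrument accuracy", {
  cv <- water_curve()
  ft <- water_fit()
  an <- angle_estimates(ft)
  expect_lt(abs(an$theta_CA - theoretical_critical_angle(1.333, 1.5125)),
            0.05)
  expect_lt(abs(an$theta_RA - cv$angles_deg[which.min(cv$values)]), 0.01)
  expect_lt(an$theta_CA, an$theta_RA)
})

test_that("angle estimates are insensitive to the criterion placement", {
  ft <- water_fit()
  sp <- default_region_split(ft)
  ra1 <- resonance_angle(ft, sp)
  ra2 <- resonance_angle(ft, region_split(sp$criterion_deg + 0.2))
  expect_lt(abs(ra1 - ra2), 2e-3)
  ca1 <- critical_angle(ft, sp)
  ca2 <- critical_angle(ft, region_split(sp$criterion_deg + 0.2))
  expect_lt(abs(ca1 - ca2), 1e-6)
})

test_that("angle estimates are stable under 2x subsampling", {
  for (cv in list(water_curve(), air_curve())) {
    ft <- fit_curve(cv)
    an <- angle_estimates(ft)
    idx <- seq(1, length(cv), by = 2)
    sub <- spr_curve(cv$angles_deg[idx], cv$values[idx])
    ans <- angle_estimates(fit_curve(sub))
    expect_lt(abs(ans$theta_RA - an$theta_RA), 0.0057)
    expect_lt(abs(ans$theta_CA - an$theta_CA), 0.0057)
  }
})

test_that("bulk-response calibration recovers known slopes", {
  ca <- seq(61.5, 62.1, length.out = 7)
  cal <- calibrate_bulk_response(ca, ca + 5, mode = "absolute")
  expect_equal(cal$k, 1, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)

  set.seed(53)
  ra <- 2 + 1.4 * ca + rnorm(7, sd = 0.001)
  cal2 <- calibrate_bulk_response(ca, ra)
  # closed-form OLS oracle
  k_hat <- sum((ca - mean(ca)) * (ra - mean(ra))) / sum((ca - mean(ca))^2)
  expect_equal(cal2$k, k_hat, tolerance = 1e-12)
  expect_lt(abs(cal2$k - 1.4), 0.02)

  expect_error(calibrate_bulk_response(rep(61, 5), 1:5), "all equal")
  expect_error(calibrate_bulk_response(1:2, 1:2), ">= 3")
})

test_that("the specific adsorption angle is theta_RA minus k theta_CA", {
  expect_equal(specific_adsorption_angle(62.4, 62.4, k = 1), 0)
  expect_equal(specific_adsorption_angle(66.62, 61.83, k = 0), 66.62)
  # reference-instrument arithmetic with the published k
  expect_equal(specific_adsorption_angle(66.6189, 61.8309, k = 0.97),
               6.642927, tolerance = 1e-10)
  cal <- calibration_model(k = 1.25)
  expect_equal(specific_adsorption_angle(10, 4, cal), 5)
})

test_that("identical frames give constant sensorgram traces", {
  geom <- detector_geometry(640L, 7.296, 60.5)
  cv <- simulate_spr_curve(kretschmann_stack(1.333), geom)
  sg <- build_sensorgram(rep(list(cv), 5))
  expect_true(all(sg$converged))
  expect_lt(max(abs(diff(sg$theta_RA_deg))), 1e-6)
  expect_lt(max(abs(diff(sg$theta_CA_deg))), 1e-6)
  expect_lt(max(abs(sg$delta_SAA)), 1e-6)
  expect_equal(sg$time_s, 0:4)
})

test_that("self-calibrated referencing cancels a pure bulk ramp", {
  sg <- bulk_ramp_sensorgram()
  expect_true(all(sg$converged))
  cal <- attr(sg, "calibration")
  expect_gte(cal$r_squared, 0.99)
  expect_lte(max(abs(sg$delta_SAA)), 0.05 * max(abs(sg$delta_RA)))
})

test_that("adlayer growth moves theta_SAA but not the critical angle", {
  sg <- adlayer_sensorgram()
  expect_true(all(sg$converged))
  expect_true(all(diff(sg$theta_SAA_deg) > 0))
  expect_lt(max(abs(sg$delta_CA)), 0.01)
})

test_that("sensorgram input validation", {
  expect_error(build_sensorgram(list()), "at least one frame")
  x <- seq(60, 64, by = 0.05)
  flat <- spr_curve(x, 1 + 0 * x)
  expect_error(build_sensorgram(list(flat)), "first frame unfittable")
})
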