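test_that("bare-interface reflectance matches the two-medium closed forms", {
  # normal incidence: ((n1 - n2)/(n1 + n2))^2, polarisation-independent
  st <- optical_stack(1.5, list(), 1.0)
  expect_equal(fresnel_reflectance(st, 1e-7, "TM"), 0.04, tolerance = 1e-9)
  expect_equal(fresnel_reflectance(st, 1e-7, "TE"), 0.04, tolerance = 1e-9)

  # closed-form Fresnel amplitude coefficients, coded independently here
  closed_form <- function(n1, n2, th_deg, pol) {
    th <- th_deg * pi / 180
    ct1 <- cos(th)
    ct2 <- sqrt(as.complex(1 - (n1 * sin(th) / n2)^2))
    r <- if (pol == "TM") (n2 * ct1 - n1 * ct2) / (n2 * ct1 + n1 * ct2)
         else (n1 * ct1 - n2 * ct2) / (n1 * ct1 + n2 * ct2)
    Mod(r)^2
  }
  set.seed(11)
  for (i in 1:1000) {
    n1 <- runif(1, 1.2, 2.0)
    n2 <- runif(1, 1.0, n1 - 0.05)
    a <- runif(1, 1, 89)
    pol <- sample(c("TM", "TE"), 1)
    st <- optical_stack(n1, list(), n2)
    expect_lt(abs(fresnel_reflectance(st, a, pol) -
                  closed_form(n1, n2, a, pol)), 1e-12)
  }
})

test_that("total internal reflection at a lossless interface gives R = 1", {
  st <- optical_stack(1.5125, list(), 1.0)
  for (a in c(50, 60, 75, 89)) {
    expect_equal(fresnel_reflectance(st, a, "TM"), 1, tolerance = 1e-12)
    expect_equal(fresnel_reflectance(st, a, "TE"), 1, tolerance = 1e-12)
  }
  # lossless dielectric coating above the critical angle is still total
  st2 <- optical_stack(1.5125, list(list(index = 1.46 + 0i, thickness_nm = 120)),
                       1.0)
  expect_equal(fresnel_reflectance(st2, 80, "TM"), 1, tolerance = 1e-12)
})

test_that("reflectance respects the passive energy bound everywhere", {
  set.seed(23)
  for (i in 1:40) {
    layers <- replicate(sample(0:3, 1),
      list(index = complex(real = runif(1, 0.2, 3.5),
                           imaginary = runif(1, 0, 5)),
           thickness_nm = runif(1, 1, 80)), simplify = FALSE)
    st <- optical_stack(runif(1, 1.4, 1.8), layers, runif(1, 1.0, 1.35))
    ang <- seq(5, 85, by = 5)
    for (pol in c("TM", "TE")) {
      R <- fresnel_reflectance(st, ang, pol)
      expect_true(all(R >= 0 & R <= 1))
    }
  }
})

test_that("the package and an independent Airy-recursion oracle agree", {
  ang <- seq(61, 69.5, by = 0.01)
  st <- kretschmann_stack(1.333)
  for (pol in c("TM", "TE")) {
    mine <- fresnel_reflectance(st, ang, pol)
    theirs <- default_chip_oracle(1.333, ang, pol)
    expect_lt(max(abs(mine - theirs)), 1e-10)
  }
  # deep TM resonance minimum below 0.15 somewhere inside (62, 70),
  # located on the independent oracle's dense scan
  scan <- default_chip_oracle(1.333, seq(62, 70, by = 0.005), "TM")
  expect_lt(min(scan), 0.15)
})

test_that("reflectance is continuous at pixel resolution", {
  for (cv in list(water_curve(), air_curve())) {
    expect_lt(max(abs(diff(cv$values))), 0.15)
  }
})

test_that("theoretical critical angle is the arcsine closed form", {
  expect_equal(theoretical_critical_angle(1.0, 2.0), 30)
  expect_equal(theoretical_critical_angle(1.0, 1.5125),
               asin(1.0 / 1.5125) * 180 / pi, tolerance = 1e-12)
  expect_equal(theoretical_critical_angle(1.330, 1.5125),
               61.5639, tolerance = 1e-3)
  expect_error(theoretical_critical_angle(1.6, 1.5125), "critical angle")
  expect_error(theoretical_critical_angle(-1, 1.5), "critical angle")
})

test_that("simulated curves have the expected SPR morphology", {
  # lossless dielectric stack entirely above critical: TM/TE ratio is 1
  st <- optical_stack(1.5125, list(list(index = 1.46 + 0i, thickness_nm = 90)),
                      1.0)
  geom <- detector_geometry(64L, 5, 70)
  cv <- simulate_spr_curve(st, geom)
  expect_equal(cv$values, rep(1, 64), tolerance = 1e-12)

  # water window of the reference instrument: a single global minimum,
  # above the critical-angle region
  cw <- water_curve()
  i <- which.min(cw$values)
  expect_gt(i, 1); expect_lt(i, length(cw))
  expect_gt(cw$angles_deg[i], theoretical_critical_angle(1.333, 1.5125))
  expect_equal(sum(diff(sign(diff(cw$values))) > 0), 1)

  # air window as in the instrument description: minimum inside (41.3, 44)
  ca <- simulate_spr_curve(kretschmann_stack(1.000),
                           detector_geometry(1280L, 7.296, 38))
  amin <- ca$angles_deg[which.min(ca$values)]
  expect_gt(amin, 41.3); expect_lt(amin, 44)
})

test_that("invalid stacks and angles are rejected", {
  expect_error(optical_stack(1.0, list(), 1.333), "prism_index must exceed")
  expect_error(optical_stack(1.5, list(list(index = 1 + 0i, thickness_nm = -3)),
                             1.0), "thickness")
  st <- optical_stack(1.5, list(), 1.0)
  expect_error(fresnel_reflectance(st, 0, "TM"), "strictly inside")
  expect_error(fresnel_reflectance(st, 95, "TM"), "strictly inside")
  expect_error(simulate_spr_curve(st, detector_geometry(10L, 10, 85)),
               "window")
})
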