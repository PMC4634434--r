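# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

water_geometry <- function() detector_geometry(1280L, 7.296, 60.5)
air_geometry <- function() detector_geometry(1280L, 7.296, 38.8)

water_curve <- function()
  fixture("water_curve",
          simulate_spr_curve(kretschmann_stack(1.333), water_geometry()))
air_curve <- function()
  fixture("air_curve",
          simulate_spr_curve(kretschmann_stack(1.000), air_geometry()))

water_fit <- function() fixture("water_fit", fit_curve(water_curve()))
air_fit <- function() fixture("air_fit", fit_curve(air_curve()))

# reference sigmoid-asymmetric parameter set shaped like a water curve
reference_sa_params <- function()
  sa_params(A = -0.27, B = 0, C = 0.05, D = 66.5, E = 0.55,
            F = 0.055, G = -47, H = 61.8, I = 0.008)

reference_sa_curve <- function() {
  p <- reference_sa_params()
  x <- 60 + (0:1279) * 0.0057
  spr_curve(x, eval_sigmoid_asymmetric(p, x))
}

# Independent multilayer reflectance oracle: recursive two-interface
# (Airy) composition of interface Fresnel coefficients, structurally
# different from the characteristic-matrix implementation in the package.
oracle_reflectance <- function(n_list, d_list, wavelength_nm, angle_deg,
                               polarization = "TM") {
  k0 <- 2 * pi / wavelength_nm
  kx <- k0 * Re(n_list[1]) * sin(angle_deg * pi / 180)
  kz <- sqrt(as.complex(k0^2 * n_list^2 - kx^2))
  kz <- ifelse(Im(kz) < 0 | (Im(kz) == 0 & Re(kz) < 0), -kz, kz)
  r_int <- function(i, j) {
    if (polarization == "TM")
      (n_list[j]^2 * kz[i] - n_list[i]^2 * kz[j]) /
        (n_list[j]^2 * kz[i] + n_list[i]^2 * kz[j])
    else
      (kz[i] - kz[j]) / (kz[i] + kz[j])
  }
  m <- length(n_list)
  r <- r_int(m - 1, m)
  if (m > 2) for (i in seq(m - 2, 1)) {
    ph <- exp(2i * kz[i + 1] * d_list[i + 1])
    r12 <- r_int(i, i + 1)
    r <- (r12 + r * ph) / (1 + r12 * r * ph)
  }
  Mod(r)^2
}

# default chip as plain vectors for the oracle
default_chip_oracle <- function(bulk_index, angle_deg, polarization = "TM") {
  n <- c(1.5125, 3.08 + 3.34i, sqrt(as.complex(-23.6 + 1.7i)), bulk_index)
  d <- c(NA, 2, 50, NA)
  vapply(angle_deg,
         function(a) oracle_reflectance(n, d, 770, a, polarization),
         numeric(1))
}

bulk_ramp_sensorgram <- function()
  fixture("bulk_ramp", {
    geom <- water_geometry()
    bulks <- seq(1.3330, 1.3402, length.out = 6)
    frames <- lapply(bulks, function(nb)
      simulate_spr_curve(kretschmann_stack(nb), geom))
    build_sensorgram(frames, calibration = "self")
  })

adlayer_sensorgram <- function()
  fixture("adlayer_series", {
    geom <- water_geometry()
    frames <- lapply(seq(0, 5, length.out = 6), function(d) {
      st <- kretschmann_stack(1.333, adlayer = if (d > 0)
        list(index = 1.45 + 0i, thickness_nm = d) else NULL)
      simulate_spr_curve(st, geom)
    })
    build_sensorgram(frames, calibration = calibration_model(k = 1.33))
  })
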