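test_that("phasor amplitude matches brute-force superposition maxima", {
  # trivial endpoints
  expect_equal(analytic_interference_amplitude(0.3, 0.2, 0), 0.5)
  expect_equal(analytic_interference_amplitude(0.3, 0.2, pi), 0.1)
  # independent oracle: dense-grid maximum of sin(u) + sin(u + dphi)
  u <- seq(0, 2 * pi, length.out = 20001)
  for (dphi in c(2 * pi / 3, pi / 2, 1.1)) {
    brute <- max(sin(u) + sin(u + dphi))
    expect_equal(analytic_interference_amplitude(1, 1, dphi), brute,
                 tolerance = 1e-6)
  }
  expect_equal(analytic_interference_amplitude(1, 1, 2 * pi / 3), 1,
               tolerance = 1e-9)
  expect_error(analytic_interference_amplitude(-1, 1, 0), ">= 0")
})

test_that("extrapolation continues the inducer waveform in space and time", {
  ind <- grating_params(spatial_frequency = 1, temporal_frequency = 5,
                        orientation = 90, contrast = 1, width = 1,
                        height = 2)
  # inducer centered at (0, -1): top border at y = 0
  ext <- extrapolate_inducer(ind, region = c(-0.5, 0.5, 0, 1),
                             inducer_center = c(0, -1), duration = 0.1)
  # at the border the extrapolated field equals the inducer field, all t
  for (k in c(1, 5, 11)) {
    want <- grating_luminance(ind, ext$x, rep(0, length(ext$x)), ext$t[k],
                              reference = c(0, -1))
    expect_equal(ext$field[, 1, k], want, tolerance = 1e-12)
  }
  # one full spatial period into the gap, phase repeats
  i0 <- which.min(abs(ext$y - 0)); i1 <- which.min(abs(ext$y - 1))
  expect_equal(ext$field[, i1, 1], ext$field[, i0, 1], tolerance = 1e-9)
  expect_error(extrapolate_inducer(ind, region = c(-0.5, 0.5, -1.5, 0.5),
                                   inducer_center = c(0, -1)),
               "overlaps")
})

test_that("extrapolated phase varies with offset as 2 pi f sin(theta) d", {
  # oracle: closed-form rotated sine evaluated at two offsets, phases
  # recovered by atan2 of quadrature samples
  f <- 0.5; theta <- 30 * pi / 180
  ind <- grating_params(spatial_frequency = f, temporal_frequency = 0,
                        orientation = 30, contrast = 1, width = 10,
                        height = 10)
  phase_at <- function(d) {
    # sample one modulation cycle through (2, d) along the modulation axis
    s <- seq(0, 1 / f, length.out = 1000)
    v <- grating_luminance(ind, 2 + s * cos(theta), d + s * sin(theta), 0,
                           reference = c(2, 0)) - 1
    atan2(v[1], (v[which.min(abs(s - 1 / (4 * f)))]))
  }
  d1 <- 0.7; d2 <- 1.9
  dphi <- (phase_at(d2) - phase_at(d1)) %% (2 * pi)
  want <- (2 * pi * f * sin(theta) * (d2 - d1)) %% (2 * pi)
  expect_equal(dphi, want, tolerance = 1e-2)
})

test_that("superposition adds modulations about the mean", {
  g <- grating_params(spatial_frequency = 1, temporal_frequency = 5,
                      orientation = 90, contrast = 0.4, width = 1, height = 1)
  a <- make_grating(g, duration = 0.05)
  # gain 0 leaves the target unchanged
  expect_equal(superpose(a, a, prediction_gain = 0)$field, a$field)
  # equal-amplitude in-phase doubles modulation
  dbl <- superpose(a, a, prediction_gain = 1)
  expect_equal(dbl$field - 1, 2 * (a$field - 1), tolerance = 1e-12)
  # antiphase cancels to a flat field at mean
  g_anti <- grating_params(spatial_frequency = 1, temporal_frequency = 5,
                           orientation = 90, phase = pi, contrast = 0.4,
                           width = 1, height = 1)
  b <- make_grating(g_anti, duration = 0.05)
  expect_equal(max(abs(superpose(a, b, 1)$field - 1)), 0, tolerance = 1e-12)
  # mismatched grids are rejected
  small <- make_grating(g, duration = 0.02)
  expect_error(superpose(a, small), "identical sample grid")
})

test_that("local contrast recovers Michelson contrast and phasor bounds", {
  g <- grating_params(contrast = 0.37, width = 2, height = 1,
                      temporal_frequency = 5, orientation = 0)
  pat <- make_grating(g, duration = 0.02)
  expect_equal(local_contrast(pat), 0.37, tolerance = 1e-6)
  # flat field
  flat <- make_grating(grating_params(contrast = 0), duration = 0.02)
  expect_equal(local_contrast(flat), 0)
  # two unit gratings at quarter-cycle offset: amplitude sqrt(2)
  a <- make_grating(grating_params(contrast = 0.5, width = 2, height = 1,
                                   temporal_frequency = 0), duration = 0)
  b <- make_grating(grating_params(contrast = 0.5, width = 2, height = 1,
                                   temporal_frequency = 0, phase = pi / 2),
                    duration = 0)
  both <- superpose(a, b, 1)
  brute <- (max(both$field) - min(both$field)) /
    (max(both$field) + min(both$field))
  expect_equal(brute, 0.5 * sqrt(2), tolerance = 1e-3)
  expect_equal(local_contrast(both), brute)
  expect_warning(local_contrast(pat, window_size = c(0.3, 0.3),
                                min_cycle = 1), "phase dependent")
})

test_that("pixel-level interference profiles match the analytic phasor", {
  offs <- seq(-6, 6, by = 0.25)
  for (theta in c(15, 30)) for (f in c(0.5, 1)) for (ph in c(0, pi / 2, pi)) {
    pa <- interference_profile(theta, f, ph, 0.5, offs)
    pp <- interference_profile(theta, f, ph, 0.5, offs, method = "pixel")
    expect_lt(max(abs(pa$local_contrast - pp$local_contrast)) / 1.5, 0.01)
  }
})

test_that("profiles are periodic with period 1/(f sin theta) and phasor-bounded", {
  offs <- seq(-6, 6, by = 0.05)
  prof <- interference_profile(30, 0.5, 0.7, 0.4, offs, c_t = 1)
  period <- 1 / (0.5 * sin(30 * pi / 180))
  shifted <- interference_profile(30, 0.5, 0.7, 0.4, offs + period, c_t = 1)
  expect_equal(prof$local_contrast, shifted$local_contrast, tolerance = 1e-9)
  expect_lte(max(prof$local_contrast), 1 + 0.4 + 1e-12)
  expect_gte(min(prof$local_contrast), 1 - 0.4 - 1e-12)
  # bounds attained over a full period
  expect_equal(max(prof$local_contrast), 1.4, tolerance = 1e-4)
  expect_equal(min(prof$local_contrast), 0.6, tolerance = 1e-4)
})

test_that("theta -> 0 gives the constant phasor amplitude", {
  offs <- seq(-5, 5, by = 0.5)
  prof <- interference_profile(0, 0.5, 2 * pi / 3, 1, offs, c_t = 1)
  expect_equal(prof$local_contrast, rep(1, length(offs)), tolerance = 1e-12)
  expect_error(interference_profile(30, 0.5, 0, 0.5, numeric(0)),
               "non-empty")
})

test_that("shifting target phase by pi shifts the profile by half a period", {
  offs <- seq(-8, 8, by = 0.1)
  p0 <- interference_profile(30, 0.5, 0, 0.5, offs)
  ppi <- interference_profile(30, 0.5, pi, 0.5, offs)
  half <- 0.5 / (0.5 * sin(30 * pi / 180))
  psh <- interference_profile(30, 0.5, 0, 0.5, offs + half)
  expect_equal(ppi$local_contrast, psh$local_contrast, tolerance = 1e-9)
})

test_that("profile period estimates match the closed form at both rotations", {
  # theta = 30, f = 0.5: period 4 deg; theta = 15: about 7.73 deg
  p30 <- interference_profile(30, 0.5, 0, 0.5, seq(-8, 8, by = 0.1),
                              method = "pixel")
  expect_equal(profile_period(p30), 4, tolerance = 0.05 / 4)
  p15 <- interference_profile(15, 0.5, 0, 0.5, seq(-12, 12, by = 0.1),
                              method = "pixel")
  expect_equal(profile_period(p15), 1 / (0.5 * sin(15 * pi / 180)),
               tolerance = 0.05 / 7.7)
  expect_gt(profile_period(p15), profile_period(p30))
})
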