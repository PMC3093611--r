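test_that("calibration inverts the phasor model in closed form", {
  obs <- calibrate_defaults(r_t = 1.49, r_in = 1.02, r_anti = 2.06,
                            baseline_threshold = 1)
  expect_equal(obs$suppression_trailing, 0.49)
  expect_equal(obs$suppression_leading, 0.54)
  expect_equal(obs$prediction_amplitude, 0.52)
  # no inducer effect when all ratios are 1
  none <- calibrate_defaults(r_t = 1, r_in = 1, r_anti = 1)
  expect_equal(none$suppression_leading, 0)
  expect_equal(none$prediction_amplitude, 0)
  expect_error(calibrate_defaults(r_in = 2.06, r_anti = 1.02), "antiphase")
  # baseline scaling: a_p is expressed in threshold units
  obs2 <- calibrate_defaults(baseline_threshold = 3)
  expect_equal(obs2$prediction_amplitude, 3 * 0.52)
})

test_that("prediction strength follows the attenuation laws", {
  obs <- calibrated
  # semisaturation: length L50 with everything else asymptotic gives a_p/2
  # (up to the 1000 ms duration attenuation)
  g_dur <- 1 - 2^(-1000 / obs$temporal_semisat)
  expect_equal(prediction_strength(obs, lead_cfg(length_deg = 15 / 60)),
               obs$prediction_amplitude / 2 * g_dur, tolerance = 1e-9)
  # gap of one e-folding constant multiplies by exp(-1)
  full <- prediction_strength(obs, lead_cfg())
  gapped <- prediction_strength(obs, lead_cfg(gap = 25 / 60))
  expect_equal(gapped / full, exp(-1), tolerance = 1e-9)
  # trailing edge and baseline carry no prediction
  expect_equal(prediction_strength(obs, trail_cfg()), 0)
  expect_equal(prediction_strength(obs, base_cfg()), 0)
  # dichoptic scales by the transfer fraction
  expect_equal(prediction_strength(obs, lead_cfg(eye_inducer = "right")),
               full * obs$interocular_transfer, tolerance = 1e-12)
  expect_lte(prediction_strength(obs, lead_cfg()), obs$prediction_amplitude)
})

test_that("effective contrast combines phasor sum and divisive suppression", {
  obs <- calibrated
  # baseline passes the raw contrast through
  ec <- effective_contrast(obs, base_cfg(), 0.8)
  expect_equal(ec$effective_contrast, 0.8)
  expect_equal(ec$suppression_divisor, 1)
  # leading in-phase: (c + a) / (1 + s_l)
  cfg <- lead_cfg(0)
  a <- prediction_strength(obs, cfg)
  ec <- effective_contrast(obs, cfg, 1.2)
  expect_equal(ec$phasor_sum,
               analytic_interference_amplitude(1.2, a, 0))
  expect_equal(ec$effective_contrast, (1.2 + a) / 1.54, tolerance = 1e-12)
  # leading antiphase with c > a: (c - a) / (1 + s_l), so the expected
  # threshold is theta0 (1 + s_l) + a  [closed form]
  expect_equal(expected_threshold(obs, lead_cfg(pi)),
               obs$baseline_threshold * 1.54 + a, tolerance = 1e-12)
  expect_equal(expected_threshold(obs, lead_cfg(0)),
               obs$baseline_threshold * 1.54 - a, tolerance = 1e-12)
  # trailing: phase-blind division by 1 + s_t
  expect_equal(effective_contrast(obs, trail_cfg(), 1.49)$effective_contrast,
               1.49 / 1.49, tolerance = 1e-12)
  expect_error(effective_contrast(obs, base_cfg(), -1), ">= 0")
})

test_that("detection probability is anchored at 75% and spans [0.5, 1]", {
  obs <- calibrated
  expect_equal(detection_probability(obs, obs$baseline_threshold), 0.75)
  expect_equal(detection_probability(obs, 0), 0.5)
  expect_equal(detection_probability(obs, 1e6), 1, tolerance = 1e-6)
  # lapses cap the upper asymptote
  lapsy <- observer_params(lapse_rate = 0.02)
  expect_equal(detection_probability(lapsy, 1e6), 0.98, tolerance = 1e-6)
  expect_error(detection_probability(obs, -0.1), ">= 0")
})

test_that("simulated trials are reproducible and hit the anchored rate", {
  obs <- calibrated
  cfg <- base_cfg()
  r1 <- withr::with_seed(7, simulate_trials(obs, cfg, rep(1, 1000)))
  r2 <- withr::with_seed(7, simulate_trials(obs, cfg, rep(1, 1000)))
  expect_identical(r1, r2)
  # 1e5 trials at threshold: proportion correct within 3 binomial SEs of 0.75
  big <- withr::with_seed(11, simulate_trials(obs, cfg, rep(1, 1e5)))
  expect_lt(abs(mean(big) - 0.75), 3 * sqrt(0.75 * 0.25 / 1e5))
  # saturated contrast: always correct
  expect_true(all(withr::with_seed(1,
    simulate_trials(obs, cfg, rep(1e5, 200))) == 1))
  one <- withr::with_seed(2, simulate_trial(obs, cfg, 1e5))
  expect_true(one$correct)
  expect_equal(one$side_reported, "left")
})

test_that("quarter-cycle phases are symmetric and intermediate", {
  obs <- calibrated
  t_quarter <- expected_threshold(obs, lead_cfg(pi / 2))
  t_threeq <- expected_threshold(obs, lead_cfg(3 * pi / 2))
  expect_equal(t_quarter, t_threeq, tolerance = 1e-12)
  expect_gt(t_quarter, expected_threshold(obs, lead_cfg(0)))
  expect_lt(t_quarter, expected_threshold(obs, lead_cfg(pi)))
})

test_that("trailing-edge expected thresholds are exactly phase-flat", {
  obs <- calibrated
  th <- vapply(c(0, pi / 2, pi, 3 * pi / 2),
               function(ph) expected_threshold(obs, trail_cfg(ph)),
               numeric(1))
  expect_equal(max(th) - min(th), 0)
})

test_that("the interference effect is monotone in length, duration, gap and eye", {
  obs <- calibrated
  diff_at <- function(...) {
    expected_threshold(obs, lead_cfg(pi, ...)) -
      expected_threshold(obs, lead_cfg(0, ...))
  }
  lens <- c(2, 5, 10, 30, 100, 400) / 60
  expect_true(all(diff(vapply(lens, function(L)
    diff_at(length_deg = L), numeric(1))) > 0))
  durs <- c(0.02, 0.05, 0.15, 0.4, 1, 2)
  expect_true(all(diff(vapply(durs, function(d)
    diff_at(duration = d), numeric(1))) > 0))
  gaps <- c(0, 5, 15, 40, 120) / 60
  expect_true(all(diff(vapply(gaps, function(g)
    diff_at(gap = g), numeric(1))) < 0))
  # dichoptic difference scales by the transfer fraction
  expect_equal(diff_at(eye_inducer = "right") / diff_at(),
               obs$interocular_transfer, tolerance = 1e-12)
})

test_that("observer parameter validation and serialization round-trip", {
  expect_error(observer_params(baseline_threshold = 0), "baseline_threshold")
  expect_error(observer_params(interocular_transfer = 1.5), "interocular")
  expect_error(observer_params(suppression_leading = -1), "suppression")
  obs <- calibrated
  tmp <- tempfile(fileext = ".json")
  save_observer(obs, tmp)
  expect_equal(load_observer(tmp), obs)
  tmpy <- tempfile(fileext = ".yaml")
  save_observer(obs, tmpy)
  expect_equal(load_observer(tmpy), obs)
  # packaged default equals the printed-means calibration
  expect_equal(default_observer(), calibrate_defaults())
})
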