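#' Parameters of the synthetic 2AFC observer
#'
#' The observer's contrast detection combines two mechanisms. (1) Divisive
#' surround suppression: an inducer abutting the target divides the target's
#' effective contrast by (1 + s), with separate strengths at the leading
#' (\code{s_l}) and trailing (\code{s_t}) edges, independent of relative
#' phase. (2) Additive predictive superposition at the leading edge only: an
#' internally generated waveform of amplitude up to \code{a_p} (the
#' extrapolated continuation of the inducer) is added to the input, so the
#' effective contrast follows the phasor sum of target and prediction —
#' raised for in-phase targets (constructive interference), lowered for
#' antiphase targets (destructive interference). The prediction amplitude
#' builds up with inducer length (half-saturating at \code{support_semisat}
#' arcmin), decays over a gap (e-folding \code{projection_constant} arcmin),
#' builds up over time (half-saturating at \code{temporal_semisat} ms), and
#' transfers partially between eyes (fraction \code{interocular_transfer}).
#'
#' Detection probability is a logistic function of log10 effective contrast
#' anchored at the baseline threshold: with no inducer and no lapses the
#' observer is 75\% correct exactly at \code{baseline_threshold}.
#'
#' @param baseline_threshold Michelson \% contrast giving 75\% correct with
#'   no inducer (> 0).
#' @param suppression_trailing,suppression_leading Unitless divisive
#'   suppression strengths s_t, s_l (>= 0).
#' @param prediction_amplitude Michelson \%; asymptotic amplitude a_p of the
#'   predicted waveform (>= 0).
#' @param support_semisat Arcmin; inducer length at which prediction strength
#'   reaches half its asymptote.
#' @param projection_constant Arcmin; e-folding distance of prediction
#'   strength over a gap.
#' @param temporal_semisat Milliseconds; duration at which prediction
#'   strength reaches half its asymptote.
#' @param interocular_transfer Fraction in [0, 1] multiplying the prediction
#'   amplitude when target and inducer are shown to different eyes.
#' @param transfer_suppression Logical; if TRUE the interocular transfer
#'   fraction also scales the suppression strengths dichoptically (default
#'   FALSE: only the prediction transfers).
#' @param psychometric_slope Logistic slope on log10 contrast.
#' @param lapse_rate Lapse fraction (default 0).
#' @param rng_seed Integer seed attached to the observer for simulation.
#' @return An \code{observer_params} object. Guess rate is fixed at 0.5
#'   (2AFC).
#' @seealso \code{\link{calibrate_defaults}} to build an observer from
#'   published suppression means.
#' @export
observer_params <- function(baseline_threshold = 1,
                            suppression_trailing = 0.49,
                            suppression_leading = 0.54,
                            prediction_amplitude = 0.52,
                            support_semisat = 15,
                            projection_constant = 25,
                            temporal_semisat = 122,
                            interocular_transfer = 0.5,
                            transfer_suppression = FALSE,
                            psychometric_slope = 10,
                            lapse_rate = 0,
                            rng_seed = 1L) {
  if (baseline_threshold <= 0) stop("baseline_threshold must be > 0")
  if (suppression_trailing < 0 || suppression_leading < 0)
    stop("suppression strengths must be >= 0")
  if (prediction_amplitude < 0) stop("prediction_amplitude must be >= 0")
  if (support_semisat <= 0 || projection_constant <= 0 ||
      temporal_semisat <= 0)
    stop("attenuation constants must be > 0")
  if (interocular_transfer < 0 || interocular_transfer > 1)
    stop("interocular_transfer must be in [0, 1]")
  if (lapse_rate < 0 || lapse_rate >= 0.5) stop("lapse_rate must be in [0, 0.5)")
  if (psychometric_slope <= 0) stop("psychometric_slope must be > 0")
  structure(list(baseline_threshold = baseline_threshold,
                 suppression_trailing = suppression_trailing,
                 suppression_leading = suppression_leading,
                 prediction_amplitude = prediction_amplitude,
                 support_semisat = support_semisat,
                 projection_constant = projection_constant,
                 temporal_semisat = temporal_semisat,
                 interocular_transfer = interocular_transfer,
                 transfer_suppression = transfer_suppression,
                 psychometric_slope = psychometric_slope,
                 lapse_rate = lapse_rate,
                 guess_rate = 0.5,
                 rng_seed = as.integer(rng_seed)),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("Synthetic 2AFC observer\n")
  cat(sprintf("  baseline threshold: %.4g%% Michelson, slope %.3g (log10), lapse %.3g\n",
              x$baseline_threshold, x$psychometric_slope, x$lapse_rate))
  cat(sprintf("  suppression: trailing %.3g, leading %.3g (divisive)\n",
              x$suppression_trailing, x$suppression_leading))
  cat(sprintf("  prediction: amplitude %.4g%%, L50 %.3g arcmin, gap e-fold %.3g arcmin,\n",
              x$prediction_amplitude, x$support_semisat,
              x$projection_constant))
  cat(sprintf("              T50 %.3g ms, interocular transfer %.3g%s\n",
              x$temporal_semisat, x$interocular_transfer,
              if (x$transfer_suppression) " (also scales suppression)" else ""))
  invisible(x)
}

#' Calibrate an observer from printed suppression ratios
#'
#' Inverts the phasor model in closed form at asymptotic prediction strength.
#' Given the threshold ratios (condition / baseline) for trailing-edge
#' targets (\code{r_t}, phase-averaged), in-phase leading targets
#' (\code{r_in}) and antiphase leading targets (\code{r_anti}):
#' \deqn{s_t = r_t - 1, \quad 1 + s_l = (r_{in} + r_{anti}) / 2, \quad
#'       a_p = \theta_0 (r_{anti} - r_{in}) / 2,}
#' since the in-phase and antiphase thresholds solve
#' (c ± a_p) / (1 + s_l) = theta_0. Defaults are the study's printed
#' suppression means (49\%, 2\% and 106\% threshold elevation) and the
#' spatial/temporal attenuation constants from the sweep experiments
#' (15 arcmin, 25 arcmin, 122 ms).
#'
#' @param r_t,r_in,r_anti Threshold ratios > 0; \code{r_anti >= r_in} is
#'   required (the phasor model cannot produce antiphase thresholds below
#'   in-phase ones).
#' @param baseline_threshold Michelson \% baseline threshold theta_0.
#' @param ... Further arguments passed to \code{\link{observer_params}}
#'   (attenuation constants, slope, transfer fraction, seed).
#' @return An \code{observer_params} object.
#' @examples
#' obs <- calibrate_defaults()        # the packaged study calibration
#' obs$suppression_trailing           # 0.49
#' @export
calibrate_defaults <- function(r_t = 1.49, r_in = 1.02, r_anti = 2.06,
                               baseline_threshold = 1, ...) {
  if (r_t <= 0 || r_in <= 0 || r_anti <= 0)
    stop("threshold ratios must be > 0")
  if (r_anti < r_in)
    stop("r_anti < r_in: the phasor model requires antiphase thresholds >= in-phase")
  s_t <- r_t - 1
  s_l <- (r_in + r_anti) / 2 - 1
  if (s_l < 0) stop("implied leading suppression is negative; check ratios")
  a_p <- baseline_threshold * (r_anti - r_in) / 2
  observer_params(baseline_threshold = baseline_threshold,
                  suppression_trailing = s_t,
                  suppression_leading = s_l,
                  prediction_amplitude = a_p, ...)
}

#' Effective prediction amplitude for a display
#'
#' The predicted waveform's amplitude after attenuation by inducer length,
#' gap, duration and eye of presentation:
#' \deqn{a_p \, (1 - 2^{-L/L_{50}}) \, e^{-g/\lambda} \, (1 - 2^{-T/T_{50}})
#'   \, \iota^{[dichoptic]}}
#' The prediction exists only ahead of the motion: at the trailing edge and
#' in baseline displays the strength is 0.
#'
#' @param params An \code{\link{observer_params}}.
#' @param config A \code{\link{display_config}}.
#' @return Michelson \% in [0, a_p].
#' @export
prediction_strength <- function(params, config) {
  stopifnot(inherits(params, "observer_params"),
            inherits(config, "display_config"))
  if (config$edge != "leading") return(0)
  L_arcmin <- config$inducer_length * 60
  gap_arcmin <- config$gap * 60
  T_ms <- config$duration * 1000
  if (L_arcmin < 0 || gap_arcmin < 0 || T_ms < 0)
    stop("length, gap and duration must be non-negative")
  g_len <- 1 - 2^(-L_arcmin / params$support_semisat)
  g_gap <- exp(-gap_arcmin / params$projection_constant)
  g_dur <- 1 - 2^(-T_ms / params$temporal_semisat)
  g_eye <- if (is_dichoptic(config)) params$interocular_transfer else 1
  params$prediction_amplitude * g_len * g_gap * g_dur * g_eye
}

# divisive suppression strength applying to a display
suppression_for <- function(params, config) {
  s <- switch(config$edge,
              leading = params$suppression_leading,
              trailing = params$suppression_trailing,
              baseline = 0)
  if (params$transfer_suppression && is_dichoptic(config))
    s <- s * params$interocular_transfer
  s
}

#' Effective contrast of a target in a display
#'
#' Combines the target contrast with the attenuated prediction via the phasor
#' sum, then divides by (1 + s): the model's full account of what the
#' observer responds to. The relative phase includes the offset-dependent
#' term 2 pi f sin(theta) d when the inducer is rotated relative to the
#' target.
#'
#' @param params An \code{\link{observer_params}}.
#' @param config A \code{\link{display_config}}.
#' @param target_contrast Michelson \% (>= 0), vectorized.
#' @return An \code{effective_contrast_breakdown} list: \code{raw_contrast},
#'   \code{prediction_effective}, \code{delta_phi}, \code{phasor_sum},
#'   \code{suppression_divisor} and \code{effective_contrast} (all vectors
#'   the length of \code{target_contrast} except the scalars).
#' @export
effective_contrast <- function(params, config, target_contrast) {
  stopifnot(inherits(params, "observer_params"),
            inherits(config, "display_config"))
  if (any(target_contrast < 0)) stop("target_contrast must be >= 0")
  a <- prediction_strength(params, config)
  f <- config$inducer$spatial_frequency
  dphi <- config$relative_phase +
    2 * pi * f * sin(config$relative_orientation_theta * pi / 180) *
    config$target_offset
  s <- suppression_for(params, config)
  phasor <- analytic_interference_amplitude(target_contrast, a, dphi)
  structure(list(raw_contrast = target_contrast,
                 prediction_effective = a,
                 delta_phi = dphi,
                 phasor_sum = phasor,
                 suppression_divisor = 1 + s,
                 effective_contrast = phasor / (1 + s)),
            class = "effective_contrast_breakdown")
}

#' Probability of a correct 2AFC response at a given effective contrast
#'
#' p = guess + (1 - guess - lapse) * logistic(beta * (log10 e - log10
#' theta_0)), anchored so that effective contrast equal to the baseline
#' threshold yields exactly 75\% correct when the lapse rate is 0. Zero
#' effective contrast gives chance (0.5) in the limit.
#'
#' @param params An \code{\link{observer_params}}.
#' @param effective Effective Michelson \% contrast (>= 0), vectorized.
#' @return Probability of a correct response.
#' @export
detection_probability <- function(params, effective) {
  stopifnot(inherits(params, "observer_params"))
  if (any(effective < 0)) stop("effective contrast must be >= 0")
  z <- ifelse(effective > 0,
              params$psychometric_slope *
                (log10(effective) - log10(params$baseline_threshold)),
              -Inf)
  params$guess_rate +
    (1 - params$guess_rate - params$lapse_rate) * stats::plogis(z)
}

#' Analytic expected threshold for a display
#'
#' Solves effective_contrast(c) = theta_0 for the target contrast c: the
#' contrast at which the model observer is 75\% correct (lapse = 0). With
#' R = theta_0 (1 + s) and prediction amplitude a, the solution is
#' c = -a cos(dphi) + sqrt(R^2 - a^2 sin^2(dphi)).
#'
#' @param params An \code{\link{observer_params}}.
#' @param config A \code{\link{display_config}}.
#' @return Michelson \% threshold.
#' @export
expected_threshold <- function(params, config) {
  a <- prediction_strength(params, config)
  s <- suppression_for(params, config)
  f <- config$inducer$spatial_frequency
  dphi <- config$relative_phase +
    2 * pi * f * sin(config$relative_orientation_theta * pi / 180) *
    config$target_offset
  R <- params$baseline_threshold * (1 + s)
  disc <- R^2 - (a * sin(dphi))^2
  if (disc < 0)
    stop("prediction amplitude exceeds the suppressed baseline; no threshold")
  -a * cos(dphi) + sqrt(disc)
}

#' Simulate 2AFC trials for one display at given target contrasts
#'
#' Draws Bernoulli outcomes with success probability
#' \code{detection_probability(effective_contrast(...))}. Reproducible: the
#' caller controls the RNG (use \code{withr::with_seed} or
#' \code{set.seed}).
#'
#' @param params An \code{\link{observer_params}}.
#' @param config A \code{\link{display_config}}.
#' @param target_contrast Vector of Michelson \% contrasts, one per trial.
#' @return Integer vector of 0/1 correctness outcomes.
#' @export
simulate_trials <- function(params, config, target_contrast) {
  p <- detection_probability(
    params, effective_contrast(params, config, target_contrast)$effective_contrast)
  stats::rbinom(length(target_contrast), 1, p)
}

#' Simulate a single trial
#'
#' Convenience wrapper around \code{\link{simulate_trials}} returning the
#' response structure for one presentation: whether the report was correct
#' and which side was reported.
#'
#' @inheritParams simulate_trials
#' @param target_contrast Michelson \% contrast of this presentation.
#' @return List with \code{correct} (logical) and \code{side_reported}.
#' @export
simulate_trial <- function(params, config, target_contrast) {
  correct <- simulate_trials(params, config, target_contrast) == 1
  true_side <- config$target_side
  other <- if (true_side == "left") "right" else "left"
  list(correct = correct, side_reported = if (correct) true_side else other)
}
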