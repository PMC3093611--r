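#' Log-spaced contrast levels for the method of constant stimuli
#'
#' @param center Michelson \% contrast at the center of the range (> 0).
#' @param span_log10 Total range in decades (> 0).
#' @param n Number of levels (>= 2).
#' @return Strictly increasing vector of \code{n} contrasts equally spaced in
#'   log10, centered on \code{center}.
#' @examples
#' make_levels(1, 0.6, 7)   # ratio 10^0.1 between adjacent levels
#' @export
make_levels <- function(center, span_log10 = 0.4, n = 7) {
  if (center <= 0) stop("center must be > 0")
  if (span_log10 <= 0) stop("span_log10 must be > 0")
  if (n < 2) stop("need at least 2 levels")
  10^seq(log10(center) - span_log10 / 2, log10(center) + span_log10 / 2,
         length.out = n)
}

#' Method-of-constant-stimuli design
#'
#' Fixed, randomized presentation of predetermined contrast levels: the
#' default is 7 log-spaced levels with 120 trials each, so one threshold
#' estimate consumes 840 trials. Levels may be left NULL to be auto-centered
#' per condition on the model observer's analytically expected threshold
#' (the study does not print the level values used for humans), with a
#' 0.4-decade span placing the extreme levels near 56\% and 94\% correct for
#' the default psychometric slope.
#'
#' @param n_levels Number of contrast levels.
#' @param trials_per_level Trials per level per condition.
#' @param span_log10 Level range in decades.
#' @param levels Optional explicit contrast levels (Michelson \%), strictly
#'   increasing; overrides auto-centering.
#' @param seed Integer seed driving trial randomization.
#' @return A \code{mocs_design} object.
#' @export
mocs_design <- function(n_levels = 7, trials_per_level = 120,
                        span_log10 = 0.4, levels = NULL, seed = 1L) {
  if (!is.null(levels)) {
    if (any(diff(levels) <= 0) || any(levels <= 0))
      stop("levels must be strictly increasing and > 0")
    n_levels <- length(levels)
  }
  if (n_levels < 2) stop("need at least 2 levels")
  if (trials_per_level < 1) stop("trials_per_level must be >= 1")
  structure(list(n_levels = n_levels, trials_per_level = trials_per_level,
                 span_log10 = span_log10, levels = levels,
                 seed = as.integer(seed)),
            class = "mocs_design")
}

#' @export
print.mocs_design <- function(x, ...) {
  cat(sprintf("MOCS design: %d levels x %d trials (%d per threshold), span %.3g decades, seed %d\n",
              x$n_levels, x$trials_per_level, x$n_levels * x$trials_per_level,
              x$span_log10, x$seed))
  invisible(x)
}

# decorrelated sub-seed derivation: adjacent parent seeds must not share
# block streams, so mix with a Lehmer multiplier modulo the Mersenne prime
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 104729) %% 2147483647)
}

# contrast levels for one condition under a design (auto-centered if needed)
levels_for_condition <- function(observer, config, design) {
  if (!is.null(design$levels)) return(design$levels)
  make_levels(expected_threshold(observer, config), design$span_log10,
              design$n_levels)
}

#' Run interleaved conditions under a MOCS design
#'
#' Simulates one block of randomly interleaved conditions: every (condition,
#' level) cell receives exactly \code{trials_per_level} presentations, and
#' all conditions share a single jointly shuffled trial schedule driven by
#' the design seed (as when leading- and trailing-edge, or in-phase and
#' antiphase, trials are mixed within a block). Contrast ranges whose levels
#' all fall below the fold point of the destructive-interference branch
#' (where detection probability stops being monotone in contrast) are
#' rejected with advice to re-center.
#'
#' @param observer An \code{\link{observer_params}}.
#' @param configs A named list of \code{\link{display_config}}s (the
#'   interleaved conditions), or a single config.
#' @param design A \code{\link{mocs_design}}.
#' @param experiment_id Label recorded in the trial table.
#' @return A \code{trial_table} data.frame with columns
#'   \code{experiment_id}, \code{condition}, \code{replicate} (index within
#'   its (condition, level) cell), \code{contrast} (Michelson \%),
#'   \code{correct} (0/1), \code{seed_path}, plus \code{trial} (position in
#'   the shuffled block).
#' @export
run_condition <- function(observer, configs, design = mocs_design(),
                          experiment_id = "condition") {
  stopifnot(inherits(observer, "observer_params"))
  if (inherits(configs, "display_config")) configs <- list(condition = configs)
  if (is.null(names(configs)) || any(names(configs) == ""))
    stop("configs must be a named list of display_config objects")
  level_sets <- lapply(names(configs), function(nm) {
    cfg <- configs[[nm]]
    lev <- levels_for_condition(observer, cfg, design)
    ec <- effective_contrast(observer, cfg, lev[1])
    fold <- -ec$prediction_effective * cos(ec$delta_phi)
    if (fold > 0 && max(lev) < fold)
      stop(sprintf(paste0("condition '%s': all contrast levels sit below the ",
                          "non-monotone destructive-interference region ",
                          "(fold at %.3g%%); raise or re-center the range"),
                   nm, fold))
    lev
  })
  names(level_sets) <- names(configs)
  schedule <- do.call(rbind, lapply(names(configs), function(nm) {
    expand.grid(condition = nm, level_index = seq_len(design$n_levels),
                replicate = seq_len(design$trials_per_level),
                stringsAsFactors = FALSE)
  }))
  withr::with_seed(design$seed, {
    ord <- sample.int(nrow(schedule))
    schedule <- schedule[ord, , drop = FALSE]
    schedule$trial <- seq_len(nrow(schedule))
    schedule$contrast <- mapply(function(nm, i) level_sets[[nm]][i],
                                schedule$condition, schedule$level_index)
    correct <- integer(nrow(schedule))
    for (nm in names(configs)) {
      idx <- which(schedule$condition == nm)
      correct[idx] <- simulate_trials(observer, configs[[nm]],
                                      schedule$contrast[idx])
    }
  })
  out <- data.frame(experiment_id = experiment_id,
                    condition = schedule$condition,
                    replicate = schedule$replicate,
                    contrast = schedule$contrast,
                    correct = correct,
                    seed_path = sprintf("%d/%d", observer$rng_seed,
                                        design$seed),
                    trial = schedule$trial,
                    stringsAsFactors = FALSE)
  class(out) <- c("trial_table", "data.frame")
  out
}

# fit all conditions of a trial table, returning a thresholds data.frame and
# the list of fits
fit_conditions <- function(table, lapse_rate = 0) {
  conds <- unique(table$condition)
  fits <- lapply(conds, function(nm) fit_logistic(table, nm,
                                                  lapse_rate = lapse_rate))
  names(fits) <- conds
  thresholds <- data.frame(condition = conds,
                           threshold = vapply(fits, function(f) f$threshold,
                                              numeric(1)),
                           slope = vapply(fits, function(f) f$slope,
                                          numeric(1)),
                           n_trials = vapply(fits, function(f) f$n_trials,
                                             numeric(1)),
                           converged = vapply(fits, function(f) f$converged,
                                              logical(1)),
                           stringsAsFactors = FALSE)
  list(thresholds = thresholds, fits = fits)
}

# display_config helpers for the canonical study geometries ------------------

collinear_config <- function(edge, phase = 0, duration = 1, gap = 0,
                        inducer_length = 6.67,
                        eye_target = "left", eye_inducer = eye_target) {
  display_config(target = grating_params(spatial_frequency = 1,
                                         temporal_frequency = 5,
                                         orientation = 90, contrast = 0.05,
                                         width = 1, height = 1),
                 inducer = grating_params(spatial_frequency = 1,
                                          temporal_frequency = 5,
                                          orientation = 90, contrast = 1,
                                          width = 1, height = 6.67),
                 edge = edge, relative_phase = phase, gap = gap,
                 inducer_length = inducer_length, duration = duration,
                 eye_target = eye_target, eye_inducer = eye_inducer)
}

#' Simulate the phase-dependence experiment
#'
#' Baseline (no inducer) plus leading- and trailing-edge targets at relative
#' phases 0, pi/2, pi and 3pi/2 — nine thresholds of 840 trials each by
#' default. Leading and trailing conditions at a common phase are interleaved
#' within a block, as in the study; baseline runs as its own block. The
#' summary reports each condition's threshold and its elevation over baseline
#' in log10 units and percent.
#'
#' @param observer An \code{\link{observer_params}}.
#' @param design A \code{\link{mocs_design}}.
#' @param phases Relative phases in radians.
#' @param duration Presentation duration in seconds.
#' @return List with \code{trials} (a \code{trial_table}), \code{thresholds},
#'   \code{fits}, \code{summary} (suppression per condition) and
#'   \code{baseline_threshold}.
#' @export
experiment_phase_dependence <- function(observer, design = mocs_design(),
                                        phases = c(0, pi / 2, pi, 3 * pi / 2),
                                        duration = 1) {
  blocks <- list(run_condition(observer,
                               list(baseline = collinear_config("baseline",
                                                           duration = duration)),
                               design, experiment_id = "phase_dependence"))
  for (i in seq_along(phases)) {
    ph <- phases[i]
    cfgs <- list(collinear_config("leading", ph, duration),
                 collinear_config("trailing", ph, duration))
    names(cfgs) <- sprintf(c("leading_phase_%.3g", "trailing_phase_%.3g"), ph)
    blk_design <- mocs_design(design$n_levels, design$trials_per_level,
                              design$span_log10, design$levels,
                              seed = derive_seed(design$seed, i))
    blocks[[i + 1]] <- run_condition(observer, cfgs, blk_design,
                                     experiment_id = "phase_dependence")
  }
  trials <- do.call(rbind, blocks)
  class(trials) <- c("trial_table", "data.frame")
  fc <- fit_conditions(trials, lapse_rate = observer$lapse_rate)
  base_thr <- fc$thresholds$threshold[fc$thresholds$condition == "baseline"]
  supp <- lapply(seq_len(nrow(fc$thresholds)), function(i) {
    th <- fc$thresholds$threshold[i]
    if (is.na(th) || is.na(base_thr))
      list(log_units = NA_real_, percent = NA_real_)
    else suppression_stats(th, base_thr)
  })
  summary <- cbind(fc$thresholds,
                   log_units = vapply(supp, `[[`, numeric(1), "log_units"),
                   percent = vapply(supp, `[[`, numeric(1), "percent"))
  structure(list(trials = trials, thresholds = fc$thresholds,
                 fits = fc$fits, summary = summary,
                 baseline_threshold = base_thr, phases = phases),
            class = "phase_dependence_experiment")
}

#' Simulate the spatial interference-profile experiment
#'
#' Targets at a grid of offsets along the edge of an inducer rotated by
#' \code{theta}, at two starting phases half a cycle apart (interleaved
#' within each offset block). Thresholds per (offset, phase) are returned
#' together with the theoretical profile from the forward model for
#' comparison.
#'
#' @param observer An \code{\link{observer_params}}.
#' @param design A \code{\link{mocs_design}}.
#' @param theta Inducer rotation in degrees (30 or 15 in the study).
#' @param offsets Signed offsets in degrees along the edge.
#' @param target_phases Two phases half a cycle apart.
#' @param f Spatial frequency in c/deg of target and inducer (0.5 in the
#'   study).
#' @param duration Seconds.
#' @return List with \code{trials}, \code{thresholds} (per offset x phase),
#'   \code{empirical} (wide data.frame of thresholds vs offset),
#'   \code{theoretical} (an \code{\link{interference_profile}} per phase) and
#'   the design metadata.
#' @export
experiment_interference_profile <- function(observer,
                                            design = mocs_design(),
                                            theta = 30,
                                            offsets = seq(-5, 5, by = 0.5),
                                            target_phases = c(0, pi),
                                            f = 0.5, duration = 1) {
  mk <- function(offset, phase)
    display_config(target = grating_params(spatial_frequency = f,
                                           temporal_frequency = 5,
                                           orientation = 0, contrast = 0.05,
                                           width = 2, height = 2),
                   inducer = grating_params(spatial_frequency = f,
                                            temporal_frequency = 5,
                                            orientation = theta, contrast = 1,
                                            width = 10, height = 10),
                   edge = "leading", relative_phase = phase,
                   relative_orientation_theta = theta,
                   inducer_length = 10, duration = duration,
                   target_offset = offset)
  blocks <- vector("list", length(offsets))
  for (i in seq_along(offsets)) {
    cfgs <- list(mk(offsets[i], target_phases[1]),
                 mk(offsets[i], target_phases[2]))
    names(cfgs) <- sprintf("offset_%+.2f_phase_%.3g", offsets[i],
                           target_phases)
    blk_design <- mocs_design(design$n_levels, design$trials_per_level,
                              design$span_log10, design$levels,
                              seed = derive_seed(design$seed, i))
    blocks[[i]] <- run_condition(observer, cfgs, blk_design,
                                 experiment_id = sprintf("profile_theta%g",
                                                         theta))
  }
  trials <- do.call(rbind, blocks)
  class(trials) <- c("trial_table", "data.frame")
  fc <- fit_conditions(trials, lapse_rate = observer$lapse_rate)
  grid <- expand.grid(offset = offsets, phase = target_phases)
  grid$condition <- sprintf("offset_%+.2f_phase_%.3g", grid$offset,
                            grid$phase)
  grid$threshold <- fc$thresholds$threshold[match(grid$condition,
                                                  fc$thresholds$condition)]
  gain <- prediction_strength(observer, mk(0, 0))
  theoretical <- lapply(target_phases, function(ph)
    interference_profile(theta, f, ph, gain, offsets,
                         c_t = observer$baseline_threshold))
  names(theoretical) <- sprintf("phase_%.3g", target_phases)
  structure(list(trials = trials, thresholds = fc$thresholds,
                 fits = fc$fits, empirical = grid,
                 theoretical = theoretical, theta = theta, f = f,
                 offsets = offsets, target_phases = target_phases),
            class = "interference_profile_experiment")
}

# shared machinery for the Fig-3-style sweeps: in-phase and antiphase targets
# at the leading edge, one swept variable, threshold difference curve
run_sweep <- function(observer, design, values, make_config, sweep_name,
                      units) {
  blocks <- vector("list", length(values))
  for (i in seq_along(values)) {
    cfgs <- list(inphase = make_config(values[i], 0),
                 antiphase = make_config(values[i], pi))
    names(cfgs) <- sprintf(c("inphase_%s_%g", "antiphase_%s_%g"),
                           sweep_name, values[i])
    blk_design <- mocs_design(design$n_levels, design$trials_per_level,
                              design$span_log10, design$levels,
                              seed = derive_seed(design$seed, i))
    blocks[[i]] <- run_condition(observer, cfgs, blk_design,
                                 experiment_id = sweep_name)
  }
  trials <- do.call(rbind, blocks)
  class(trials) <- c("trial_table", "data.frame")
  fc <- fit_conditions(trials, lapse_rate = observer$lapse_rate)
  thr <- function(nm) fc$thresholds$threshold[match(nm,
                                                    fc$thresholds$condition)]
  curve <- data.frame(value = values,
                      inphase = thr(sprintf("inphase_%s_%g", sweep_name,
                                            values)),
                      antiphase = thr(sprintf("antiphase_%s_%g", sweep_name,
                                              values)))
  curve$difference <- curve$antiphase - curve$inphase
  names(curve)[1] <- units
  list(trials = trials, thresholds = fc$thresholds, fits = fc$fits,
       curve = curve)
}

#' Simulate the spatial-support experiment (inducer length sweep)
#'
#' Varies inducer length from 4 arcmin to 3.33 degrees with interleaved
#' in-phase and antiphase targets at the leading edge, and fits a saturating
#' exponential to the antiphase-minus-in-phase threshold difference; its
#' half-point estimates the spatial support of the prediction.
#'
#' @param observer An \code{\link{observer_params}}.
#' @param design A \code{\link{mocs_design}}.
#' @param lengths_arcmin Inducer lengths in arcmin.
#' @param duration Seconds.
#' @return List with \code{trials}, \code{thresholds}, \code{curve}
#'   (threshold vs length) and \code{fit} (an \code{exponential_fit}).
#' @export
experiment_support <- function(observer, design = mocs_design(),
                               lengths_arcmin = c(4, 8, 12, 18, 25, 40, 60,
                                                  120, 200),
                               duration = 1) {
  res <- run_sweep(observer, design, lengths_arcmin,
                   function(L, ph) collinear_config("leading", ph, duration,
                                               inducer_length = L / 60),
                   "support", "length_arcmin")
  res$fit <- fit_saturating_exponential(res$curve$length_arcmin,
                                        res$curve$difference,
                                        units = "arcmin")
  structure(res, class = "sweep_experiment")
}

#' Simulate the spatial-projection experiment (gap sweep)
#'
#' Introduces a gap between inducer and target (inducer phase continued
#' across the gap, so in-phase targets stay consistent with extrapolation)
#' and fits a decaying exponential to the threshold-difference curve; its
#' e-folding constant estimates how far the prediction projects ahead of the
#' inducer.
#'
#' @inheritParams experiment_support
#' @param gaps_arcmin Gaps in arcmin.
#' @return As \code{\link{experiment_support}}.
#' @export
experiment_projection <- function(observer, design = mocs_design(),
                                  gaps_arcmin = c(4, 8, 12, 16, 22, 30, 40,
                                                  55, 75, 100, 140, 200),
                                  duration = 1) {
  res <- run_sweep(observer, design, gaps_arcmin,
                   function(g, ph) collinear_config("leading", ph, duration,
                                               gap = g / 60),
                   "projection", "gap_arcmin")
  res$fit <- fit_decaying_exponential(res$curve$gap_arcmin,
                                      res$curve$difference,
                                      units = "arcmin")
  structure(res, class = "sweep_experiment")
}

#' Simulate the time-course experiment (duration sweep)
#'
#' Varies the duration of all stimuli between 20 and 2000 ms and fits a
#' saturating exponential to the threshold-difference curve; its half-point
#' estimates the buildup time of the prediction.
#'
#' @inheritParams experiment_support
#' @param durations_ms Stimulus durations in milliseconds.
#' @return As \code{\link{experiment_support}}.
#' @export
experiment_timecourse <- function(observer, design = mocs_design(),
                                  durations_ms = c(20, 40, 70, 110, 160,
                                                   230, 320, 450, 700, 1000,
                                                   1500, 2000)) {
  res <- run_sweep(observer, design, durations_ms,
                   function(T_ms, ph) collinear_config("leading", ph,
                                                  duration = T_ms / 1000),
                   "timecourse", "duration_ms")
  res$fit <- fit_saturating_exponential(res$curve$duration_ms,
                                        res$curve$difference, units = "ms")
  structure(res, class = "sweep_experiment")
}

#' Simulate the interocular-transfer experiment
#'
#' Compares in-phase and antiphase leading-edge thresholds when target and
#' inducer go to the same eye (monocular) versus different eyes (dichoptic).
#' The ratio of dichoptic to monocular threshold difference estimates the
#' interocular transfer of the prediction.
#'
#' @inheritParams experiment_support
#' @return List with \code{trials}, \code{thresholds}, \code{curve} (one row
#'   per viewing condition) and \code{transfer_ratio}.
#' @export
experiment_interocular <- function(observer, design = mocs_design(),
                                   duration = 1) {
  mk <- function(viewing, ph)
    collinear_config("leading", ph, duration,
                eye_target = "left",
                eye_inducer = if (viewing == "monocular") "left" else "right")
  blocks <- list()
  for (i in seq_along(c("monocular", "dichoptic"))) {
    viewing <- c("monocular", "dichoptic")[i]
    cfgs <- list(mk(viewing, 0), mk(viewing, pi))
    names(cfgs) <- sprintf(c("inphase_%s", "antiphase_%s"), viewing)
    blk_design <- mocs_design(design$n_levels, design$trials_per_level,
                              design$span_log10, design$levels,
                              seed = derive_seed(design$seed, i))
    blocks[[i]] <- run_condition(observer, cfgs, blk_design,
                                 experiment_id = "interocular")
  }
  trials <- do.call(rbind, blocks)
  class(trials) <- c("trial_table", "data.frame")
  fc <- fit_conditions(trials, lapse_rate = observer$lapse_rate)
  thr <- function(nm) fc$thresholds$threshold[match(nm,
                                                    fc$thresholds$condition)]
  curve <- data.frame(viewing = c("monocular", "dichoptic"),
                      inphase = thr(c("inphase_monocular",
                                      "inphase_dichoptic")),
                      antiphase = thr(c("antiphase_monocular",
                                        "antiphase_dichoptic")))
  curve$difference <- curve$antiphase - curve$inphase
  structure(list(trials = trials, thresholds = fc$thresholds,
                 fits = fc$fits, curve = curve,
                 transfer_ratio = curve$difference[2] / curve$difference[1]),
            class = "sweep_experiment")
}
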