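# shared fixtures: the study-calibrated observer and canonical displays
calibrated <- calibrate_defaults()

lead_cfg <- function(phase = 0, duration = 1, gap = 0, length_deg = 6.67,
                     eye_inducer = "left")
  display_config(edge = "leading", relative_phase = phase,
                 duration = duration, gap = gap,
                 inducer_length = length_deg,
                 eye_target = "left", eye_inducer = eye_inducer)

trail_cfg <- function(phase = 0)
  display_config(edge = "trailing", relative_phase = phase)

base_cfg <- function() display_config(edge = "baseline")

# simulate one MOCS session for a single display and fit it
fit_session <- function(observer, config, seed, trials_per_level = 120) {
  tab <- run_condition(observer, list(cond = config),
                       mocs_design(trials_per_level = trials_per_level,
                                   seed = seed))
  fit_logistic(tab, "cond")
}
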