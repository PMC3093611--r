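# motionforecast

Simulation and analysis toolkit for psychophysical studies of
**motion-induced forward prediction**: the finding that a drifting pattern
makes the visual system anticipate the spatial pattern ahead of its leading
edge, so that detection of a small sinusoidal target there is phase-specific
— easy when the target continues the moving waveform, hard when it is in
antiphase — while suppression at the trailing edge is phase-blind.

The package is for vision scientists and modelers who want to regenerate
every figure-level analysis of such an experiment from simulation alone: no
deposited data are needed, all inputs are parametric.

## The model

Detection is governed by an effective contrast

```
E(c) = sqrt(c^2 + a^2 + 2 c a cos(Δφ)) / (1 + s)
```

where `c` is target contrast, `a` the amplitude of an internally generated
predicted waveform (the extrapolated continuation of the inducer), `Δφ` their
relative phase, and `s` a phase-blind divisive surround-suppression strength
(`s_l` at the leading edge, `s_t` at the trailing edge, 0 in baseline). The
prediction exists only at the leading edge and is attenuated by inducer
length, gap, duration and eye:

```
a = a_p · (1 − 2^(−L/L50)) · exp(−g/λ) · (1 − 2^(−T/T50)) · ι^[dichoptic]
```

with defaults `L50 = 15` arcmin, `λ = 25` arcmin, `T50 = 122` ms. The
probability of a correct 2AFC response is a logistic in log10 effective
contrast anchored at 75% correct when `E = θ0` (the baseline threshold).
When the inducer is rotated by θ relative to the target, `Δφ` varies with
position `d` along the edge as `2π f sin(θ) d + φ0`, giving a periodic
interference profile with period `1/(f sin θ)`.

The packaged default observer is calibrated in closed form from the three
mean threshold elevations of the phase-dependence experiment (49% trailing,
2% leading in-phase, 106% leading antiphase), yielding `s_t = 0.49`,
`s_l = 0.54`, `a_p = 0.52 θ0`.

## Worked example

Simulate the phase-dependence experiment (baseline + two edges × four
phases, 840 trials per threshold) with the packaged calibrated observer and
summarize threshold elevations:

```r
library(motionforecast)
obs <- default_observer()
exp <- experiment_phase_dependence(obs, mocs_design(seed = 1))
exp$summary[, c("condition", "threshold", "log_units", "percent")]
```

```
                              condition threshold log_units percent
baseline                       baseline     0.989    0.0000     0.0
trailing_phase_0       trailing_phase_0     1.482    0.1754    49.7
leading_phase_0         leading_phase_0     1.086    0.0406     9.8
leading_phase_1.57   leading_phase_1.57     1.371    0.1417    38.6
trailing_phase_1.57 trailing_phase_1.57     1.404    0.1519    41.9
trailing_phase_3.14 trailing_phase_3.14     1.572    0.2011    58.9
leading_phase_3.14   leading_phase_3.14     2.109    0.3287   113.1
trailing_phase_4.71 trailing_phase_4.71     1.405    0.1523    42.0
leading_phase_4.71   leading_phase_4.71     1.412    0.1543    42.7
```

Thresholds are in Michelson percent; `log_units` is log10(threshold /
baseline). In this single simulated session the trailing-edge elevations sit
near 0.15–0.20 log units at every phase (phase-blind suppression), the
leading in-phase target is close to baseline, and the leading antiphase
target is maximally suppressed — the model's signature. Quarter-cycle phases
fall in between, and averaging sessions drives the three summary means
toward 0.17, 0.01 and 0.31 log units.

A sweep experiment returns its exponential summary directly:

```r
su <- experiment_support(obs, mocs_design(seed = 2))
su$fit
```

```
Saturating exponential: asymptote 1.091, semisaturation constant 19.47 arcmin
  residual SS 0.04472
```

i.e. this session's in-phase/antiphase threshold difference grows with
inducer length and half-saturates near the generating 15 arcmin (single
sessions scatter around it; replicate averages converge).

Everything regenerates end-to-end from one seed:

```r
run_all(seed = 7, out_dir = "out")   # trial tables, fits, summaries, plots
```

A thin CLI wrapper for shell use ships at `inst/cli/motion-forecast.R`.

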