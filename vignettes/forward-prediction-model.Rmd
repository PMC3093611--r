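---
title: "Simulating motion-induced forward prediction of spatial pattern"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating motion-induced forward prediction of spatial pattern}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motionforecast)
```

## The phenomenon and the model

When a high-contrast grating drifts across the visual field, the detectability
of a small test grating placed just beyond its *leading* edge — the border the
pattern drifts toward — depends on the test's phase relative to the
continuation of the moving waveform. Targets whose waveform continues the
inducer in space and time are detected about as easily as with no inducer at
all, while targets in antiphase suffer a large threshold elevation. At the
*trailing* edge the threshold elevation is phase-blind. This package simulates
and analyzes that phenomenon with a stimulus-level model:

1. **Divisive surround suppression.** An inducer abutting the target divides
   the target's effective contrast by $(1 + s)$, with separate strengths at
   the trailing ($s_t$) and leading ($s_l$) edges. Suppression is independent
   of relative phase.
2. **Additive predictive superposition.** At the leading edge only, an
   internally generated waveform — the extrapolated continuation of the
   inducer, with its spatial frequency, orientation and phase trajectory — is
   added to the sensory input. Two equal-frequency sinusoids of amplitudes
   $c_t$ (the target) and $a$ (the prediction) at relative phase
   $\Delta\varphi$ sum to amplitude
   $$\sqrt{c_t^2 + a^2 + 2\,c_t\,a \cos\Delta\varphi},$$
   so in-phase targets gain effective contrast (constructive interference)
   and antiphase targets lose it (destructive interference).

The observer's effective contrast is the phasor sum divided by $(1+s)$, and
the probability of a correct two-alternative forced-choice (2AFC) response is
a logistic function of $\log_{10}$ effective contrast anchored so that
effective contrast equal to the baseline threshold $\theta_0$ yields exactly
75% correct.

When the inducer's orientation is rotated by $\theta$ relative to the target,
the relative phase varies with the target's position $d$ along the inducer
edge as $\Delta\varphi(d) = 2\pi f \sin(\theta)\, d + \varphi_0$, producing a
periodic *interference profile* of local contrast along the edge with spatial
period $1/(f\sin\theta)$ — 4° for $f = 0.5$ c/° at $\theta = 30°$, about
7.73° at $\theta = 15°$. Shifting the target's starting phase by half a
cycle shifts the profile by half a period.

## Attenuation of the prediction

The prediction's amplitude is $a_p$ scaled by four factors, isolated behind
`prediction_strength()`:

| factor | form | default | meaning |
|---|---|---|---|
| inducer length $L$ | $1 - 2^{-L/L_{50}}$ | $L_{50} = 15$ arcmin | spatial support: the region of motion pooled into the prediction |
| gap $g$ | $e^{-g/\lambda}$ | $\lambda = 25$ arcmin | spatial projection: how far the prediction extends ahead |
| duration $T$ | $1 - 2^{-T/T_{50}}$ | $T_{50} = 122$ ms | temporal buildup of the prediction |
| eye | $\iota$ if dichoptic | $\iota = 0.5$ | partial interocular transfer |

Two naming conventions coexist in this literature and we map them to standard
definitions: a *semisaturation constant* is the half-point of the half-life
saturating form $1 - 2^{-x/x_{50}}$ (so the constant named is exactly where
the curve reaches half its asymptote), while a *space constant* is the
e-folding distance of $A e^{-x/\lambda}$. The saturating form uses base 2
precisely so the semisaturation parameter is the half-point; an equivalent
$1 - e^{-x/\tau}$ parameterization would report $\tau = x_{50}/\ln 2$
instead.

The interocular transfer fraction is not pinned down quantitatively by the
dichoptic data, which show the interference effect surviving but attenuated
across eyes; $\iota = 0.5$ ("partial transfer") is the package default, and
whether $\iota$ also scales suppression dichoptically is left as an observer
flag (`transfer_suppression`, default `FALSE`) because the data do not decide
it. Only the prediction transfer enters any quantitative claim here.

## Calibration

`calibrate_defaults()` inverts the phasor model in closed form from three
threshold ratios (condition/baseline): trailing $r_t = 1.49$, leading
in-phase $r_{in} = 1.02$ and leading antiphase $r_{anti} = 2.06$ — i.e. the
49%, 2% and 106% mean threshold elevations of the phase-dependence
experiment:

$$s_t = r_t - 1, \qquad 1 + s_l = \tfrac{r_{in} + r_{anti}}{2}, \qquad
a_p = \theta_0\,\tfrac{r_{anti} - r_{in}}{2},$$

because at asymptotic prediction strength the in-phase and antiphase
thresholds solve $(c \mp a_p)/(1+s_l) = \theta_0$. This gives $s_t = 0.49$,
$s_l = 0.54$, $a_p = 0.52\,\theta_0$. Because the calibration *is* the
inversion of those printed means, simulated phase-dependence experiments
reproduce them by construction up to sampling error: they validate the
round trip through stimulus scheduling, simulation and fitting, not an
independent prediction. The sweep experiments are equally round trips for
the three attenuation constants.

```{r calibration}
obs <- calibrate_defaults()
obs
expected_threshold(obs, display_config(edge = "leading", relative_phase = pi))
```

## The synthetic observer and what it does not emulate

`simulate_trials()` draws Bernoulli outcomes at the model's detection
probability. The generator emulates: the 2AFC design, phase/orientation/
length/gap/duration/eye condition dependence, and binomial trial noise. It
deliberately does **not** emulate between-observer variability (it is a
single "mean observer"; jitter the parameters if you need a cohort), lapses
(default rate 0, since the original fits used none), serial dependence,
learning, eye movements, or spatial attention. Passing tests therefore show
that the analysis machinery recovers the model's own constants under
realistic trial noise — not that the model captures every property of human
observers.

Defaults the underlying study leaves open, fixed here once:

* **Baseline threshold** $\theta_0 = 1$% Michelson — a realistic detection
  threshold for a 1 c/° target at 2° eccentricity and 1 s duration.
* **Psychometric slope** $\beta = 10$ on $\log_{10}$ contrast, matching the
  typical Weibull slope of ≈3.5 for contrast detection; the psychometric
  function rises from ~56% to ~94% correct over 0.4 decades.
* **MOCS placement**: seven levels spanning 0.4 decades, centered per
  condition on the analytically expected threshold (the published work does
  not print the level values used for humans). This places the extreme
  levels near 56% and 94% correct — the textbook-efficient placement for a
  method-of-constant-stimuli threshold estimate.
* **Sweep grids**: inducer lengths 4–200 arcmin (9 points), gaps 4–200
  arcmin (12 points, denser at small gaps where the decay carries its
  information), durations 20–2000 ms (12 points, denser over the rise).
  Published values state only the ranges; the grids are chosen to sample
  each curve's informative region.

## Experiments and estimation

Each driver (`experiment_phase_dependence()`, `experiment_interference_profile()`,
`experiment_support()`, `experiment_projection()`, `experiment_timecourse()`,
`experiment_interocular()`) schedules method-of-constant-stimuli sessions —
840 trials per threshold (7 levels × 120) by default — with the same
interleaving structure as the original experiments: leading/trailing at a
fixed phase within a block, in-phase with antiphase within sweep blocks, the
two target phases within profile blocks. All randomization flows from named
integer seeds; sub-seeds for blocks are derived with a Lehmer-style mix so
that adjacent parent seeds give statistically independent sessions.

`fit_logistic()` maximizes the binomial likelihood of
$p(c) = 0.5 + 0.5\,\sigma\!\left(\beta(\log_{10} c - \log_{10}\alpha)\right)$,
reporting $\alpha$ (the 75% point) directly. Numerical choices: the search is
a bounded quasi-Newton (L-BFGS-B) multi-started from a 3 × 3 grid of slope
and threshold starts, ties broken by lowest deviance then lowest threshold;
probabilities are clamped at $10^{-9}$; slope bounds are $[0.5, 200]$ on the
natural-log scale of $\beta$. Degenerate data are flagged rather than
silently fitted: all-at-chance data return no finite threshold, and
step-like data (the fitted 55–95% rise narrower than the level spacing) are
flagged as perfectly separated with the threshold bracketed between adjacent
levels. `bootstrap_se()` resamples within contrast level, preserving the
MOCS structure. Exponential summaries of sweep curves are least-squares fits
(Levenberg–Marquardt) of the two forms above, fitted to the
antiphase-minus-in-phase threshold *difference* — the one case the source
states explicitly fits the difference is generalized to all three sweeps.

The destructive-interference branch makes effective contrast non-monotone in
target contrast below the fold point $c = a\,|\cos\Delta\varphi|$;
`run_condition()` rejects contrast ranges that sit entirely below the fold,
and auto-centered ranges always clear it.

## Pixel-level versus analytic interference profiles

`interference_profile()` computes the profile two ways: the analytic phasor
formula, and a brute-force pixel route (`method = "pixel"`) that samples the
superposed luminance and takes Michelson contrast over a window. The pixel
window is a thin rectangle aligned with the *carrier* of the two-grating sum
(direction $\theta/2$), spanning exactly one carrier wavelength
$1/(f\cos(\theta/2))$: along that direction the interference envelope is
constant while the carrier completes a full cycle, so the window's
(max − min)/(max + min) equals the local envelope amplitude. An axis-aligned
window would mix envelope phases and smear the profile. The two routes agree
within 1% over a grid of $(\theta, f, \varphi)$; this equivalence is
enforced by tests.

```{r profile}
prof <- interference_profile(30, 0.5, 0, prediction_gain = 0.5,
                             offsets = seq(-6, 6, 0.25))
prof
```

## Problem sizes and reproducibility

The figure-level analyses regenerate from a single seed with
`run_all(seed, out_dir)`; the default uses 40 trials per level for a quick
desk run, and `trials_per_level = 120` gives the full study scale. The
acceptance script (`scripts/acceptance.R`) averages replicate full-scale
sessions — eight phase-dependence sessions and six-to-ten sessions per sweep
— mirroring how the published means average over observers; replicate
averaging is what makes the stochastic summary statistics stable at the
scale of their printed precision. A complete acceptance run takes well under
a minute of CPU.

## Known limitations

* The model is stimulus-level: no receptive fields, no neural population,
  no contrast normalization pool. The divisive factor and additive phasor
  are the minimal account of the printed effects.
* Leading and trailing suppression are separate parameters ($s_l = 0.54$ vs
  $s_t = 0.49$ after calibration); the data do not force them equal and the
  package does not assume it.
* Thresholds recovered from the antiphase branch assume target contrast
  above the fold point; adaptive procedures that wander below it are out of
  scope.
* The temporal buildup uses the smooth saturating form at all durations; no
  dead-time below one frame is modeled (interference at 50 ms is within the
  form's reach, and published data do not constrain a latency floor).
* Eccentricity dependence, tracking-induced retinal motion and
  contrast-defined (second-order) motion are outside the model's scope.
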