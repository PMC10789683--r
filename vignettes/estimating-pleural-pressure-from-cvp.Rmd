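---
title: "Estimating tidal pleural pressure swings from central venous pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tidal pleural pressure swings from central venous pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Limiting transpulmonary pressure — airway pressure minus pleural pressure —
is central to lung-protective ventilation, but pleural pressure (Ppl) is not
directly measurable at the bedside. The clinical surrogate, esophageal
balloon manometry (Pes), is technically demanding and rarely used. Central
venous pressure (CVP), by contrast, is routinely monitored through a
catheter most critically ill patients already have, and its respiratory
swing partially transmits pleural pressure changes. The catch is
*partially*: the raw CVP swing underestimates the pleural swing by an
unknown, patient- and state-dependent attenuation factor.

This package implements, and stress-tests on synthetic data, a calibration
method for that attenuation. During an end-expiratory **occlusion test
(OT)** the airway is closed and the chest gently compressed. With no gas
flow, lung volume cannot change, so the transpulmonary pressure is fixed
and the airway pressure change equals the pleural pressure change:

$$\Delta P_{aw}^{OT} = \Delta P_{pl}^{OT}.$$

Writing the pleural-to-CVP transmission as $T$ (so
$\Delta CVP = T\,\Delta P_{pl}$), the occlusion test measures

$$\kappa = \frac{\Delta P_{aw}^{OT}}{\Delta CVP^{OT}} = \frac{1}{T},$$

and during subsequent ventilation the **corrected CVP-derived pleural
swing** is

$$\widehat{\Delta P_{pl}} = \kappa \times \Delta CVP.$$

If the transmission during ventilation equals the transmission during the
occlusion test, this identity is exact whatever the value of $T$ — that is
the method's correctness core, and the package's central invariant: in the
noise-free limit the estimator reproduces the directly measured pleural
swing to machine precision for any $T \in (0, 1.5]$.

## The synthetic study

No public recordings exist for this experimental design (direct pleural
catheterisation plus controlled blood withdrawal/transfusion is only
possible in an animal model), so the package ships a first-class waveform
simulator. It emulates the calibration experiment: ten subjects, each
measured under six conditions — three intravascular volume states (blood
withdrawal of 20 mL/kg, return, then colloid loading), which shift the CVP
baseline, crossed with two chest-wall states (with and without an
abdominal band, which roughly halves to thirds the chest wall compliance).

### Breath engine

Mechanics follow the single-compartment model under volume-controlled
ventilation, in closed form per phase rather than via an ODE solver —
transparent and exactly testable:

* **Inspiration**: constant flow, $V(t)$ linear from 0 to TV;
  $P_{aw} = PEEP + V/C_{rs} + R\,\dot V$ with
  $1/C_{rs} = 1/C_L + 1/C_{cw}$.
* **Inspiratory hold**: zero flow at $V = TV$, so
  $P_{aw} = PEEP + TV/C_{rs}$ (the plateau) exactly.
* **Expiration**: passive, time constant $\tau = R \cdot C_{rs}$, using a
  normalized exponential that reaches zero volume exactly at the end of
  the expiratory phase. The truncated remainder is below $10^{-4}$ of TV
  at default time constants; folding it into the profile (rather than
  leaving it trapped) makes end-expiratory states exact, so the invariants
  "expiratory hold reads $P_{aw} = PEEP$" and "volume returns to the same
  end-expiratory value" hold identically rather than approximately.
* **Occlusion test**: volume pinned at end-expiration, a smooth cosine
  ramp raises the pleural pressure by the squeeze magnitude (default
  10 cmH2O); $\Delta P_{aw} \equiv \Delta P_{pl}$ by construction. The
  estimator never uses the ramp shape, only the baseline and plateau
  windows, so a step squeeze would give identical results.

The pleural swing is $V/C_{cw}$ above its end-expiratory value. The
esophageal channel sees a fixed per-subject fraction of it (balloon
transmission, prior $0.9 \pm 0.1$ truncated to $[0.7, 1.1]$ — draws below
0.8 model the mis-calibrated balloons that the validity filter is designed
to catch). The CVP channel sees the condition-specific fraction $T$, plus
a cardiac sinusoid and white measurement noise.

### Parameters and units

All internal pressures are cmH2O; venous and abdominal pressures are
specified in mmHg at the prior layer (as they are charted clinically) and
converted with 1 mmHg = 1.36 cmH2O. Priors are truncated normals centred
on the calibration experiment's group statistics:

| parameter | default prior | units |
|---|---|---|
| weight | 43.2 ± 1.8 | kg |
| tidal volume | 8 × weight | mL |
| PEEP | 6 | cmH2O |
| lung compliance $C_L$ | 30 ± 9, [12, 60] | mL/cmH2O |
| chest wall $C_{cw}$ (normal / banded) | 89 ± 26 / 37 ± 17 | mL/cmH2O |
| CVP baseline (6 cells, low→high volume) | 7.5 → 19.7 (± 1–3.3) | mmHg |
| true $\kappa = 1/T$ | 2.2 ± 1.3, truncated ≥ 1.05 | — |
| esophageal transmission | 0.9 ± 0.1, [0.7, 1.1] | — |
| cardiac oscillation | 2 ± 0.5 cmH2O at 88 ± 17 bpm | |
| white noise per pressure channel | 0.3 | cmH2O |

The $\kappa$ prior is truncated below at ~1 because transmission fractions
above 1 are non-physical for a partially shielded vascular compartment;
the truncation shifts the realised mean slightly above 2.2, which we
accept rather than distort the prior's shape. Noise of 0.3 cmH2O SD per
sample is a transducer-scale figure chosen once; it was not tuned to any
target statistic. Hold durations default to 3 s and the squeeze plateau to
2 s so every averaging window spans at least one full cardiac cycle at
default heart rates; the default sampling rate is 100 Hz.

### What the generator does *not* emulate

No closed-loop cardiovascular model (stroke volume, fluid responsiveness
indices are descriptive constants, not mechanistic outputs), no lung
heterogeneity, recruitment or airway closure, no spontaneous breathing,
and cardiac interference is a sinusoid rather than a physiological venous
waveform. Consequently, passing tests demonstrate the *signal-processing
and statistical pipeline* is correct and calibrated under the stated
model; they cannot certify performance on real recordings where the
transmission may vary within a breath or drift between calibration and
measurement.

## Reading plateaus

Plateau pressures are means over the last 50% of each hold window
(`avg_frac = 0.5`), skipping post-maneuver equilibration — standard
plateau-reading practice. The CVP channel needs more care because the
cardiac oscillation (±2 cmH2O) is as large as the signals being read. We
average over the largest whole number of cardiac cycles that fits in the
sub-window: the cycle length is estimated from the autocorrelation peak of
the window (searched between 0.4 and 2 s lag, parabolic refinement),
then sharpened by a linear-prediction fit, which is exact for a pure tone;
the plateau value is the fitted constant of a
$\{1, \sin, \cos\}$ regression at that frequency over the whole-cycle
span. For a noise-free sinusoid this removes the oscillation to machine
precision, which is what makes the calibration ratio recoverable to 0.01%
rather than 1%; under white noise the fitted constant has variance
$\approx \sigma^2/n$ over $n$ samples. If the window cannot hold one
cycle the reader falls back to a plain mean with a degraded-precision
warning. Windows are annotation-first: the experiment's events are known,
and flow-based detection (maximal $|\dot V| < 0.005$ L/s intervals lasting
≥ 1.5 s) is a fallback for unannotated data. Expiratory-hold annotations
span the whole zero-flow quiescent interval, including the tail of the
passive expiration, because nothing observable distinguishes the tail
from the valve closure and all channels are already at their
end-expiratory values there.

## Validity filtering

A measurement is trusted only if the occlusion test validates it: the
ratio of the esophageal (or direct pleural) swing to the airway swing
during occlusion must lie between 0.8 and 1.2. We treat the band as
inclusive at both boundaries, so the typical balloon-transmission
population ($0.9 \pm 0.1$) sits interior to it. Exclusions cascade:

1. an out-of-band direct-pleural/airway ratio means the airway or pleural
   measurement itself failed, removing the condition from **every**
   comparison;
2. among the remainder, an out-of-band esophageal ratio removes the
   condition from the esophageal comparisons;
3. an occlusion-test failure (tidal CVP swing below `eps_cvp` = 0.5 cmH2O,
   where $\kappa$ becomes numerically unstable) or a CVP measurement
   failure removes it from the CVP-derived comparisons.

Each comparison therefore has its own n, and the accounting table makes
the cascade reproducible from the report alone.

## Agreement statistics

Both statistics are computed from definition rather than delegated, since
they *are* part of what the package exists to pin down:

* **Bland–Altman**: bias = mean(estimate − reference), precision = sample
  SD of the differences, limits of agreement = bias ± 1.96 × precision.
  The simple independent-pairs formula is used, pooling repeated measures
  per subject, matching how such analyses are conventionally presented
  with per-subject markers; no within-subject variance correction is
  applied.
* **Repeated-measures correlation**: the common within-subject
  correlation from the shared-slope ANCOVA. Centering both variables
  within subject, $r$ is the correlation of the centered values (carrying
  the common slope's sign), with $df = N - k - 1$ over $k$ subjects and
  $N$ pairs, and $p$ from $t = r\sqrt{df/(1-r^2)}$. p-values are reported
  unadjusted, with the df stated. Although the repeated-measures design
  needs ≥ 2 subjects, the implementation accepts a single subject (with a
  warning), where it reduces to that subject's ordinary correlation — a
  consistency limit the tests assert.

## Error propagation

Writing $M$ for the occlusion airway swing, $c_0$ for the occlusion CVP
swing and $a_0$ for the tidal CVP swing, with each windowed mean carrying
independent noise of variance $\sigma^2/n_w$, first-order propagation
through $\hat{\Delta P_{pl}} = (M/\hat c)\,\hat a$ gives

$$\mathrm{SD}(\hat{\Delta P_{pl}} - \Delta P_{pl}) \approx
\kappa \sqrt{\sigma^2\left(\tfrac{1}{n_{insp}} + \tfrac{1}{n_{exp}}\right)
 + \left(\tfrac{a_0}{c_0}\right)^2
   \sigma^2\left(\tfrac{1}{n_{base}} + \tfrac{1}{n_{sqz}}\right)}.$$

Both the tidal term and the calibration term matter (the calibration term
is damped by $(a_0/c_0)^2$, typically ~0.15 at default settings). A
1000-replicate Monte-Carlo run in the test suite matches this formula
within a few percent. The formula also shows why the method is robust to
unit mix-ups: rescaling the CVP channel by any factor multiplies $\kappa$
by its inverse and cancels in the product — an invariance the tests assert
directly.

## Design choices on genuinely open points

* $\kappa$ is read from endpoint deltas of windowed means (baseline vs
  squeeze plateau), matching the two-level reading of the occlusion
  maneuver, not from a regression over the ramp; the estimator is thereby
  independent of the squeeze shape.
* One occlusion test per condition, applied to that condition's tidal
  measurement immediately after; $\kappa$ is never reused across
  conditions, and how long a calibration stays valid is outside the
  model (the simulator holds $T$ constant within a condition).
* The tidal airway swing is plateau minus total PEEP (both zero-flow
  pressures from holds), not peak minus PEEP, because the occlusion logic
  guarantees only zero-flow pressures.
* Tidal CVP swings are read at the same hold windows as the airway
  pressures, not from dynamic waveform extremes.
* The tidal volume entering the compliance partition is measured from the
  volume channel (inspiratory-hold minus expiratory-hold plateau), not
  copied from the generator's settings.
* The transmission-drift mechanism (`transmission_drift`) deliberately
  violates the calibration assumption — $T$ during ventilation differs
  from $T$ during the occlusion test — and is the lever for sensitivity
  analyses; the null model keeps it at zero, reflecting the working
  hypothesis that accuracy is independent of volume status and chest-wall
  compliance.

## Numerical notes and degenerate inputs

* Waveform CSVs are written with 17 significant digits and parsed with
  `strtod`, so write→read round trips are bit-exact.
* $C_L$ is undefined when the pleural swing equals or exceeds the driving
  pressure; it is returned as missing with a flag rather than a negative
  compliance.
* A condition whose occlusion CVP swing is below 0.5 cmH2O is flagged as
  an occlusion-test failure (classed warning) instead of producing an
  unstable $\kappa$.
* Strata with fewer than two pairs are omitted from Bland–Altman output
  with a warning; subjects with fewer than two complete pairs are dropped
  from the repeated-measures correlation.

## Problem sizes used in the checks

The shipped checks run the full pipeline at the study's own scale — 10
subjects × 6 conditions — for the exact-recovery and default-study
analyses; 100 seeded occlusion tests for calibration recovery; 1000
Monte-Carlo replicates for noise propagation; 50 random small datasets
for the correlation oracle; and 250 simulated condition-pairs per cell
(1500 total) for the volume/chest-wall null model. With three ordinary
breaths per record these sizes characterise every statistic well while a
complete run stays around a minute on a single core.

## Known limitations

The estimator shares the method's intrinsic limits: it provides only the
*change* in pleural pressure, not its absolute value; it requires a
successful occlusion test and passive (paralyzed) ventilation; and its
accuracy on real data hinges on the transmission being stable between
calibration and measurement — exactly the assumption the drift sweeps
probe. The simulator's cleanliness means the reported precisions are
optimistic relative to animal or clinical recordings, whose noise is
neither white nor stationary.
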