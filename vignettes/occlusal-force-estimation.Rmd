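---
title: "Estimating occlusal force from ear canal movement: model, estimator and synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating occlusal force from ear canal movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earforce)
```

## The measurement problem

Occlusion recruits the masticatory muscles around the temporomandibular
joint, and that recruitment deforms the ear canal. An earphone-type optical
sensor (infrared LED plus phototransistor) turns the deformation into a
voltage, so bite force could in principle be read from the ear — without an
in-mouth pressure sensor or EMG electrode pads. `earforce` implements the
desk side of that idea: given simultaneously recorded ear-sensor,
masseter-EMG-envelope and occlusal-force-meter channels, it (i) quantifies
how tightly the ear signal tracks force, (ii) checks that the association
is not merely a shadow of muscle activation, and (iii) estimates force from
the ear signal alone, with an honest cross-validated error.

All channels are consumed after analog-to-digital conversion: 0–3.3 V at
100 Hz and 12 bit, normalized to [0, 1] ("AD units"). One *run* is a 2 s
press-and-hold chew trial (200 samples); a *session* is one subject's K
runs (the protocol uses K = 6). AD force values map to Newtons through an
affine calibration `F = 1985.6 v − 75.066`, determined experimentally for
the force meter. Two conventions are worth making explicit:

* **The calibration acts on the normalized AD value**, not on raw volts.
  With this reading the conversion reproduces the published worked values
  (0.6004 → 1117 N, 0.0614 → 47 N, 0.4411 → 801 N, 0.0448 → 14 N)
  exactly, which fixes the convention unambiguously.
* **No clamping.** The relation is applied as printed, so AD values below
  the zero crossing (≈ 0.0378) yield small negative Newton values rather
  than being truncated.

## Correlation structure

Per run, three Pearson coefficients (ear–force, ear–EMG, EMG–force) and two
first-order partial coefficients are computed: ear–force controlling for
the EMG envelope, and EMG–force controlling for the ear signal. The partial
uses the textbook recursion

$$ r_{xy\cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}
   {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}, $$

which equals the correlation of the residuals after regressing each
variable on the control; both forms are implemented, and the test suite
uses the residual form as an independent oracle for the recursion
(agreement to 1e−10 over 1000 random triples). Partials are computed **per
run** from that run's own pairwise coefficients and then aggregated — not
from run-averaged coefficients — since each run is a separate realization
of the coupling. Every per-run series is summarized by its mean and the
square root of its unbiased (n − 1) variance across runs.

Degenerate inputs fail loudly: a zero-variance channel or a |r| = 1 control
raises a classed error naming the subject, run and channel. Silent `NA`s
would corrupt the run averages. A corollary worth knowing: on *exactly*
affine noise-free channels all pairwise |r| = 1 and the partial coefficient
is 0/0, so `correlation_table()` refuses such sessions; the pairwise
coefficients still converge to ±1 (and their dispersion to 0) in the
vanishing-noise limit.

## The anchored single-regression estimator

For fold k of leave-one-run-out cross-validation, each training run
contributes the OLS slope of force on ear (computed with an intercept); the
fold slope $\bar a_k$ is the arithmetic mean of the K − 1 training slopes.
Prediction on the held-out run deliberately discards the fitted intercept
and anchors at the run's first sample:

$$ \tilde f_{kj} = \bar a_k (e_{kj} - e_{k0}) + f_{k0}. $$

The anchor is the first sample (j = 1) of the held-out run: it mirrors the
intended device usage, where the wearer brings the teeth into contact
(force ≈ 0) at activation and the sensor reading at that instant is the
initial value. Anchoring is what makes the estimator robust to the ear
sensor's run-to-run offset drift — the ear–force traces of different runs
form near-parallel lines, so a common slope with a per-run anchor fits all
of them, while a pooled intercept would not.

Accuracy per fold is $RMSE_k$ against the measured force, and the
scale-free $NRMSE_k = RMSE_k / (\tilde f_{kMAX} - \tilde f_{kMIN})$, which
normalizes by the *estimated* range so subjects with different bite
strengths are comparable. The subject summary averages each per-fold column
independently; in particular the summary NRMSE is the mean of the per-fold
ratios, **not** the ratio of the mean RMSE to the mean width (for a typical
subject 0.0338/0.5390 = 0.0627 ≠ 0.0659). Both conventions are defensible;
the independent-column average is used because it weights every fold
equally in each reported quantity. Errors are reported in AD units — the
natural scale of the estimator; Newton-scale columns are available in the
reports via the calibration.

Numerical/degenerate-case choices: a constant ear channel in any training
run aborts the fold with an error naming the run (silently dropping folds
would change K and bias the averages); estimates are not clamped to [0, 1]
even though measured channels are, because the affine predictor can
legitimately overshoot on extreme inputs; a zero estimated width makes
NRMSE undefined and errors.

## What the synthetic generator emulates

Real recordings of this protocol are restricted, so `generate_session()`
produces sessions with the statistical structure the analysis assumes:

* a latent force signal per run: a smoothstep ramp over 2 s from `f_base`
  to a per-run peak `f_peak (1 + jitter)` — monotone "press to maximum",
  with run-to-run peak variability;
* an ear channel affinely coupled to the latent force with subject-specific
  *signed* slope (`ear = e_base + δ_r + (force − f_base)/slope`): the
  coupling sign differs between subjects because ear-canal geometry
  differs; δ_r is a per-run offset drift (Normal, sd `drift_sd`),
  reproducing the near-parallel-lines pattern;
* an EMG envelope linearly coupled to the latent force (a saturating
  coupling was considered and rejected: the observed EMG–force
  correlations are near-linear and high);
* independent per-sample Gaussian measurement noise per recorded channel,
  then clamping to [0, 1] and optional 12-bit quantization, in that order —
  matching the physical AD path.

Noise is attached to the *recorded* channels, not to the latent signal the
other channels couple to. This is the standard errors-in-variables reading,
and it is what makes two calibration experiments meaningful: with noise on
the force channel only, the ear predictor is clean and the recovered slope
is unbiased (the acceptance suite verifies recovery of −16.1 to well within
2% over 100 seeds); with noise on the ear channel, the slope attenuates
toward zero, a monotone trend the property tests check at three noise
levels.

Defaults (AD units throughout) emulate a well-behaved subject: force ramp
0.06 → 0.60 (≈ 44 N → 1116 N), slope −16.1, `drift_sd = 0.01`,
`noise_ear_sd = 0.0015`, `noise_force_sd = 0.005`, `noise_emg_sd = 0.06`,
EMG gain 1.2 with baseline 0.08, peak jitter 3%. The noise scales were
chosen by a closed-form signal-to-noise argument to land the per-run
pairwise correlations in the observed 0.91–0.99 band; none of them is
recoverable from published summaries, so their absolute magnitudes are
documented as plausible rather than validated. One constraint matters for
the qualitative partial-correlation finding (ear–force partial exceeding
EMG–force partial): writing ρ for a channel's correlation with the latent
signal, the regime must satisfy **ρ_ear > ρ_emg for every subject** — the
ear must be the cleaner proxy of force than the EMG envelope. Because the
ear signal's amplitude shrinks as |slope| grows, the binding case is the
steepest-coupling preset; the default EMG noise (0.06) satisfies the
constraint with a wide margin for all five presets.

The five presets (`preset_subjects()`) reuse the published per-subject
slopes (−16.11, −22.86, +12.00, −8.96, +18.75) and force ranges, giving
three negative- and two positive-coupling subjects; the pipeline reproduces
the qualitative published pattern on them (coupling-signed ear–force and
ear–EMG correlations, always-positive EMG–force, dominant ear–force
partial). What the generator does **not** model: the relax phase after the
press (the estimator consumes only the 2 s press window), motion artifacts,
optical saturation of the ear sensor at extreme forces, and any
nonlinearity in the ear–force coupling. Passing tests on synthetic data
therefore demonstrate correctness of the pipeline under its own
assumptions, not validity of those assumptions for real ears.

## Determinism and sizes

Each `subject_params()` carries a master seed; `generate_session()` is
bit-reproducible given `(params, K)` and restores the caller's RNG state.
The quantization flag defaults to on (the hardware path); exactness checks
(zero noise ⇒ RMSE = NRMSE = 0 and exact slope recovery) run with it off,
since grid rounding is itself a small noise source. The test and acceptance
problem sizes — 200-sample runs, K = 6, 100-replicate recovery experiments,
1000 oracle triples — match the protocol's native scale, which is small
enough that the full suite runs in well under a minute.

## Limitations

The estimator is a single regression on one predictor: it inherits
attenuation bias from ear-channel noise, assumes the within-run ear–force
relation is linear and stable across runs up to an offset, and its NRMSE
normalization becomes unstable when the estimated width is near zero (weak
bites). Aggregation uses plain means over folds; median- or mode-based
slope aggregation and EMG-augmented multivariate estimation are out of
scope. Calibration constants are device-specific and should be re-measured
for any other force meter.
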