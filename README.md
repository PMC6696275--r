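# earforce

Occlusal (bite) force estimation from ear canal movement sensing.

Chewing deforms the ear canal, and an earphone-type optical sensor can track
that deformation noninvasively. `earforce` implements the analysis pipeline
behind such an ear-sensor bite-force meter: it characterizes how three
simultaneously recorded channels — the ear sensor, the masseter-muscle EMG
envelope, and an in-mouth occlusal force meter — covary during press-and-hold
chew trials, and it estimates occlusal force from the ear signal alone by a
fold-averaged anchored single regression, evaluated with leave-one-run-out
cross-validation. Because real subject recordings of this kind are typically
access-restricted, the package ships a seeded synthetic session generator
that emulates the measurement protocol, so the whole pipeline is testable and
reproducible end to end.

It is aimed at researchers developing wearable biosignal calibrations:
people who need a tested reference implementation of the estimator and its
evaluation, or a simulation harness to probe its behavior (noise
sensitivity, attenuation bias, drift robustness) before collecting data.

## Data model

All channels live on a normalized AD scale: the 0–3.3 V analog inputs are
digitized at 12 bit and 100 Hz and mapped to [0, 1]. A **run** is one 2 s
press window (200 samples, j = 1..200); a **session** is one subject's K = 6
runs. AD force values convert to Newtons through the affine calibration

    F = 1985.6 v − 75.066   [N per AD unit]

## The estimator

For fold k of a K-fold leave-one-run-out scheme, each training run i
contributes the ordinary least-squares slope of force on ear,

    a_ki = ( n Σ e_j f_j − Σ e_j Σ f_j ) / ( n Σ e_j² − (Σ e_j)² ),

and the fold slope is the average ā_k of the K − 1 training slopes. The
held-out run is predicted by anchoring at its first sample (e_k0, f_k0)
rather than a fitted intercept:

    f̃_kj = ā_k (e_kj − e_k0) + f_k0 .

Anchoring makes the predictor immune to the run-to-run offset drift the ear
sensor exhibits (near-parallel ear–force traces across runs). Accuracy per
fold is RMSE_k against the measured force and NRMSE_k = RMSE_k /
(f̃_kMAX − f̃_kMIN); the subject summary averages each fold column
independently. Alongside, the package reports per-run Pearson correlations
for the three channel pairs and the two first-order partial correlations
(ear–force controlling EMG, EMG–force controlling ear), each summarized as
its mean and the square root of its unbiased variance over runs.

## Worked example

```r
library(earforce)
params <- subject_params(slope = -16.1, seed = 1)   # negative ear-force coupling
session <- generate_session(params, subject_id = "A")
correlation_table(session)
#>  subject statistic      pair  mean_r   sd_r n_runs
#>        A   pearson ear_force -0.9914 0.0014      6
#>        A   pearson   ear_emg -0.9568 0.0030      6
#>        A   pearson emg_force  0.9640 0.0023      6
#>        A   partial ear_force -0.8940 0.0125      6
#>        A   partial emg_force  0.4057 0.0563      6

cv <- cross_validate(session)
cv
#> Leave-one-run-out cross-validation: subject A, K = 6 folds
#>   slope a_bar: -15.7742 (sqrt unbiased variance 0.0300)
#>   RMSE 0.0331 | width 0.6169 | NRMSE 0.0539 (fold averages)

round(calibrate_force(c(0.6004, 0.0614)))
#> [1] 1117   47
```

Reading the numbers: the ear channel tracks force almost perfectly within a
run (|r| ≈ 0.99, with the subject's negative coupling sign), and it keeps
most of that association after the EMG envelope is partialled out (−0.89),
whereas the EMG–force partial collapses (0.41) — the ear sensor carries
force information beyond what muscle activation explains. The recovered
slope (−15.77) sits slightly below the generating −16.1 because per-sample
ear noise attenuates a regression slope toward zero; the cross-validated
NRMSE of about 5% of the estimation range says the anchored predictor
generalizes across runs despite offset drift. `calibrate_force()` converts
estimate extremes to Newtons (here ≈ 1117 N peak, 47 N baseline).

`summary(cv)` prints the per-fold table, `plot(cv)` overlays measured and
estimated force per fold, and `analyze_sessions()` writes CSV/text reports
for many subjects at once. Sessions round-trip to disk as plain CSV plus a
YAML manifest (`write_session()` / `read_session()`).

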