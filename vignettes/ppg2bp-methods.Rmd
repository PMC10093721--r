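---
title: "Methods: cuffless blood pressure estimation from PPG waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cuffless blood pressure estimation from PPG waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Arterial blood pressure is conventionally measured with an inflatable cuff.
The photoplethysmogram (PPG) — an optical measure of blood-volume change in
peripheral tissue — carries morphological information about the pressure
pulse, so a regression from PPG-derived features to systolic (SBP) and
diastolic (DBP) pressure offers a cuffless alternative suitable for wearables
and continuous monitoring.

`ppg2bp` implements that pipeline end to end:

1. **Preprocessing.** Baseline wander (sub-0.5 Hz drift from respiration and
   vasomotion) is removed by subtracting a running-median estimate; residual
   high-frequency noise is removed by a zero-phase low-pass filter; the
   cleaned PPG is cut into fixed-length windows; paired SBP/DBP references
   are read off the arterial pressure (ABP) channel beat by beat.
2. **Feature extraction.** Each window is summarised by 24 features:
   17 time-domain statistics of the amplitude sequence (mean absolute value,
   waveform length, crossing counts, energy measures, weighted variants) and
   7 "chaotic" statistics (sample, approximate, fuzzy, Shannon and
   permutation entropy; Higuchi and Katz fractal dimension) that quantify
   the regularity and complexity of the pulse train.
3. **Regression.** Seven models map the feature vector to pressure: ordinary
   and Huber-robust linear regression, exact Gaussian-process regression
   (GPR) under rational quadratic (RQ), squared exponential (SE) and
   Matérn 5/2 kernels, and ε-insensitive support-vector regression with
   linear and Gaussian kernels.
4. **Evaluation.** k-fold cross-validation with pooled out-of-fold RMSE,
   MSE, MAE, MAPE and R², Pearson correlation, Bland–Altman limits of
   agreement, time-series overlays, and categorical grading of readings on
   the British Hypertension Society scale.

The modelling assumption throughout is that segment-level PPG morphology is
informative about segment-level pressure; the package makes that assumption
testable by shipping a synthetic generator in which it holds by
construction.

## The synthetic data generator

`synth_config()` / `generate_record()` produce paired PPG+ABP records with a
per-beat truth table. Each beat contributes a systolic Gaussian pulse and a
smaller, delayed dicrotic Gaussian to the PPG; a sinusoid below 0.5 Hz
emulates baseline wander and white noise emulates sensor noise. The ABP
channel is rendered beat by beat so that its sampled maximum equals the
truth-table SBP and its onset sample equals the truth-table DBP *exactly* —
reference extraction can therefore be verified to numerical precision.

Per-beat SBP and DBP are exact linear functions of the beat's morphology
(pulse amplitude, pulse width, heart period) plus Gaussian noise
(`bp_noise_sd`, default 1 mmHg). Defaults: 125 Hz sampling (the common
waveform-database rate), 75 ± 3 beats/min, pulse amplitude 1 ± 0.1 units,
width 0.12 ± 0.01 s, dicrotic fraction 0.35, baseline 0.3 units at 0.2 Hz,
PPG noise SD 0.02. The amplitude coefficients of the pressure map are
negative, and the PPG pulse is centred at 0.70 of the beat period (pulse
transit delay relative to the pressure upstroke), which together reproduce
the *negative* instantaneous PPG–ABP correlation characteristic of
intensive-care recordings (about −0.5 on default records).

Two deliberate choices deserve explanation:

* **Amplitude drift.** Per-beat amplitudes follow a stationary AR(1)
  (`amp_drift_phi = 0.95`) rather than i.i.d. draws. Independent jitter
  averages out within an 8 s window, leaving almost no between-segment
  signal for the regression stage to find; slow vasomotor-like drift keeps
  the per-beat SD realistic while giving each segment a distinct mean
  amplitude, so a correct pipeline attains high held-out R² (about 0.9 for
  SBP on default records) and a broken one visibly does not.
* **What the generator does not emulate.** There is no hemodynamic
  simulation (no Windkessel dynamics, no reflected waves), no motion
  artifacts, no sensor saturation, no inter-patient variation in the
  feature→pressure map. Passing tests therefore demonstrate that the
  *pipeline machinery* is correct — exact formulas, exact references,
  recoverable mappings — not that blood pressure is predictable from real
  PPG at any particular accuracy. Published segment-level error rates on
  intensive-care data (RMSE of roughly 4 mmHg systolic, 2 mmHg diastolic)
  live on a data distribution this generator does not claim to match.

## Preprocessing choices

* **Median baseline windows (0.6 s, then 1.2 s).** Two running-median passes
  are the established baseline-correction practice for quasi-periodic
  physiological waveforms. A running median tracks — and therefore removes —
  components whose period is long relative to its window, so drift at
  0.2 Hz is attenuated by more than 90 % while beat-rate content passes.
  The trade-off is intrinsic: any window short enough to track sub-0.5 Hz
  drift is comparable to the ~0.8 s beat period and partially tracks the
  pulse train itself, so repeated application rescales pulse amplitude by
  tens of percent (shape and peak timing are preserved — re-application
  correlates > 0.99 with its input and moves no pulse peak by more than
  2 samples). Exact idempotence would require windows of at least two beat
  periods, which degrades drift tracking below the 90 % mark; we keep drift
  removal, which is the stage's purpose. Both windows are configurable.
* **Low-pass: 4th-order Butterworth at 5 Hz, forward–backward.** The cutoff
  follows standard PPG practice; the zero-phase (filtfilt) realisation
  preserves pulse timing, which the difference-based features rely on.
  Filter edge transients are a property of zero-phase filtering; analyses
  that care (tests, amplitude measurements) evaluate away from the edges.
* **Windows: 8 s, no overlap.** At least six full beats even at 50 beats/min
  — enough support for the template entropies (1000 samples at 125 Hz).
  Trailing partial windows are dropped; indices are 0-based, windows
  half-open.
* **References: mean over beats.** Within each window, systolic reference =
  mean of detected per-beat maxima, diastolic = mean of the troughs between
  consecutive peaks. The mean is robust to a single odd beat. Peak
  detection is deliberately simple and deterministic: strict local maxima
  above the window's 60th amplitude percentile with a 0.33 s refractory
  period. Windows with no detectable beat are excluded and counted.

## Feature definitions and conventions

The 17 time-domain features follow their standard formulas (see
`?time_features`). Parameter conventions, all configurable via
`feature_params()`:

* Zero-crossing and slope-sign-change thresholds default to 0; Willison
  amplitude and myopulse thresholds default to `0.5 * sd(x)`, making the
  counts invariant to PPG gain. (On strongly smoothed clean signals the
  Willison count can be identically zero across segments; the regression
  stage handles the resulting constant column by dropping it with a logged
  warning.)
* The enhanced features (EMAV/EWL) use exponent `P = 0.75` on the central
  half of the window and `0.5` outside; MMAV1 uses weights 1 (centre) and
  0.5 (edges); MMAV2 uses the rising/falling ramps `4i/L`, `4(L−i)/L` —
  the established conventions of this feature family.
* The log detector floors `|x|` at 1e−12 so windows containing exact zeros
  stay finite; the geometric mean is perturbed negligibly.
* `var` is computed as `sum(x²)/(L−1)` *without* mean subtraction. After
  baseline removal segments are near-zero-mean, where this coincides with
  the usual variance; keeping the raw-moment form preserves the exact
  algebraic identity `rms² · L = ssi` alongside it.
* Maximum fractal length is `log10(sqrt(sum(diff(x)²)))` (the square-root
  form of the literature definition).

Chaotic features:

* **Sample entropy** (m = 2, r = 0.2·SD, Chebyshev distance, self-matches
  excluded). When no (m+1)-template pair matches, the value is capped at
  `log(B + 1)` — the smallest resolvable conditional probability — instead
  of returning infinity, keeping feature tables finite.
* **Approximate entropy** uses the standard Φ-difference construction with
  self-matches included.
* **Fuzzy entropy** is the De Luca–Termini *membership* entropy of min-max
  normalised absolute amplitudes, with 0·log 0 = 0 and the constant window
  mapping to 0 by convention. This is a fuzzy-set entropy, not the
  template-matching "FuzzyEn" statistic common in pulse-wave work; the
  tolerance/exponent parameters are retained in `feature_params()` for
  forward compatibility but unused by the membership form.
* **Shannon entropy**: 16 equal-width amplitude bins, natural log, empty
  bins skipped.
* **Permutation entropy**: ordinal patterns of order 3 at delay 1, natural
  log, unnormalised; ties resolved by index order (earlier sample ranks
  lower), which makes constant windows give exactly one pattern and zero
  entropy.
* **Higuchi fractal dimension**: scales k = 1..10, Higuchi end-correction,
  least-squares slope in log–log coordinates.
* **Katz fractal dimension**: amplitude path length over amplitude
  excursion; a constant window (zero path length) returns 1, the
  straight-line value.

All entropies use the natural logarithm; the fractal dimensions use log10 as
their printed definitions do.

## Regression models

Features are z-scored inside every fit (constants stored on the model), so
predictions are invariant to affine rescaling of any feature column.

* **Linear / robust linear.** QR-based least squares; rank-deficient designs
  fall back to the pseudo-inverse (or drop dependent columns, for the
  robust fit) with a warning. The robust loss is Huber with tuning constant
  1.345, the conventional 95%-efficiency choice.
* **Gaussian-process regression** is exact (Cholesky) with a zero mean
  function on centred targets. Kernels: squared exponential; rational
  quadratic `σf²(1 + r²/(2αℓ²))^(−α)` (the standard form — as α → ∞ it
  converges to the SE kernel, a limit the tests verify at α = 10⁶); and
  Matérn 5/2 `σf²(1 + √5 r/ℓ + 5r²/(3ℓ²)) exp(−√5 r/ℓ)`. A Matérn 3/2
  variant (`as_printed = TRUE`) is retained because the 3/2 and 5/2 forms
  are easily conflated in the literature. Hyperparameters (σf, ℓ, σn, α)
  are optimised by maximising the log marginal likelihood with analytic
  gradients (L-BFGS-B on log-parameters). Three fixed, data-scale-derived
  starts (ℓ at 0.5/1/2 × the median pairwise distance, σn at 5/10/20 % of
  SD(y)) are scored and the best is polished, so fits are deterministic
  without a seed. The noise variance is floored at `1e−6 · var(y)` and the
  Gram matrix carries a 1e−10 jitter, guaranteeing a stable Cholesky;
  pairwise distances are precomputed once per fit so each likelihood
  evaluation is an elementwise kernel map plus one factorisation.
* **Support-vector regression** (ε-insensitive, via `e1071`): box constraint
  `C = IQR(y)/1.349` and tube `ε = IQR(y)/13.49` (scale-adaptive presets),
  Gaussian kernel scale `σ = √p` for `p` features — the "medium Gaussian"
  convention. All overridable through `model_spec()`.

## Evaluation

Cross-validation shuffles rows into k balanced folds from a stated seed
(default k = 10; 5-fold appears in parts of the motivating literature, so k
is a parameter rather than a constant). Every row is predicted exactly once
out-of-fold; headline metrics are computed on the pooled out-of-fold
predictions (per-fold values are retained for dispersion — pooling is the
aggregation that makes RMSE² = MSE hold exactly). R² is the standard
coefficient of determination `1 − SSE/SST` about the target mean. MAPE is
undefined when a target is zero and is reported as `NA` with a reason,
leaving the other metrics intact.

Bland–Altman differences are signed predicted − actual; limits of agreement
are mean ± 1.96·SD (n−1 denominator). The British Hypertension Society
grade map treats printed integer ranges as inclusive (140–159 means
140 ≤ x ≤ 159, implemented as [140, 160) on the continuous scale), resolves
disagreement between the SBP and DBP columns by severity (the higher grade
wins), and labels readings with SBP ≥ 140 and DBP < 90 as isolated systolic
hypertension, graded by SBP alone.

## Problem sizes and runtime

The shipped tests and the acceptance script are sized for a laptop-class
single core: oracle cross-checks use 50 segments of up to 400 samples;
model-recovery checks use feature tables of 500 rows; the end-to-end runs
use six to ten records of 80–120 s at 125 Hz (roughly 60–150 analysis
windows). All are choices of the package, adjustable through the same
public parameters they exercise.

## Known limitations

* Median baseline correction rescales spiky pulse trains (discussed above);
  downstream features see a consistently preprocessed signal, but absolute
  amplitude-bearing features should not be compared across different
  baseline settings.
* The WFDB reader supports the common single-file, format-16 layout only.
* GPR is exact and therefore O(n³); tables beyond a few thousand segments
  would need an approximation the package deliberately does not include.
* `classify_bp_grade` maps readings to categories; it is not an
  AAMI/BHS device-grading protocol.
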