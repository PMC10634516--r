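---
title: "Estimating blood lactate from exercise ECG: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating blood lactate from exercise ECG: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactecg)
```

## The estimation problem

Blood lactate concentration (BLC, mmol/L) is the standard index of metabolic
strain during endurance exercise: the first and second ventilatory thresholds
correspond roughly to 1–2 and 4 mmol/L, and training prescriptions are often
phrased as lactate targets. Measuring it requires blood sampling. The exercise
ECG, in contrast, is cheap and continuous, and its morphology shifts
systematically as intensity and metabolic strain rise: the RR interval
shortens, the ST segment and J point sink, the QT interval shortens, the
R-wave amplitude falls slightly and the T-wave amplitude grows.

`lactecg` treats end-exercise BLC as a function of the ECG,

$$Y = f(X),$$

with $X$ a window of single-lead (lead II) beats sampled at 200 Hz plus the
per-beat RR interval and three anthropometrics (age, sex, BMI), and $f$ a
hybrid neural network estimated from constant-work-rate (CWR) exercise
sessions. Sessions come in three intensities — L, M, H at roughly 35/60/90 %
of maximal work rate — and separate models are fitted for the combined
low/moderate regime (`LM`) and the high regime (`H`), because the
lactate–ECG relationship differs across the ventilatory thresholds.

## The estimator

1. **Beat segmentation.** R peaks are found with a Pan–Tompkins-style
   detector (5–15 Hz band-pass, derivative, squaring, 150 ms integration,
   adaptive threshold, 200 ms refractory period), then each interior peak is
   cut into a one-beat window spanning 35 % of the previous RR interval
   before the peak and 65 % of the next one after it. Consecutive windows
   tile the signal exactly, so segmentation is lossless; the first and last
   peaks lack a complete window and are dropped. Synthetic records carry
   ground-truth annotations that may bypass detection.
2. **Imaging.** Each beat is resampled to a fixed width (128 columns by
   default), its voltage is mapped from a fixed window of −1.5 to +2.0 mV
   onto the image rows, and the trace is drawn as a connected one-pixel
   polyline with anti-aliased (fractional-coverage) intensities. Time runs
   along the x axis, voltage change along the y axis. Anti-aliasing matters:
   with binary pixels a 128-row image quantizes amplitude to ~27 µV, while
   fractional coverage preserves sub-pixel amplitude so the convolutional
   backbone can recover fine morphology. Resampling discards the beat's
   duration, so the RR interval re-enters as a fusion scalar.
3. **Backbone.** A residual CNN with the classic four-stage layout
   (3, 4, 6, 3 two-convolution blocks; 34 weighted layers in the reference
   configuration) maps each image to a 300-dimensional feature vector via a
   final fully connected layer. Identity shortcuts are used within stages
   and 1×1 projections across downsampling boundaries. Shallower presets
   (6, 10, 18 layers) exist for desk-scale experiments; all keep the
   300-dimensional feature so downstream analyses are depth-invariant.
4. **Fusion.** The four scalars [age, sex, BMI, RR] are standardized
   (training-set mean/SD for age, BMI, RR; sex coded male = 0, female = 1),
   placed at the head of the feature vector, and the resulting 304-vector
   passes through four fully connected layers (ReLU, hidden width 64 by
   default) into the output heads. The scalars are injected only at the
   first fusion layer.
5. **Binary-coded output.** The network does not regress lactate directly.
   The value is rounded to 0.1 mmol/L and split into two 8-bit binary
   targets: S1 codes the integer part, S2 the first decimal digit
   (5.2 → S1 `00000101`, S2 `00000010`; the rightmost bit carries weight
   $2^0$). The 16 sigmoid outputs are trained with mean per-bit binary
   cross-entropy; at inference each probability is thresholded at 0.5 and
   the code is decoded back to mmol/L, clamping S2 patterns above 9 to 9.
6. **Session aggregation.** Each beat in the analysis window — by default
   the final 180 beats, since the reference blood sample is drawn at the end
   of exercise — is scored independently and the session estimate is the
   median, rounded to one decimal. The median is robust to occasional
   mis-segmented beats and makes the accuracy-versus-window-size sweep well
   defined; the mean is available as an option.

Training uses Adam (learning rate 3e-3, batch 32 in the desk-scale
configuration) for a fixed epoch count, with all randomness — initialization
and data order — derived from the configuration seed, so training and
inference reproduce bit for bit.

## The synthetic generator

No public cohort pairs exercise ECG with end-exercise lactate, so the package
ships a generator that emulates the study conditions and provides known
ground truth:

* **Subjects:** age ~ Normal(33, 9) truncated to [18, 80] years, BMI ~
  Normal(22.8, 2.7) truncated to [15, 40] kg/m², P(female) = 17/31 — the
  cohort moments the estimator targets.
* **Lactate:** per-intensity Normal draws (L: 3.7 ± 2.3, M: 6.9 ± 4.2,
  H: 10.4 ± 4.1 mmol/L), truncated to [0.5, 25.5] by rejection and rounded
  to the 0.1 mmol/L codec resolution.
* **Beats:** a six-Gaussian P-Q-R-S-ST-T template (coefficients fixed in a
  versioned configuration). With $\lambda = \min(\mathrm{BLC}, 15)/15$, the
  template applies, relative to rest: R amplitude × (1 − 0.10 λ), T
  amplitude × (1 + 0.50 λ), ST offset −0.08 λ mV, QT interval × (1 − 0.15 λ).
  Exercise-ECG literature fixes only the *directions* of these changes;
  these magnitudes are this package's declared ground-truth convention,
  chosen within physiological plausibility and, deliberately, invertible —
  parameter-recovery testing requires that lactate be recoverable from
  morphology.
* **Sessions:** mean heart rates default to 110/140/170 bpm for L/M/H
  (typical CWR values; configurable), per-beat RR jitter is lognormal with
  3 % coefficient of variation, and the record adds 0.2 Hz sinusoidal
  baseline wander (0.05 mV) plus white noise (0.01 mV by default).

What the generator does **not** emulate: respiratory sinus arrhythmia,
ectopy and motion artifact, electrode drift beyond the single wander tone,
inter-subject morphology differences (all subjects share the template), and
any physiological coupling between anthropometrics and ECG shape. Passing
recovery tests therefore demonstrates that the pipeline is correct and that
the estimator can invert a known morphology–lactate mapping at low noise;
they say nothing about accuracy on real exercise ECG.

## Problem sizes and experiment design

The test suite runs two scales, chosen as sensible desk-scale experiments:

* a small cohort (6 subjects × L,M sessions, 80 beats each) on the 6-layer
  backbone with 32×32 images for capacity, determinism and reporting tests;
* a recovery cohort of 12 subjects × three sessions (L, M, H) with 200
  beats per session for the cross-validation and window-sweep experiments
  (fourfold CV plus five independent train/holdout splits), training on an
  evenly spaced subsample of 40 beats per session for 40 epochs.

## Two generalization regimes, and why they differ

Within-session generalization — scoring beats of a training session that
were never themselves trained on — reaches the 80 % level at 3 % relative
tolerance in the capacity test: the network separates the couple of dozen
training sessions (morphology, RR level and anthropometrics jointly identify
a session) and emits each one's memorized code.

Across-session generalization — fourfold cross-validation partitioned at the
*session* level, so a held-out session's lactate value was never seen — is
a categorically harder task under a binary-coded head, and the suite's CV
experiment shows session accuracy at 3 % tolerance near zero at this scale.
The reason is structural, not a training defect: a 3 % relative band around
typical lactate values is ±0.1–0.3 mmol/L, so the estimate's first decimal
digit must be nearly exact. Each S2 bit is a sawtooth in BLC with period as
short as 0.2 mmol/L, and ~18 training sessions provide far too few distinct
labels to pin those transitions down between them — no smooth interpolation
of bit probabilities can recover the decimal digit of an unseen label. The
near-perfect consistency achievable when beats of one session appear on both
sides of a partition is exactly the within-session regime above. Session
prediction, Bland–Altman agreement and the window sweep remain fully
supported and honestly measured under the leakage-free design; users who
need fold-level consistency numbers comparable to a beat-level partition
should be aware of the distinction.

## The weighting analysis

After training, the first fusion layer's 304 input weights are read as
variable importances: per input, the mean absolute outgoing weight; then,
following the normalization convention, absolute weights $w_1..w_t$ are
turned into proportions $y_i = w_i / \sum w$, centered
($w'_i = y_i - \overline{y}$, summing to zero) and rescaled by the maximum
absolute centered value into [−1, 1]. The identities $\sum y = 1$,
$\sum w' = 0$, scale invariance and the [−1, 1] range are asserted
property-style in the suite.

One caution established by the synthetic experiments: summarizing the ECG
block by the *average* of its 300 centered weights dilutes it — the backbone
spreads morphology information across a redundant 300-dimensional embedding,
so each individual feature weight is small even when the block as a whole
dominates (it carries well over 80 % of the absolute weight mass in trained
bundles). Per-variable bar charts built on the block average should be read
with that in mind; the package's dominance test is therefore formulated on
the block's total share. The 300 features are also not literally time
points; the waveform-weighting curve maps feature index uniformly onto the
resampled time axis and records that assumption in its metadata.

## Numerical choices and degenerate inputs

* Detection refuses records shorter than 2 s, flat signals, and signals with
  no energy maximum above the adaptive threshold (explicit "no beats"
  errors); segmentation needs ≥ 3 peaks; windows shorter than requested are
  used in full with a warning.
* The 0.35/0.65 beat split and the fixed −1.5..+2.0 mV voltage window are
  chosen to contain P through T at exercise heart rates; both are
  configurable. Voltages outside the window clip to the edge rows.
* Sample SDs (Bland–Altman, fold variance) use the n − 1 denominator.
* Soft decoding thresholds at ≥ 0.5; S2 codes above 9 clamp to 9 with a
  warning rather than erroring, since an unconstrained head can emit them.
* A constant standardization scale of 1 replaces any zero training-set SD.
* An `LM` bundle refuses `H` sessions (and vice versa) unless the caller
  overrides explicitly; the override is logged.
* Training aborts with a diagnostic on non-finite loss.
* A recurrent aggregator over per-beat features was considered and left out:
  each beat is scored independently and aggregated by the median, which
  keeps the window sweep interpretable and the estimator stateless.

## Limitations

The estimator is validated only against its own synthetic generator; the
morphology–lactate magnitudes are a declared convention, not physiology.
Real deployment would require a cohort with paired ECG and blood lactate,
calibration to the recording hardware, and artifact handling absent here.
The binary-coded head, while faithful to the reference design, is the main
obstacle to across-session generalization at fine tolerance; a direct
regression or ordinal head would be the natural alternative to benchmark.
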