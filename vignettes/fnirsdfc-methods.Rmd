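---
title: "Static and dynamic functional connectivity from task fNIRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static and dynamic functional connectivity from task fNIRS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`fnirsdfc` implements a complete analysis chain for multi-channel functional
near-infrared spectroscopy (fNIRS) recordings acquired during a 150-s block
verbal-fluency-style task: channel quality control, conversion to hemoglobin
concentration changes, denoising, region-of-interest (ROI) aggregation,
static and sliding-window functional connectivity (FC), per-participant
principal-component (PC) features of the window-wise connectivity, group
statistics, symptom correlations, and a cross-validated random-forest
classifier separating a clinical group (adolescent major depressive
disorder, "MDD") from healthy controls ("HC"). Because task-fNIRS cohorts of
this kind are rarely deposited, the package ships a seeded synthetic cohort
generator with planted effects so every stage can be exercised and validated
end to end.

```{r, eval = FALSE}
library(fnirsdfc)
cohort <- simulate_cohort(simulation_config(seed = 1))
result <- run_pipeline(cohort)
print(result)
```

# The measurement model

A recording holds raw dual-wavelength (695/830 nm) light intensities for 52
channels formed by adjacent source-detector pairs of a 3 x 11 frontotemporal
probe grid (17 sources, 16 detectors, 3 cm spacing), sampled at 10 Hz: a
10-s quiet baseline followed by the 150-s analysis period (30 s pre-task
counting, 60 s task, 60 s post-task counting).

**Quality control.** Channel retention uses the baseline signal-to-noise
ratio in decibels, `SNR = 20 log10(mean / sd)` per channel and wavelength,
with the sample (n-1) standard deviation and a 40 dB threshold. A channel is
kept only when it passes at *both* wavelengths. Exclusions are cohort-wide
by default (a channel failing in any participant is dropped for everyone,
so all analyses share one montage); a per-participant mode is available.
Whether baseline SNR should be computed on raw intensity or optical density
is genuinely ambiguous in the field; this package uses raw intensity.

**Conversion.** Optical density `OD(t) = -log10(I(t) / mean(I))` per channel
and wavelength, then the modified Beer-Lambert law: per sample the 2 x 2
system `dOD_lambda = d * DPF_lambda * (eps_HbO * dHbO + eps_HbR * dHbR)` is
solved for oxy/deoxyhemoglobin changes. The differential pathlength factor
(default 6.0 at both wavelengths) and the extinction table
(`extinction_coefficients()`, standard published values in cm^-1 mM^-1) are
configurable; all correlation-based results are invariant to these scalars,
which matter only for absolute concentration units and round-trip tests.

**Denoising order** is fixed and logged: conversion, Butterworth band-pass
0.01-0.2 Hz (3rd order, applied forward-backward for zero phase; edge
padding is sized from the filter's slowest pole so the 0.01 Hz corner's
transient dies inside the padding), wavelet motion correction, hemodynamic
modality separation. The wavelet step decomposes each channel with a
periodized orthogonal Daubechies-5 bank (dyadic reflection padding, maximum
depth allowed by the padded length), fits a zero-mean Gaussian with a robust
MAD scale to each detail level, zeroes coefficients whose two-sided tail
probability falls below 0.1, and reconstructs. Spikes and sharp baseline
shifts concentrate in few large coefficients and are suppressed; a pure
low-frequency signal passes nearly unchanged. One property of this
tail-zeroing algorithm is worth knowing: on Gaussian-like signals about 10%
of the coefficients — carrying roughly a fifth of the detail energy — are
in-distribution yet zeroed, which slightly attenuates recovered
connectivity values (see "Known limitations").

**Hemodynamic separation** decomposes each channel's (dHbO, dHbR) pair into
a functional component, on which deoxy change is a fixed negative ratio of
oxy change (`k = -0.6`, configurable; within the range reported for the
method), and a systemic component on the positively correlated direction
(ratio +1). Global physiology — Mayer waves around 0.1 Hz survive the
band-pass — rides on the systemic direction and is projected out; the
functional oxyhemoglobin signal is the backbone for everything downstream.

**ROI aggregation.** The retained channels map onto six ROIs — right/left
dorsolateral prefrontal cortex, right/left medial prefrontal cortex,
right/left temporal lobe — by lateral position on the grid; the map is
editable JSON configuration, not code. ROI traces are the linear sum of the
member channels' dHbO (a mean option exists; Pearson correlations are
indifferent to the choice, only stored magnitudes change).

# Connectivity features

**Static FC.** Pearson correlation of every ROI pair over the full 150-s
analysis period, Fisher z-transformed (`atanh`, with `|r|` clipped at
`1 - 1e-7` so degenerate inputs stay finite): a 6 x 6 symmetric matrix,
flattened to 15 pairs in the fixed row-major upper-triangle order. The full
recording (pre + task + post) is used for both static and dynamic FC; the
printed window arithmetic of the study design (131 windows from 150 s)
forces this interpretation, and using the same span for both keeps them
comparable.

**Dynamic FC.** A 20-s window sliding in 1-s steps (half-open,
sample-aligned, no partial final window) gives M = 131 windows at 10 Hz;
window-wise Fisher-z correlations form the K x M matrix **X** (K = 15
pairs).

**PC features.** Following the convention in which eigenvalues are indexed
by window, the covariance matrix of **X** is taken over the window
dimension (M x M): the 15 pairs are the observations and the windows the
variables, so at most K - 1 = 14 eigenvalues are positive and the selected
component count is capped at 14. Columns of **X** are centered before the
covariance (implied by "covariance matrix", and what standard PCA routines
do); the decomposition itself is computed by SVD of the centered matrix for
numerical stability, and a brute-force eigendecomposition of the covariance
serves as the independent oracle in the tests. Because each participant has
their own PCA, eigenvector signs are arbitrary; the package fixes each
eigenvector's sign so its largest-magnitude loading is positive, a
deterministic convention that makes score entries comparable across
participants (the cross-participant comparability of per-participant PC
axes remains an assumption of the source method, reproduced rather than
repaired). The reduced matrix **D** is the centered projection onto the
first N eigenvectors (the score convention of standard PCA
implementations), so the truncated reconstruction obeys the Eckart-Young
bound exactly, which the tests assert.

N is selected once for the whole cohort: the smallest N whose cohort-mean
cumulative contribution rate `CCR(N) = 100 * sum(eigenvalues[1:N]) /
sum(eigenvalues)` reaches 90%, with a logged warning if it overshoots 95%.
A single N keeps every participant's feature table aligned. On cohorts with
the default generator settings the selection typically lands at N = 6-7
with a mean CCR a little above 90%.

All participants' **D** matrices are then shifted by one global constant —
the cohort-wide minimum — so every dynamic feature is non-negative; a
constant shift preserves all differences and rank statistics. Inside
cross-validation the shift is re-derived from the training subsets of each
fold and applied to the held-out data, avoiding an information leak the
original protocol does not address (a shared constant cannot move forest
split decisions, so this is protocol hygiene rather than a numerical
difference, and the tests confirm determinism either way).

The feature table is 15 static + 15 N dynamic columns per participant
(105 when N = 6), labelled `static|<pair>` and `PC<k>|<pair>`.

# Statistics

Per feature, normality in each group is screened with the
Lilliefors-corrected one-sample Kolmogorov-Smirnov test at alpha = 0.05
(the behavior of mainstream statistics packages when a "KS one-sample
test" is reported); both groups normal gives the two-sided pooled-variance
Student t-test, otherwise the Wilcoxon rank-sum test. Counts use the
Pearson chi-square without continuity correction. Benjamini-Hochberg
q-values are computed within feature families — the static family, and each
PC order separately, matching a per-map presentation — with an option to
correct across everything at once; feature-symptom Spearman correlations
are corrected across the full feature x score grid.

A symptom score enters the correlation analyses when a cohort majority of
the clinical group exceeds its clinical threshold (depression subscale 14,
anxiety 7, stress 14 — configurable); the anhedonia score, which has no
established threshold, is always included. Regression models are fitted per
outcome: ordinary least squares of the score on that outcome's
FDR-significant features plus four covariates (age, sex coded 0/1, illness
duration, antidepressant exposure as fluoxetine-equivalent mg/day:
`dose * 40 / equivalent`, with the five-drug equivalence table fluoxetine
40, sertraline 98.5, paroxetine 34, clomipramine 116.1, venlafaxine 149.4).
Continuous variables are z-scored so slopes are standardized betas;
variance-inflation factors, a Breusch-Pagan homoscedasticity flag and a
Shapiro-Wilk residual-normality flag accompany every fit. Zero-variance
covariates are dropped rather than allowed to make the design singular.

# Classification

A random forest (Gini splitting) separates the groups from the full feature
table. The 10-fold plan is stratified by group with near-equal subset sizes
(16-17 at n = 161); within fold i, subset i is the test set, subset
`(i mod k) + 1` the validation set — a deterministic rotation in which every
subset serves each role exactly once — and the remaining eight subsets form
the training set. The hyper-parameter grid spans trees 10-150 by 10,
minimum leaf size 1-11, and bootstrap fraction 0.5-1.0 by 0.1 (990
configurations); each configuration is trained per fold and scored on the
validation subsets, and the best mean validation accuracy wins with a
deterministic tie-break (fewer trees, then larger leaf, then smaller
fraction). Per-tree bootstrap draws `round(fraction * n_train)` cases with
replacement. Test predictions are pooled across folds for accuracy
(percent), F1 (clinical group positive) and AUC, with the per-fold means
also reported since protocols are often ambiguous between the two; the AUC
score is the fraction of trees voting for the clinical group. 95%
confidence intervals are percentile bootstrap over 1000 resamples of the
pooled test predictions. Feature importance is out-of-bag permutation
importance per fold, averaged, floored at zero and normalized to a maximum
of one. `rf_grid_reduced()` is a 3 x 3 x 2 sub-grid spanning the corners of
the space for compute-constrained runs; the validation surface is flat
enough that the chosen corner is stable.

# The synthetic cohort generator

The generator's defaults encode the study conditions the analysis assumes;
they are fixed design choices, not tuning knobs.

* **Latents.** Six ROI hemodynamic latents per participant are stationary
  band-limited (0.01-0.2 Hz, flat spectrum) Gaussian processes synthesized
  in the frequency domain — spectral synthesis is exact and avoids the
  low-frequency distortion that time-domain filtering of finite white-noise
  segments introduces. They are mixed through a slowly time-varying
  correlation matrix: per-participant pairwise Fisher-z targets plus
  sinusoidal coupling modulation (amplitude 0.15 in z units, drawn
  uniformly +/-50% per pair, period 60 s, random phases), updated every
  second and ridged to positive definiteness when needed.
* **Group structure.** Target mean pairwise Fisher-z 0.39 (HC) and 0.32
  (MDD), with between-subject SDs 0.07 and 0.11 — the group summaries the
  generator is asked to emulate. Pathway offsets plant the four group
  differences the analysis is designed to detect: -0.10 on
  DLPFC(R)~mPFC(R), -0.08 on DLPFC(R)~TL(L) and DLPFC(L)~TL(L), +0.18 on
  DLPFC(L)~TL(R) (MDD side); the base level is renormalised so the group
  mean stays on target. The offset magnitudes were sized by an a-priori
  power analysis: with feature estimation noise of ~0.14-0.17 z units on a
  150-s band-limited recording, between-subject feature SDs are ~0.19-0.21,
  and detecting a difference with 80% power at an effective BH threshold of
  ~0.02 at n = 80/group needs a gap of at least ~0.095; the positive
  pathway must additionally overcome the opposite-signed base group gap of
  0.07, hence its larger offset.
* **Measurement chain.** Channels carry their ROI latent plus a global
  systemic waveform (cardiac ~1 Hz, respiratory ~0.3 Hz, Mayer ~0.1 Hz
  sinusoids with jittered frequency, channel-specific gain), consistent
  with systemic physiology being body-wide rather than channel-local. Oxy
  and deoxy traces follow the two-compartment ratios (-0.6 functional, +1
  systemic), go through the forward Beer-Lambert model to dual-wavelength
  optical density, and receive white measurement noise (SD 2e-3 OD) plus
  motion artifacts: single-sample spikes of +/-8 channel SDs (0.5 per
  minute) and step shifts of +/-4 SDs (0.2 per minute), logged with onsets.
  A 10-s artifact-free baseline intensity segment is prepended; six
  peripheral channels (1, 10, 12, 20, 22, 31) are generated with ~34 dB
  baselines so the default cohort exercises the channel-exclusion path,
  the rest sit near 50 dB. The study design reports no raw-signal summary
  statistics, so these noise levels are free parameters of the simulation,
  chosen once at values that give realistic post-filter signal-to-noise,
  and documented here.
* **Clinical table.** Ages 12-18, ~45% male, school years ~8.6 +/- 1.7,
  log-normal illness duration, medication sampled from the five drugs of
  the equivalence table at plausible doses (clinical group only). Symptom
  scores follow per-group marginals (clinical group: DASS-D 16.12 +/- 1.93,
  DASS-A 11.43 +/- 4.16, DASS-S 11.22 +/- 5.77, SHAPS 33.07 +/- 7.37;
  controls in the healthy range) and are rounded and clipped to instrument
  ranges. Planted symptom links use a Gaussian copula on feature ranks
  (copula correlation `2 sin(pi r / 6)`), which controls the target
  Spearman correlation exactly in expectation: DASS-D -0.48 and DASS-A
  -0.51 on the static DLPFC(R)~mPFC(R) feature, SHAPS -0.52 on the
  PC3 DLPFC(L)~TL(L) feature.
* **Anchoring.** The correlations this design reports are between
  *measured* connectivity features and scores, so by default the copula is
  anchored on the features the standard extraction computes from the
  generated recordings (`anchor = "measured"`); the pipeline then recovers
  the planted Spearman values up to copula discretization and sampling
  noise. Anchoring on the noise-free latent features instead
  (`anchor = "latent"`) is available; recovery is then attenuated by the
  measurement chain (by a factor of roughly 0.7 at the default noise
  settings), which is itself informative about how much of a true
  latent-level association survives a 150-s recording.

What the generator does **not** emulate: photon transport and anatomy,
task-locked hemodynamic response shapes (latents are stationary processes,
so activation-style analyses would find nothing), non-sinusoidal
physiology, serial artifacts such as probe decoupling, and real
between-site variability. Passing the recovery tests therefore demonstrates
that the analysis machinery is correct and calibrated under its own
assumptions, not that the original clinical findings replicate.

# Numerical choices and degenerate inputs

* Fisher transform clips `|r|` at `1 - 1e-7`; constant traces inside a
  window or the full period are hard errors naming the ROI.
* PCA uses SVD of the centered matrix; eigenvalues below numerical rank are
  exactly zero and the orthonormal basis is completed by QR.
* The band-pass refuses corners outside (0, Nyquist); the wavelet step
  refuses signals shorter than one filter support; detail levels with zero
  MAD are left untouched.
* SNR of a zero-variance baseline is `+Inf` (passes); a non-positive
  baseline mean yields an undefined SNR that is flagged and excluded rather
  than silently dropped.
* All randomness flows from explicit integer seeds: participant-level
  generator streams are deterministic functions of `(seed, index)`, and the
  classifier derives one seed per fold, so identical seeds reproduce every
  artifact bit for bit (asserted in the tests).

# Problem sizes used in the validation suite

The packaged tests validate parameter recovery at the design's stated size,
n = 80 per group, over 20 simulated cohorts for pathway power and 10 for
null calibration; Spearman-link recovery uses three cohorts of n = 83
clinical participants; the classifier check uses one default cohort with
the reduced grid and five fold/forest seeds. Unit tests run on cohorts of
4-12 participants. These sizes are the package's validation design; the
generator and pipeline accept any cohort size.

# Known limitations

* The wavelet tail-zeroing correction attenuates Gaussian-like signal
  (roughly 15-20% in recovered z at the defaults), so pipeline-recovered
  group means sit below the latent targets (about 0.30/0.25 against
  0.39/0.32) while group *differences* and rank structure are preserved;
  this is a property of the published algorithm family, kept faithfully.
* Single-pair Fisher-z estimates from a 150-s band-limited recording carry
  ~0.14 z of sampling noise — more than the planted between-subject SD —
  which bounds how well any latent-level association can be recovered and
  motivates the measured-feature anchoring above.
* Per-participant PCA axes are only comparable across participants up to
  the sign convention and the stability of each cohort's window-covariance
  structure; this assumption is inherited from the method being
  implemented.
* The deoxyhemoglobin signal is carried through preprocessing (the
  separation step needs it) but no deoxy-based analysis is provided.
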