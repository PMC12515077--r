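---
title: "EEG-informed fMRI analysis of sensorimotor alpha-BOLD coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG-informed fMRI analysis of sensorimotor alpha-BOLD coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During executed and imagined hand movements the sensorimotor mu/alpha
rhythm (8–13.5 Hz over C3 and C4) desynchronizes contralaterally to the
moving hand, while the BOLD signal in the same cortex rises. `alphabold`
implements a pipeline that links the two modalities *without giving the
fMRI model any task timings or electrode geometry*: the continuous alpha
power at C3 and C4 is itself turned into hemodynamic regressors, and
lateralized t-contrasts between the C3- and C4-derived coefficients
recover which hemisphere a task engaged. A conventional block (boxcar)
analysis of the same data provides the reference maps, and Dice,
precision and recall quantify their agreement.

Because the human recordings are not redistributable at desk scale, the
package ships a synthetic generator that encodes the same assumptions the
analysis makes, so every stage is testable end to end.

## The paradigm

Runs alternate rest blocks (16 s) with task blocks (22 s). A task block
is 2 s of written instruction followed by four 3 s trials, each with a
2 s inter-trial interval: 2 + 4×(3+2) = 22 s. The four task conditions
are left/right-hand motor execution (`ME_LH`, `ME_RH`) and motor imagery
(`MI_LH`, `MI_RH`); block order is randomized with execution always
preceding imagery for the same hand, and runs are padded with trailing
rest to a whole number of TRs (TR = 2 s).

## EEG feature extraction

The trial pipeline mirrors standard practice:

1. zero-phase Butterworth band-pass, 0.2–40 Hz;
2. epoching from 2 s before trial onset to 1 s after trial end
   (half-open sample windows, `floor(t × rate)` indexing);
3. rejection of trials whose within-epoch channel SD strictly exceeds
   100 µV;
4. Morlet time-frequency decomposition, 1–40 Hz in 0.5 Hz steps, 7
   cycles per frequency (a common default whose ~0.9 s support at 8 Hz
   is compatible with the baseline window), unit-energy wavelets, edge
   samples inside the wavelet support flagged invalid;
5. event-related desynchronization
   `ERD(t,f,c) = (P(t,f,c) − R(f,c)) / R(f,c) × 100 %`, with the
   baseline spectrum `R` taken per trial from the 1 s to 0.1 s window
   before onset (the epoch's 2 s pre-trial span exists precisely to host
   it; a cross-trial baseline average is a documented switch away);
6. the trial alpha ERD: the unweighted mean over the 8–13.5 Hz bins
   (12 bins) and the valid samples from 0.5 s after onset to trial end.
   The cross-modal analysis uses the high-alpha band (10.5–13.5 Hz, 7
   bins) instead — the two bands are deliberately separate constants.

## EEG-informed regressors

The continuous alpha power of C3 and C4 (same Morlet estimator, averaged
over the band, edge samples filled with the nearest valid value, bad
trial spans replaced by the mean of same-condition good trials) is

1. masked by condition: block-wide square waves for ME, MI and REST
   (instruction and inter-trial intervals belong to their block), so the
   three masked series partition the original sample-for-sample;
2. convolved causally with the canonical double-gamma HRF
   (`g(t; 6, 1) − g(t; 16, 1)/6` on [0, 32] s, peak scaled to 1 — the
   kernel "canonical" denotes in SPM-style pipelines);
3. resampled to the TR grid by within-TR averaging (anti-aliasing;
   point sampling is available as an option);
4. high-pass filtered by residualizing against the discrete-cosine basis
   with periods above 128 s, then mean-centered. Columns are *not*
   variance-normalized: the C3/C4 comparison relies on both being in the
   same µV²-derived units.

Per scan this yields six labeled columns (C3/C4 × ME/MI/REST). The
fixed-effects group design concatenates scans: EEG columns are shared,
six motion parameters and an intercept enter per scan. The rest column
is a covariate only; no contrast touches it.

## GLM, contrasts, clusters

Mass-univariate OLS per voxel, independent homoscedastic errors. The
contrast `"C3<C4-ME"` puts +1 on `C4-ME` and −1 on `C3-ME`: positive t
marks voxels whose BOLD covaries more negatively with C3 alpha than with
C4 alpha, i.e. right-hand-related cortex under C3. Maps are thresholded
at one-sided p < 0.001 and cleaned with an extent threshold (default
k = 10 voxels; a user parameter, since the random-field-theory "expected
voxels per cluster" is out of scope) under 18-connectivity, the SPM
convention. All reported contrasts are directional, so one-sided tests
are used throughout.

No autocorrelation correction is applied by default, matching the
model's stated error assumptions; an optional single-pass
Cochrane–Orcutt AR(1) prewhitening sits behind `prewhiten = TRUE`.
Because OLS under AR(1) noise mildly inflates t, the null-calibration
check uses white noise; with the default AR coefficient (0.3) the
voxelwise p < 0.001 exceedance roughly triples, which the extent
threshold absorbs in practice.

The conventional reference analysis (`block_design()`) uses one boxcar
per task condition convolved with the same HRF, the same high-pass, and
the same motion/intercept layout. A second-level random-effects model
(`second_level()`) regresses per-subject contrast values on an intercept
plus mean-centered covariates (age, sex, handedness) and returns the
intercept t map.

## Validation metrics

Binarized map agreement is quantified with TP/FP/FN counts and
Dice = 2TP/(2TP+FP+FN), precision = TP/(TP+FP), recall = TP/(TP+FN).
Undefined ratios (empty denominators) surface as `NA`, never as zeros,
so aggregation cannot silently bias. Dice is algebraically the harmonic
mean of precision and recall — the package asserts this identity to
1e-12 on every report, and uses it to recover the reported Dice values
(0.25/0.30/0.04) from the reported precision/recall pairs. Subject
screening keeps subjects whose mean precision over the two lateralized
imagery maps strictly exceeds 15 % (screening maps are voxel-thresholded
without the extent rule; configurable). Head motion is summarized by
Power-style framewise displacement (sum of absolute backward differences,
rotations × 50 mm) — the convention is cited by reference in the
literature this mirrors; subjects are excluded when mean FD exceeds the
group mean by more than 3 group SDs, one reading of an ambiguous verbal
rule, kept configurable.

## The synthetic generator

`simulate_eeg()` gives each channel a 10 Hz carrier with an
amplitude-modulated envelope plus 1/f background noise (default 2 µV
against a 10 µV carrier — low, so that planted effect sizes are
recoverable from desk-scale trial counts). Right-hand conditions
modulate C3, left-hand C4; the ipsilateral channel receives a 0.4
fraction of the contralateral ERD (present-but-weaker ipsilateral
desynchronization is an assumption, exposed as a parameter).
Instruction and inter-trial periods carry the block's modulation at half
depth; trial amplitude is scaled by `sqrt(1 + e/100)` *relative to that
level*, so the measured trial-versus-pre-trial-baseline power change
equals the planted `e` exactly (power is quadratic in amplitude) while a
block-level envelope still exists. Default planted depths use the
imagery values around −16 to −19 % and deeper execution ERD (−25 %;
execution depth is a package choice, as only imagery depths are
reported).

`simulate_bold()` plants neurovascular coupling on a 20×20×12 grid of
2 mm voxels: voxels in each electrode×condition mask receive
`weight × (condition-masked, HRF-convolved, TR-averaged alpha power)`,
plus AR(1) noise (φ = 0.3), slow cosine drift (periods ≥ 200 s, so the
128 s high-pass is genuinely exercised), and a small motion-correlated
nuisance; motion itself is a smoothed random walk. With the default
scales (baseline 32000, noise SD 150, weight −0.5 on the µV²-scale
regressor) a coupled voxel's task response is ~1.5 % of baseline against
~0.5 % noise — a strongly responding sensorimotor voxel. C3 and C4
masks are disjoint left/right-hemisphere blobs.

What the generator does *not* emulate: head-model forward projection,
line noise, gradient/ballistocardiogram artifacts, physiological
(cardiac/respiratory) noise, multi-band acquisition physics, or spatial
preprocessing needs (volumes are born aligned). Passing tests therefore
demonstrate the correctness and internal consistency of the analysis
chain under its own assumptions, not robustness to real-data artifacts.

## Numerical choices and degenerate inputs

* Epoch windows are half-open `[start, end)`; sample index
  `floor(t × rate)` — no boundary double-counting.
* Trial rejection uses strict `>` at 100 µV ("exceeding").
* Voxels whose residual variance is numerically zero (pure
  floating-point noise) yield `NA` t values rather than huge finite
  ones.
* The precision screen uses strict `>` at 15 %; a subject at exactly
  15 % is excluded.
* Empty cluster tables, empty trial sets and all-`NA` maps are returned
  as empty/flagged objects, not errors.
* One master seed; per-subject seeds derive as master + index.

## Scale of the shipped checks

The test-suite and acceptance-script problem sizes are the package's
choices for a desk-scale demonstration: cohorts of 6 subjects × 400
volumes for lateralization recovery, 10⁶ voxel-draws for null
calibration, ≥40 trials per planted ERD depth, and 100 Monte-Carlo
cohorts of 17 subjects for the cross-modal sign check.

## Design notes on genuinely open points

* **Per-trial baseline.** "Average baseline power" is read per trial;
  a pooled-across-trials baseline is available as a switch.
* **Imputation order.** Bad-trial imputation operates on the
  band-averaged power series (after band-averaging, not before).
* **Cross-modal first-level statistic.** For the synthetic cohorts the
  ROI statistic is the single-condition task response tested in its
  modeled direction. Under the generator's forward model (BOLD a linear
  function of *condition-masked* alpha power) the lateralized
  difference contrast is scale-free at desk scale — the planted
  signal's intra-block structure dominates both the contrast and the
  residual, so its t saturates to a layout-dependent constant — whereas
  the task-response t grows with coupling strength and yields the
  expected negative ERD–BOLD correlation across subjects (deeper
  desynchronization, stronger response).
* **22 s block hemodynamics.** The convolved response to a 22 s block
  peaks ~10–12 s after block onset (dense-grid evaluation); the familiar
  5–6 s peak lag applies to brief events only.
* **Pooling.** The cross-modal regression concatenates the two imagery
  tasks' samples; with one task per synthetic subject a cohort
  contributes 17 samples.

## Limitations

Fixed-effects pooling treats subjects as fixed; the per-scan
lateralization information is limited, so single-subject EEG-informed
maps are noisy and the group concatenation carries the inference.
Random-field cluster FWE, atlas labeling and spatial normalization are
out of scope; the extent threshold is a heuristic stand-in and a
permutation option is the principled alternative at this scale.
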