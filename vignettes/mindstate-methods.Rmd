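---
title: "Methods: synthetic SART sessions and mind-state markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic SART sessions and mind-state markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mindstate)
```

## Scope

`mindstate` implements an end-to-end analysis of ongoing mind states —
on-task (ON), mind wandering (MW) and mind blanking (MB) — from EEG
recorded during a sustained attention to response task (SART) with
experience-sampling probes. Because real high-density recordings are large
and not redistributable, the package ships a synthetic session generator
with planted, parameterized state signatures; every analysis stage is
exercised and validated against the generator's ground truth. The analysis
stages themselves are agnostic about where the data came from: epoched EEG
plus event/probe tables in the package's tabular formats run through the
same code paths.

## The task model

A session consists of `n_blocks` blocks (default 6). Stimuli (faces or
digits, mixed at random within block) follow each other with a stimulus
onset asynchrony drawn uniformly from 750–1250 ms and a null
inter-stimulus interval; one stimulus in nine is a No-Go target. Probes
interrupt the task at uniform random intervals of 40–70 s; the response
records the participant's mind state (ON / MW / MB / "don't remember",
the last merged into MB by every downstream stage) and a 1–4 vigilance
rating. Trials up to 5 s before a probe inherit the probe's state
("5-second rule", boundary inclusive); all other trials are unlabeled.

One deliberate simplification: the original task presented faces and
digits in separate blocks. The generator mixes both categories within each
block so that face-vs-digit decoding cannot be confounded with block
identity, which matters at desk scale where a session has only six blocks.

## The latent-state schedule

States follow a semi-Markov schedule: dwell times are exponential with
mean `state_dwell` (default 30 s, truncated at block boundaries), and each
switch moves to one of the other two states with equal probability. The
default dwell is far above the 5-s labeling window, so within a labeling
window the state is effectively constant; the labeling-agreement test
(≥ 99% of labeled trials match generator truth) depends on this
separation and is the reason `state_dwell` should not be pushed below
~15 s without revisiting the labeling rule.

Probe answers equal the latent state at probe onset exactly by default.
`report_noise` can corrupt a fraction of answers (and is the only way
"don't remember" answers arise); it defaults to 0 because the acceptance
surface needs recoverable ground truth.

## The signal model

The EEG of each channel is a sum of:

* a 1/f background (power ∝ 1/f over 1–45 Hz, RMS `bg_amp` = 5 µV);
* five band-limited Gaussian oscillations (delta 1–4, theta 4–8, alpha
  8–12, beta 12–30, gamma 30–45 Hz) with base RMS amplitudes (4, 3, 3, 2,
  1.5) µV, each scaled per state and per channel row by the square root of
  `band_power_map` — this matrix is where the spatial state signatures
  live;
* additive raised-cosine ERP templates per stimulus;
* shared-source coupling on three designated fronto-parietal channel
  pairs;
* white sensor noise (`noise_sd` = 2 µV).

The 32 channels sit in four anterior-to-posterior rows (frontal, central,
parietal, occipital) of eight; rows, not individual electrodes, carry the
planted gradients. This stands in for a high-density montage at desk
scale.

### Planted state signatures

Relative oscillatory power per state (selected multipliers of the common
base):

* **ON** — posterior alpha suppressed (0.45–0.95 across rows): the
  task-engagement signature. Full central P3b (4.5 µV, 400–650 ms),
  strong early (~200 ms, 4 µV) and late (0.35–0.65 s, 3 µV)
  category-dependent responses.
* **MW** — theta increased globally (×1.6), posterior alpha increased
  (up to ×1.6), fast activity (beta/gamma) decreased frontally (×0.5) and
  increased centro-posteriorly (×1.2–1.35), frontal delta up. P3b
  reduced and delayed (1.5 µV at 500 ms, shorter), late category
  response weak (1.4 µV) and shorter (0.40–0.55 s).
* **MB** — fast activity increased frontally (×1.8) and decreased
  posteriorly (×0.4–0.5), posterior delta up (×1.5). No P3b, no
  category-dependent response.

The MB-vs-MW contrast of the fast-power fraction is therefore positive on
frontal rows and negative on posterior rows (the front-back dissociation),
and sample entropy / compression complexity follow the same gradient
because they track relative fast power. Effect sizes were fixed once, at
values that make every stage recoverable from a single desk-scale session;
they are larger than what small real cohorts show, which is the standard
trade-off for a generator that must support property-based validation with
20 seeds rather than 62 participants.

### Coupling and the PLV/wSMI dissociation

Two independent alpha-band sources per planted pair:

* the **linear** source is added to both channels at zero lag with
  strength `linear_coupling` — this is volume-conduction-like mixing: it
  aligns phases (high PLV) but produces identical rank patterns, which
  wSMI's weighting deliberately discards;
* the **nonlinear** source is added to one channel as-is and to the other
  after a quarter-cycle lag (25 ms) and a rank-preserving cubic
  distortion, with strength `nonlinear_coupling` — a lagged, monotone-
  distorted dependence that symbolic mutual information detects but that
  contributes much less phase alignment.

MB plants strong linear and nearly no nonlinear coupling (0.85 / 0.05); ON
the reverse (0.10 / 0.60); MW sits between. This is the mechanism behind
the planted "phase synchrony up, information sharing down" pattern in MB.

### Behavior

Responses are drawn per stimulus from the latent state's parameters
(log-normal RTs; median/spread in ms): ON misses 4%, false alarms 20%,
RT 520; MW 8%, 52%, 440; MB 20%, 40%, 640. The orderings (misses MB > MW >
ON; RT MB slowest, MW fastest; FA MW highest) mirror the reported "absent"
MB and "impulsive" MW profiles; the magnitudes are at the upper end of the
plausible range so that the predicted-state validation remains decidable
on a few hundred predicted trials.

## Analysis conventions

* **Windows** are half-open `[lo, hi)` in seconds; a window of `w` seconds
  spans `round(w · fs)` samples. The 5-s labeling boundary is inclusive.
* **Response ownership** (null-ISI design): a response belongs to the
  nearest preceding stimulus within 1250 ms (the maximum SOA), and is
  consumed once.
* **Welch PSD**: mean-detrended Hann segments, 50% overlap; 1-s segments
  on 5-s pre-probe epochs, 0.5-s segments on 1-s stimulus epochs (at least
  three segments per epoch, delta band keeps at least one bin).
  Normalized band power divides by the integral over the union of the five
  bands (which tile 1–45 Hz).
* **Sample entropy**: m = 2, r = 0.2·SD, Chebyshev distance, self-matches
  excluded, templates for both lengths taken at 1…n−m. Degenerate inputs
  (no matches) return `NA`, which downstream stages treat as a flagged
  sentinel and exclude rather than impute.
* **Compression complexity**: binarize at the median, pack to bytes,
  gzip (DEFLATE); the ratio compressed/packed bytes.
* **Symbolic transform**: k = 3 rank patterns with lag
  τ = max(1, round(fs/(3·f_hi))) per band (alpha: 7 samples at 250 Hz);
  ties break earlier-index-smaller; the six patterns are indexed in
  lexicographic order of their rank vectors, and "opposite" means the
  rank-reversed pattern (index 7 − i). wSMI weights identical and opposite
  pairs at zero and normalizes by ln 6; probabilities are maximum-
  likelihood histograms without smoothing; degenerate inputs give 0.
* **Filtering**: zero-phase FIR band-pass (Hamming design via `fir1`,
  order three cycles of the band's low edge, capped to a third of the
  series), reflection padding. For 1-s stimulus epochs (too short for a
  delta-band FIR) the connectivity features rely on τ-selection alone,
  without band-pass.
* **PLV**: analytic-signal phases, 10% of samples trimmed at each edge.
  Note the null level of PLV depends on bandwidth: narrowband filtering
  shrinks the effective sample count, so null checks against white noise
  use a broadband (1–45 Hz) phase extraction.
* **ERP contrasts / marker topographies**: two-stage scheme — with
  multiple subjects, subject-level means then a paired test across
  subjects (paired t for ≥ 15 subjects, Wilcoxon signed-rank below);
  with one subject, Welch t over trials. This is a deliberate,
  dependency-light surrogate for the mixed models used with real cohorts;
  the contrast structure (effect sign, per-node FDR mask) is preserved,
  while random-effect shrinkage is not. BH-FDR is applied per contrast,
  jointly over channels × timepoints for ERPs and over nodes for marker
  maps.
* **Temporal decoding**: per-timepoint ridge classifier (per-sample
  penalty λ = 1) on within-fold standardized channel amplitudes,
  stratified 5-fold CV, pooled held-out scores, rank-statistic AUC. The
  permutation null re-runs the identical CV with shuffled labels (folds
  and label-free standardization fixed), then per-timepoint add-one
  p-values and BH-FDR across timepoints. A ridge read-out makes the
  permutation null affordable because the projector depends on the data
  only; this is exactly equivalent to re-fitting per permutation.
* **State classifier**: features are the per-channel markers, row-pair
  wSMI per band and windowed ERP amplitudes
  ([0.08, 0.15], [0.15, 0.35], [0.35, 0.7] s); leave-one-block-out CV;
  per fold the pipeline imputes (training medians), standardizes, reduces
  dimension and fits a 300-tree random forest with class-balanced
  per-tree sampling (each tree bootstraps equal counts per class — with
  probe-sampled labels the class counts are often very unbalanced and
  Gini-level weights alone leave minority states without vote share).
  Balanced accuracy is the mean per-class recall over pooled held-out
  trials. The permutation null shuffles labels across labeled trials and
  re-runs the CV; the unsupervised pipeline stages are label-free, so
  their per-fold fits are computed once and reused exactly.

### Dimensionality reduction

The default reduction is linear PCA on standardized features, keeping
components up to 95% cumulative variance but at most 25. Radial-basis
kernel PCA (width from the median pairwise squared-distance heuristic) is
available via `method = "kpca"`. Both were evaluated on synthetic
sessions: with ~100 labeled trials per session, RBF kernel PCA measurably
degraded block-grouped recovery relative to linear PCA, and uncapped
component counts (≈ n−1 components at 95% kernel variance) diluted the
forest with noise directions; the capped linear default recovered the
planted states best. Kernel PCA remains the right choice when trial counts
are an order of magnitude larger.

## Problem sizes

The validation suite and the acceptance script use: single-state sessions
of 1 block × 240 s for marker, connectivity and decoding recovery (20
seeds each); classifier cohorts of synthetic subjects with 6 blocks ×
180 s, 100-permutation chance levels, and ~400 predicted unlabeled trials
per subject (all unlabeled No-Go trials plus 300 Go trials, so that
false-alarm comparisons rest on enough No-Go trials). Decoding
significance uses 500 permutations: BH across m ≈ 84 timepoints can only
flag a set of k timepoints if the attainable per-timepoint p (the add-one
floor 1/(n_perm+1)) is below 0.05·k/m, and with 100 permutations the
floor of 1/101 cannot survive the correction unless a third of all
timepoints is truly significant. Six blocks per subject matter for the
classifier: with fewer (or shorter) blocks, each block contains probes
from only one or two states, the leave-one-block-out folds become
label-degenerate, and cross-validated accuracy drops below chance — an
instructive failure mode of grouped cross-validation with clustered
labels rather than a bug.

## What passing tests do and do not show

The generator emulates: state-dependent band-power topographies, complexity
gradients, linear-vs-nonlinear long-range coupling, ERP components with
state-dependent late responses, category-selective response patterns,
state-dependent behavior, and the SART/probe timing statistics. It does not
emulate volume conduction from cortical sources, eye/muscle artifacts,
non-stationary drowsiness drift, inter-subject variability in electrode
positions, report noise or bias, or realistic class imbalance (states are
uniform at 1/3 each). Passing recovery tests therefore demonstrates that
the implementations measure what they claim to measure and that the
pipeline is leakage-free and statistically calibrated — not that real
recordings would yield effects of this size.

## Known limitations

* The ROI stage consumes source-space signals; no EEG inverse modeling is
  provided, so cortical source maps of stimulus-evoked activity are out of
  scope by design.
* Mixed-effects group models are approximated by the two-stage scheme
  described above; an external mixed-model backend can be slotted in at
  the `*_state_contrast` surfaces.
* The single-subject bootstrap for behavioral contrasts is approximate for
  rates based on very few No-Go trials.
* `signal_params` carries category-response fields (`cat_early_amp`,
  `cat_late_amp`, `cat_late_window`) that have no analogue in a
  state-marker-only description of the task; they exist because category
  decoding is undecidable unless the generator plants category
  information.
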