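# mindstate

EEG and behavioral signatures of ongoing mind states — on-task (ON), mind
wandering (MW) and mind blanking (MB) — in a sustained attention to
response task (SART) with experience-sampling probes.

During a SART, participants respond to frequent Go stimuli (faces or
digits) and withhold to rare No-Go targets (1 in 9), while probes every
40–70 s ask what their mind was doing "just before". `mindstate` is for
researchers who want to analyse such sessions end to end, or to prototype
and validate the analysis before touching real data:

* **state markers** from the 5 s preceding each probe: normalized band
  power (δ/θ/α/β/γ), sample entropy (SampEn), compression-based
  Kolmogorov complexity (KC), weighted symbolic mutual information (wSMI)
  and phase-locking value (PLV) per band, with ROI-pair aggregation for
  source-space signals;
* **stimulus-evoked analyses**: single-trial ERP contrasts between states
  and per-timepoint decoding of stimulus category with a permutation
  chance level;
* **behavior**: misses, false alarms and reaction times per state with
  FDR-corrected pairwise contrasts;
* **trial-by-trial mind-state prediction** from the combined marker set
  (block-grouped cross-validation, permutation null, prediction of
  unlabeled trials, behavioral validation);
* a **synthetic SART-session generator** with planted, parameterized state
  signatures, so all of the above is testable without any data download.

## The core quantities

For two band-passed signals symbolized into rank patterns
(k = 3, lag τ per band),

wSMI(X,Y) = (1/ln 6) Σᵢⱼ w(i,j) p(i,j) ln[ p(i,j) / (p(i)p(j)) ],

with w = 0 for identical and rank-reversed pattern pairs (the pairs volume
conduction produces for free) and w = 1 otherwise, and

PLV(X,Y) = | ⟨ exp(i·(φX(t) − φY(t))) ⟩ₜ |.

SampEn = −ln(A/B), the negative log conditional probability that two
length-2 templates within Chebyshev distance r = 0.2·SD remain within r at
length 3. KC is the gzip compression ratio of the median-binarized
signal. Trials up to 5 s before a probe inherit the probe's reported
state; a 300-tree random forest on PCA-reduced marker features, cross-
validated by experimental block, predicts the state of every other trial.

## A worked example

```r
library(mindstate)

cfg <- session_config(n_blocks = 2, block_duration = 120, seed = 7)
rec <- generate_session(cfg)
rec
#> <mind_recording> 32 ch x 60000 samples @ 250 Hz (4.0 min), 239 stimuli, 3 probes

pre <- epoch_preprobe(rec)               # one 5-s epoch per probe
mk  <- compute_marker_matrix(pre)        # trials x channels x 7 markers
round(colMeans(mk$values[, , "psd_alpha"])[row_channels(rec$channels, "occipital")], 3)
#> O1 .. O8 alpha fractions:
#> 0.191 0.147 0.192 0.225 0.179 0.150 0.211 0.159

stim <- label_trials(baseline_correct(epoch_stimuli(rec)), rec$probes)
table(stim$metadata$state_label)
#>        MW        ON unlabeled
#>         4        10       225
```

The three probes (two ON, one MW) label 14 trials; everything else is
unlabeled and would be predicted by `run_state_classification()` on a
full-length session (six blocks), which returns the cross-validated
balanced accuracy, its permutation chance level, per-trial predictions
and the behavioral validation of the predicted states:

```r
rec <- generate_session(session_config(seed = 1, n_blocks = 6,
                                       block_duration = 180))
out <- run_state_classification(rec, seed = 1, n_perm = 100)
round(out$fit$balanced_accuracy, 3)   # 0.841 (3-class chance = 1/3)
round(median(out$chance$null), 3)     # 0.329
out$validation$ordering
#> mb_most_misses  mb_slowest_rt     mw_most_fa
#>           TRUE           TRUE           TRUE
```

The classifier recovers the latent state well above its permutation chance
level, and the behavior of the predicted (unprobed) trials reproduces the
planted profile: most misses and slowest responses in predicted mind
blanking, most false alarms in predicted mind wandering. Numbers are from
the exact seeds shown; they vary with the seed.

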