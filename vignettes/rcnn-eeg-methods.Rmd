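---
title: "Recognizing epileptic EEG states with a residual 1-D CNN + indRNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing epileptic EEG states with a residual 1-D CNN + indRNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcnneeg)
```

## The problem

Clinical review of long scalp EEG recordings for epileptic activity is slow
and subjective. `rcnneeg` implements an automatic recognizer for
single-channel EEG: a continuous recording is cut into fixed 10-second
windows and every window is assigned a brain-state class — `normal`,
`interictal` (between seizures), `preictal` (approaching a seizure) or
`ictal` (during a seizure), depending on the task. Two task families are
supported:

* **benchmark-style**: short single-class records (the public five-group
  benchmark convention: 100 plain-text series of 23.6 s per group at
  173.61 Hz), two-class (non-epileptic vs seizure) and three-class
  (normal / interictal / ictal) designs;
* **clinical-style**: long annotated recordings at 500 Hz, with classes
  derived from expert seizure onset/offset annotations, two-class
  (preictal vs ictal) and three-class (interictal / preictal / ictal)
  designs.

## From annotations to labels

Seizure annotations are `(onset_s, offset_s)` intervals. Labeling follows
fixed clinical-convention rules, all exposed in `period_params()`:

| parameter | default | meaning |
|---|---|---|
| `merge_gap_min` | 30 | seizures closer than this to the previous offset are one seizure |
| `preictal_lead_min` / `preictal_len_min` | 35 / 30 | preictal = the earliest 30 min of the 35 min before onset |
| `post_offset_clear_min` | 60 | interictal must be at least 1 h past the previous offset |
| `pre_onset_clear_min` | 40 | interictal must end at least 40 min before the next onset |
| `window_s` | 10 | analysis window length (seconds) |

`merge_seizures()` applies the merge rule transitively (measured
offset-to-onset); `derive_periods()` then partitions the record into
`preictal`, `ictal`, `interictal` and `excluded` interval sets — the four
sets are disjoint and cover the record, which the test suite verifies
against a brute-force per-second classifier. Everything that is neither
ictal, preictal nor cleared interictal time (postictal recovery, guard
gaps) is `excluded`. The 5-minute gap immediately before onset is left out
of the preictal segment deliberately: a prediction horizon gap is standard
in seizure-prediction labeling, and the source convention places the
"30 min of pre-onset data" inside the 35 min before the attack.

Two readings of that convention were genuinely open. The interictal
clearance is stated as "at least 1 h after seizure and at least 40 min
after seizure", which is internally inconsistent; we read the second
clause as *before the next onset*, giving an asymmetric 60 min / 40 min
guard. And the merge gap is measured offset-to-onset (the time the brain
has actually been out of seizure), not onset-to-onset.

`label_windows()` labels a window only when it lies entirely inside one
interval; windows straddling boundaries are dropped rather than
majority-voted, avoiding label noise at state transitions.
`balance_classes()` undersamples every class to the minority count with a
seeded RNG — the class-imbalance handling used throughout (e.g. 400
non-epileptic vs 100 seizure records in the benchmark two-class design).

## The synthetic generator

Real clinical recordings cannot be redistributed, so `synth_spec()` /
`gen_class_record()` generate seeded single-channel EEG with class-distinct
structure:

* **normal** — 1/f ("pink") background noise (RMS 20 µV) plus a 10 Hz alpha
  rhythm (10 µV amplitude);
* **interictal** — background plus Poisson-timed biphasic spikes
  (0.5 events/s, 70 ms, amplitude 5 × background RMS);
* **preictal** — background with alpha power reduced 30% and twice the
  interictal spike rate;
* **ictal** — background plus a continuous 3 Hz spike-wave train at
  5 × background RMS.

These are caricatures tuned for testability: the spectral slope, spike
rate and class contrasts are realistic in scale, but real EEG has
non-stationary artifacts (EMG bursts, eye blinks, electrode pops),
patient-specific morphology and far weaker class contrasts. Passing the
end-to-end tests therefore shows that the pipeline and optimizer work —
that separable structure in the input reaches the decision layer — not
that clinical-grade accuracy is attained on hospital data. A trivial 3 Hz
band-power threshold separates synthetic ictal from normal exactly (a
property the test suite asserts), which is what makes the end-to-end
learning check well-posed.

`gen_clinical_session()` lays the textures out along a timeline consistent
with the labeling rules above and returns the record, the annotation table
and the ground-truth texture timeline, so the annotation-to-label pipeline
can be validated end to end.

## The network

`architecture_spec()` describes the classifier; `build_rcnn()` instantiates
it. The default mirrors the reference design:

```
input (L samples, 1 channel)
BLOCK1  Conv1D(64, k=8, s=1)+BN+LeakyReLU
        Conv1D(64, k=5, s=2)+BN+LeakyReLU
        Conv1D(64, k=3, s=1)+BN
        shortcut Conv1D(64, k=1, s=2)+BN ; Add ; LeakyReLU
BLOCK2  same with 128 filters
BLOCK3  same with 64 filters
AveragePooling1D(width 2)
indRNN(128)+BN
indRNN(128)+BN
Dense(256)+LeakyReLU
Softmax(n_class)
```

With "same" padding and one stride-2 stage per block the time axis follows
`L -> ceil(L/8)`, then halves under pooling; a 10-s window at 500 Hz
(5000 samples) reaches the recurrent stage as a 312-step sequence of
64-channel feature vectors.

Design choices that the source description left open:

* **Shortcut strides.** The layer table lists stride 2 on each block's
  middle convolution but stride 1 on the kernel-1 shortcut, which cannot
  type-check at the Add; the projection shortcut uses stride 2, the only
  shape-consistent reading.
* **Block 3 shortcut.** Block 3 has no kernel-1 row in the table, but its
  channel count changes 128 to 64, so an identity add is impossible; the
  builder inserts a kernel-1 projection whenever channels change
  (`block_spec(projection_shortcut = FALSE)` is honoured only when the
  identity is well-typed).
* **Pooling.** The table's `GlobalAveragePooling1D - 2 -` row is ambiguous
  (a global pooling has no size-2 parameter and would leave the recurrent
  stage a single step). Default reading: average pooling of width 2 over
  time (`pool = "avg2"`). The alternative — per-sub-segment global pooling
  feeding the recurrent stage `n_segments` pooled feature vectors — is
  available as `pool = "global"`.
* **indRNN recurrence.** The element-wise recurrence
  `h_t = relu(W x_t + u * h_{t-1} + b)` with per-unit recurrent weight `u`
  and the constraint `|u| <= u_clip = 2^(1/T)` applied after every update
  (memory can at most double over a `T`-step sequence). Batch norm after an
  indRNN layer normalizes per feature over (batch x time).
* **Recurrent initialization.** `u` starts at 1: with a ReLU recurrence
  each unit then begins as a perfect integrator, so evidence from anywhere
  in the window reaches the last hidden state, which is what the dense head
  reads. This long-memory initialization matters here: with `u` drawn from
  a wide interval, units with `|u| < 0.99` forget a 312-step sequence
  almost completely, the readout sees only the last fraction of a second,
  and the network memorizes its training windows instead of learning the
  sparse-spike feature that distinguishes interictal from normal windows —
  we observed exactly that failure (perfect training loss, depressed
  cross-validated accuracy) before fixing the initialization. Training
  remains free to shorten memory where useful.
* **Conv biases.** Every convolution is followed by batch norm, whose mean
  subtraction cancels an added constant exactly — conv biases are inert and
  their gradient through BN is identically zero. The compiled engine
  therefore skips them (they stay 0); they remain declared parameters, so
  layer parameter counts match the usual `C_in*k*F + F` arithmetic (block 1:
  33 600 weights and biases excluding BN).
* **Batch norm defaults**: momentum 0.99, epsilon 1e-3.

## Training

`train_config()` defaults to the reference recipe: SGD (learning rate 0.01,
momentum 0.9), categorical cross-entropy, batch size 64, 512 iterations.
"Iterations" is read as epochs (the idiom the vocabulary suggests);
`iterations_as = "steps"` gives the batch-step reading. Each window is
standardized to zero mean and unit variance before the network — amplitude
units differ between recording setups, and the standardization choice is
recorded in the run manifest.

Two engine details are the package's own:

* **Single-precision compiled kernels.** Forward, backward and the SGD
  update run in float32 through RcppArmadillo kernels (the convention of
  the deep-learning frameworks this reimplements), with the exported layer
  functions (`indrnn_step()`, `indrnn_forward()`,
  `residual_block_forward()`) kept as double-precision reference
  implementations; the test suite checks the two paths against each other
  and the backward pass against double-precision finite differences.
* **Batch-norm statistics calibration.** After the last epoch the running
  statistics are replaced by the exact average of per-batch statistics
  under the final weights (one forward-only sweep). Momentum-smoothed
  running averages need many hundreds of updates to forget their
  initialization; after short trainings they leave inference-mode
  normalization arbitrarily wrong even though the training loss has
  converged.

All randomness — parameter initialization, shuffling, fold assignment,
undersampling, synthetic generation — funnels through explicit integer
seeds, and identical configurations reproduce runs bit-for-bit (the
acceptance suite compares manifests and per-fold confusion matrices of
repeated runs).

## Evaluation

`evaluate()` tallies argmax predictions into a confusion matrix and
per-class one-vs-rest counts; `compute_metrics()` applies
`sen = TP/(TP+FN)`, `spe = TN/(TN+FP)`,
`acc = (TP+TN)/(TP+FN+TN+FP)`, returning `NA` plus an `undefined` flag when
a denominator is zero rather than silently reporting 0.

`cross_validate()` runs stratified k-fold cross-validation (default
k = 10) with a freshly initialized model per fold and reports per-fold and
mean metrics. Two conventions are the package's own, since the source
reports single Sen/Spe values for three-class tasks without defining them:
multi-class sensitivity and specificity are macro-averaged one-vs-rest,
and accuracy is the overall correct fraction. For binary tasks the
seizure-like class is the positive class. Folds are stratified at the
window level for the synthetic sets; for benchmark-style data whole series
should be assigned to folds (pass record-derived labels) to avoid
within-record leakage — which of the two the original experiments used is
not stated.

## Problem sizes used by the tests and acceptance script

The committed end-to-end check trains a reduced model (16/32/16 filters,
everything else as above) on 300 ten-second 500 Hz synthetic windows
(three-class, 10-fold, 30 epochs, batch 32) and on the balanced two-class
subset (n = 200), expecting mean accuracy of at least 0.95 and 0.98
respectively; the reduced budget keeps the check informative (an
unconverged or defective pipeline fails it) while staying fast enough to
run routinely. `scripts/acceptance.R` re-runs the same two experiments at 5 folds
to keep its runtime modest, and reports fold-mean Sen/Spe/Acc in percent.
Unit tests use still smaller rates (50-100 Hz) and architectures. These
sizes are the package's choices for a thorough-but-fast check; nothing in
the method depends on them.

## Known limitations

* Single channel only: no montage handling, re-referencing or multi-channel
  spatial structure.
* No artifact model beyond broadband noise; no EDF/BDF readers — records
  are plain text, one sample per line.
* The synthetic classes are far easier than clinical EEG; reported
  synthetic accuracies are pipeline checks, not clinical performance
  claims.
* The external five-group benchmark experiment
  (`run_bonn_experiment()`, `scripts/bonn_experiment.R`) requires a locally
  downloaded copy of the public dataset and is not part of the test suite.
* Training is CPU-bound single-threaded float32; the full 512-epoch recipe
  on benchmark-scale data takes hours, not minutes.
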