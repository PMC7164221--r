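---
title: "Decoding gait intention from pre-movement EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding gait intention from pre-movement EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitintent)
```

## The problem

A lower-limb brain–computer interface is only useful if it can recognize the
*intention* to start or stop walking before the movement happens: the
assistive device needs lead time to adapt. Event-related desynchronization
(ERD) — a drop in alpha (≈8–13 Hz) and beta (≈13–30 Hz) band power over the
sensorimotor cortex that begins roughly 1.5–2 s before a self-paced movement
— is detectable in single trials and therefore a candidate control signal.
`gaitintent` implements a fully predictive decoding chain for eight-channel
sensorimotor EEG (10-20 sites Cz, C3, C4, CP3, CP4, FCz, CPz, Pz) sampled at
500 Hz, framed as two balanced binary problems:

* **rest vs. start** — steady resting vs. the pre-movement window before a
  gait start;
* **walk vs. stop** — steady walking vs. the pre-termination window before a
  gait stop.

Two separate classifiers are used rather than one walk-vs-rest machine
because the informative signal lives in the short transition windows, not in
the steady states.

## The decoding chain

1. **Preprocessing** (`preprocess_session()`): downsample to 250 Hz
   (zero-phase FIR anti-aliasing before decimation), 1 Hz linear-phase FIR
   high-pass (windowed sinc, transition 0.5–1.5 Hz, group delay compensated,
   tap sum forced to zero so DC gain is exactly 0), 60 Hz second-order IIR
   notch (Q = 30, applied forward–backward), bad-channel rejection, a
   simplified artifact-subspace burst repair, and common-average
   re-referencing. A channel is rejected when it is constant for more than
   5 s or its maximum absolute Pearson correlation with every other channel
   falls below 0.7. Detection statistics are computed on the *unfiltered*
   recording: a long FIR smears a flat run over its ~3.3 s support, which
   would destroy the evidence the flat rule needs; rejection itself still
   happens at its usual position in the chain. The montage is only eight
   electrodes, so "adjacent channel" correlation is operationalized as the
   maximum over all other channels. An optional `ica_hook` receives and
   returns a session between burst repair and re-referencing, where an
   independent-component cleaning step would sit; no decomposition is
   shipped.

2. **Burst repair** (`asr_repair()`): a sliding-window principal-component
   variant of artifact subspace reconstruction. The covariance of an
   artifact-light calibration segment (default: the lowest-variance
   contiguous stretch) defines a component basis and per-component reference
   scales; 0.5 s windows with 50% overlap are projected onto that basis, and
   components whose RMS exceeds `cutoff_sd = 10` reference SDs are removed
   before raised-cosine overlap-add reconstruction. `cutoff_sd = Inf` is an
   exact pass-through. This is a deliberate simplification of toolbox ASR
   (no covariance interpolation, no per-window recalibration); it passes
   clean data essentially unchanged (<5% RMS) and removes >80% of a 50×
   burst's RMS without touching its flanks.

3. **Segmentation** (`extract_epochs()`): gait starts and stops anchor the
   positive-class epochs; walk and rest anchors are the midpoints between
   adjacent events, keeping the steady-state epochs far from any transition.
   The trailing rest interval (last stop to recording end) also contributes
   a rest anchor, so a session of *n* cycles yields *n* anchors per class.
   Epoch intervals are half-open `[onset, offset)`, so abutting windows do
   not overlap; classes are trimmed to equal size by dropping the latest
   surplus anchors, and any cross-class overlap drops the offending pair.
   Five window specifications are studied: trans-event `[-1 1]` and
   `[-1.5 0.5]`, and fully predictive `[-2 0]`, `[-1.5 0]`, `[-1 0]`
   (seconds relative to the event).

4. **Features** (`build_features()`): each epoch channel is decomposed with
   a 5-level db4 discrete wavelet transform with periodized boundaries. At
   250 Hz the level-3 details span 15.625–31.25 Hz (beta) and level-4
   details 7.8125–15.625 Hz (alpha); those two levels are reconstructed as
   band-limited signals. Each band signal is cut into 0.5 s sub-windows
   advancing by 50 ms — 11/21/31 sub-windows for 1/1.5/2 s epochs — and
   each sub-window contributes the three Hjorth parameters: activity
   (variance), mobility (SD ratio of first difference to signal, a frequency
   proxy), and complexity (mobility of the first difference divided by
   mobility, a bandwidth proxy). That gives 66/126/186 features per channel
   and 528/1008/1488 in total for eight channels. Derivatives are plain
   first differences (the dt factors cancel in the ratios) and variances are
   population variances. The complexity *ratio* definition is the default
   because it has the correct pure-sinusoid limit of 1; a
   `complexity = "literal"` switch provides the multiplicative variant,
   which reduces to `sd(diff(diff(x)))/sd(x)` and lacks that limit. A
   constant sub-window yields an explicit `NA` sentinel and flags its epoch,
   never a silent `NaN`. The 50 ms quantity is interpreted as the
   *step* between sub-window onsets (i.e. 450 ms overlap): that is the only
   reading that reproduces all three printed counts 11/21/31
   simultaneously. At 250 Hz a 50 ms step is 12.5 samples; onsets are
   rounded per window so the nominal counts hold exactly.

5. **Feature selection** (`select_features()`): features are scored by the
   absolute standardized rank-sum statistic `|z|` of a two-sample unpaired
   Wilcoxon (Mann–Whitney) test — midranks for ties, tie-corrected null SD,
   normal approximation without continuity correction. Selection is greedy:
   the first pick maximizes `|z|`; each later pick maximizes
   `|z| · (1 − ρ̄)^β`, where `ρ̄` is the mean absolute Pearson correlation
   with the features already chosen. The multiplicative penalty with β = 1
   was chosen because it has clean limits — β = 0 recovers the plain `|z|`
   top-k, and an exact duplicate of an already-selected feature scores 0
   against its twin — while matching the qualitative behaviour that highly
   correlated candidates are "less likely to be included". Twenty features
   are kept.

6. **Classification and evaluation** (`crossval()`): a cost-sensitive
   RBF-kernel soft-margin SVM with separate misclassification costs for the
   intention class (C⁺, default 2) and the steady-state class (C⁻, default
   1), kernel width γ defaulting to `1/(n_features × mean feature
   variance)`. Evaluation is stratified ten-fold cross-validation;
   z-scoring and feature selection are refit on the training folds of every
   round so no test information leaks (a `selection_scope = "global"` mode
   exists for comparison and is documented as leaking). Metrics are
   accuracy, sensitivity (intention recall), specificity, and FP/min — the
   false-positive rate scaled by the frequency of steady-state trials per
   minute. Cross-subject aggregation is the arithmetic mean with sample SD.
   Trans- vs pre-event windows are compared with one-tailed two-sample
   t-tests (pooled variance by default, Welch by switch) with Holm
   step-down over the six (trans, pre) pairs per problem; both raw and
   adjusted decisions are reported because it is ambiguous which of the two
   the reference tables print.

## The synthetic session generator

No public recordings accompany the protocol this package models, so
`generate_session()` produces the study conditions directly: eight channels
at 500 Hz, alternating rest→start→walk→stop cycles with state durations
drawn uniformly from [5, 8] s (the protocol fixes only the 5 s minimum),
and band-limited ERD beginning 1.5 s before every start and stop event.

The signal model is the simplest one that exposes everything the pipeline
measures:

* **Background**: 1/f-shaped broadband noise, built from three shared
  sources projected with per-channel weights plus a per-channel independent
  stream (3:1 power split). The shared sources emulate volume conduction and
  give realistic inter-channel correlations, which the bad-channel rule
  depends on.
* **Oscillators**: a 10 Hz alpha and a 20 Hz beta carrier, reaching every
  channel with non-uniform gains and a per-channel phase lag of at most
  π/2. The phase spread keeps pairwise covariances positive (high raw
  correlations) while preventing the instantaneous channel mean from
  absorbing the rhythm, so common-average referencing attenuates rather
  than cancels it. Both carriers wax and wane under a slow (~0.2 Hz)
  amplitude modulation with relative SD 0.3, emulating the natural
  variability of ongoing band power; without it single-trial classification
  would be degenerately easy.
* **ERD envelope**: amplitude ramps linearly to `sqrt(1 − drop)` over
  0.5 s starting 1.5 s before each event, holds until 0.5 s after it, and
  releases over 0.5 s. A ramp spread over the whole lead interval would
  leave the `[-1 0]` window at ~65% of baseline power for a nominal 50%
  drop; the short-ramp shape makes the configured drop the drop an
  independent PSD estimator actually measures in that window, which is the
  property the generator exists to provide. Default depths are 0.5 for
  both bands; the reference study does not quantify its subjects' ERD
  depth, so these are conventions, not estimates.
* **Walking signature**: a ±10% rhythmic (~1 Hz) modulation of the
  broadband background during walk states, so walk vs. rest is
  non-degenerate.
* **Artifacts** (all off by default): Poisson blink-like 300 ms
  raised-cosine transients with a frontal-weighted topography, 60 Hz line
  noise, and flat-channel faults. Flat faults are applied last — a railed
  electrode outputs a constant regardless of ambient pickup.

What the generator does **not** emulate: forward-modelled scalp physics,
movement-related cortical potentials (near-DC), EMG or pressure waveform
realism beyond event timing, non-stationary electrode drift, and real
artifact morphology. Passing tests on this generator therefore demonstrate
that the chain recovers the structure it is designed for under controlled
conditions — not that it would reach any particular accuracy on recorded
EEG.

## Subjects, sessions, and pooling

A study subject performs ~140 gait cycles collected over repeated runs.
`run_experiment()` models a subject as `n_sessions` generated sessions of
`n_cycles` cycles whose epochs are pooled before cross-validation (defaults:
14 sessions × 10 cycles ≈ 140 trials per class). Feature columns are
z-scored *within each session* before pooling (`pool_features()`): sessions
differ in overall signal state (gains, slow band-power level), those offsets
are shared by both classes of a session, and without per-session
normalization a cross-validated classifier can exploit session identity —
in null experiments this showed up as systematically below-chance held-out
accuracy. The transform uses no class labels. The packaged defaults run
3 subjects; this keeps a full 5-window, 2-problem experiment at a few
minutes on one CPU while leaving cross-subject aggregation meaningful, and
the per-subject trial count — the quantity that controls the stability of a
single cross-validation — at the study's scale.

## Numerical choices

* Wavelet boundaries use periodization, making the transform orthogonal and
  the per-level band reconstructions sum *exactly* to the input (tested to
  1e-8 relative error); odd lengths are extended by repeating the final
  sample at the level where they occur and trimmed on inversion. The db4
  analysis taps are the standard orthonormal Daubechies-4 filter.
* The rank-sum statistic uses the normal approximation with tie-corrected
  SD; at the sample sizes involved (tens to hundreds of epochs) this is the
  standard choice, and an all-tied column is defined to score 0.
* A constant feature column's correlation is undefined; its redundancy
  contribution is defined as 1 so constant features are never preferred.
* Greedy selection breaks ties toward the lower column index, making
  selection deterministic; permuting columns permutes the result
  consistently.
* EDF signals are quantized to 16 bits against a per-channel symmetric
  physical range; round trips are exact to that quantization and the event
  sidecar stores onsets at 1 ms resolution.
* Fold assignment is stratified (within-class round-robin after a seeded
  shuffle) so fold class counts are balanced within one; every derived seed
  stays below 2³¹.

## Worked example

```{r example, eval = FALSE}
library(gaitintent)

cfg <- experiment_config(
  windows = list(c(-1, 0), c(-1, 1)),
  synth = list(n_subjects = 2, n_sessions = 6, n_cycles = 10),
  seed = 42)
res <- run_experiment(cfg)
res$report
write_report(res$report, "report.json")
```

The printed report shows, per problem and window, the cross-subject mean ±
SD accuracy, the mean sensitivity and specificity, and FP/min. With the
default 50% ERD depth the pre-movement `[-1 0]` window decodes rest vs.
start well above chance, and label-null configurations
(`alpha_drop = beta_drop = 0`) stay inside the binomial chance band.

## Known limitations

* The generator's ERD is deterministic in depth and timing; real
  pre-movement dynamics vary trial to trial, so synthetic accuracies are
  not predictions of performance on recorded EEG.
* The simplified burst repair is not toolbox ASR; it shares the
  calibration-plus-threshold structure but none of the implementation
  details.
* The cost asymmetry direction is exposed in configuration
  (`cost_pos`/`cost_neg`) because published descriptions of cost-sensitive
  training in this setting are ambiguous about which class carried the
  higher cost; the default penalizes missed intentions more (C⁺ = 2).
* Online/asynchronous operation is out of scope: all evaluation is offline
  cross-validation on pre-cut epochs.
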