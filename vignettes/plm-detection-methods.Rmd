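---
title: "Detecting periodic leg movements without leg EMG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting periodic leg movements without leg EMG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Periodic leg movements (PLM) in sleep are stereotyped leg-EMG bursts —
0.5 to 5 s long, recurring in series of at least four with onset-to-onset
intervals between 5 and 90 s (the Coleman scoring rules). They are
normally scored from dedicated leg-EMG channels of an overnight
polysomnogram (PSG). Every extra electrode, however, costs setup time,
patient comfort and storage, so an attractive question is whether PLM
epochs can be recognized from the *other* PSG channels: EEG, EOG, chin
EMG, ECG, oximetry, respiration, position and sound.

`plmdetect` implements that pipeline end to end: leg EMG is used once,
to score ground-truth labels, and never again; a classifier then has to
recover those labels from 77 attributes computed on the remaining
channels. Because the clinical recordings behind the original experiment
are not publicly available, the package ships a synthetic PSG generator
that reproduces the *statistical structure* the pipeline relies on, so
every stage is testable end to end without patient data.

## Pipeline

1. **Segmentation.** Recordings are cut into 5-s epochs — 5 s is the
   minimum PLM onset-to-onset interval, so one epoch cannot span two
   movements of a series. Epochs are half-open intervals `[5i, 5i+5)`;
   a trailing partial epoch is dropped.
2. **Exclusion.** Three independent flags, computed per epoch:
   *artefact* (any overlap with a scored artefact on any channel),
   *apnea-adjacent* (overlap with an apnea/hypopnea dilated by 15 s on
   both sides, separating respiratory-event-associated leg movements
   from periodic ones), and *wake* (the 30-s scoring page containing the
   epoch start is Wake). Because flags are independent, the three stages
   commute; any positive-length overlap triggers exclusion (the
   strictest reading, chosen because the source bookkeeping does not
   specify tie handling). The apnea rule removes whole epochs rather
   than trimming time, again the conservative reading.
3. **Labelling.** `detect_movements()` rectifies the leg EMG and smooths
   it with a 100-ms moving-RMS envelope; maximal runs above
   `resting + 8` units become candidate movements, runs outside
   \[0.5, 5\] s are discarded. `group_periodic_series()` chains
   movements greedily left to right while onset intervals stay within
   \[5, 90\] s; a short (< 5 s) interval breaks the chain and skips the
   offending movement, a long (> 90 s) interval starts a new chain;
   chains of ≥ 4 movements are PLM series. An epoch is labelled PLM iff
   any in-series movement overlaps it, so a movement spanning an epoch
   boundary labels both epochs (the overlap rule is our choice; the
   alternative — assigning to one epoch only — is not stated anywhere).
   The "8 units above resting" amplitude criterion is implemented as a
   configurable `threshold_delta` with the unit carried by the channel
   metadata, since EMG scoring thresholds are conventionally microvolts.
4. **Balancing.** The majority class is downsampled to the minority
   size, allocated across patients proportionally to each patient's
   majority count with largest-remainder rounding, then both classes are
   subsampled to `sample_percent` (default 10%) of the balanced size,
   sampling uniformly over each patient's night. This replaces a manual
   per-patient equalization step in the original workflow with a
   deterministic, seeded rule; only recorded epochs are used, nothing is
   duplicated.
5. **Features.** 77 attributes (the fixed registry in
   `feature_registry()`): for each of six EEG derivations the four Haar
   subband powers plus zero crossings, mean, mean power spectrum, RMS
   and spectral entropy; the same five spectral/time statistics for ECG
   and chin EMG; RMS of EOG, airflow, thorax, abdomen and snore sound;
   SpO₂ desaturation (max − min in the epoch), minimum and RMS; mean
   heart rate; body position; sleep-stage code; and an apnea flag. The
   apnea flag is retained for registry fidelity although it is
   identically 0 on retained epochs — the apnea-adjacency exclusion
   removes every epoch that could set it.
6. **Attribute ranking.** Gain ratio
   `GR = (H(Class) − H(Class | Attribute)) / H(Attribute)` per
   attribute, with equal-frequency discretization into 10 bins
   (ties share the lower bin, so the binning — and hence the score — is
   invariant under strictly monotone transforms). Supervised MDL binning
   is the common alternative; equal-frequency was chosen because it is
   deterministic, parameter-light and makes the oracle tests
   binning-agnostic. Constant attributes score 0 by convention
   (avoiding 0/0 on, e.g., the apnea flag).
7. **Classification.** Four models with fixed published defaults: 1-NN
   (Euclidean on min-max normalized features), random forest (100
   trees), a 1-hidden-layer MLP (42 sigmoid units, per-sample SGD,
   learning rate 0.3, momentum 0.2, 500 iterations) and logistic
   regression (ridge 10⁻⁸, IRLS). Min-max normalization is fitted on
   training folds only and applied to test folds, so no information
   leaks across the split. Evaluation is stratified 10-fold
   cross-validation repeated 10 times, reporting per-fold confusion
   matrices (columns actual, rows predicted), accuracy, and
   probabilistic RMSE `sqrt(mean((p − y)²))` over instances and the two
   one-hot classes — the probability-based definition is the only one
   consistent with error values near 0.3 at accuracies above 0.9.
   Fold remainders are rotated across classes so total fold sizes never
   differ by more than one (9286 rows at k = 10 gives folds of 929 and
   928).

## Haar subbands and their limits

EEG band features use the orthonormal multilevel Haar transform. Detail
level *k* at sampling rate `fs` spans the dyadic octave
`[fs/2^(k+1), fs/2^k)` Hz, so the nominal bands map to the nearest
octaves: beta ≈ 16–32 Hz, alpha ≈ 8–16 Hz, theta ≈ 4–8 Hz, delta the
union of the deeper detail levels down to 0.5 Hz. The 0–0.5 Hz
approximation is deliberately excluded from delta so DC and slow drift
never enter a band power. Exact 13 Hz and 30 Hz edges are unattainable
with a dyadic filter bank, and Haar's frequency roll-off is slow: a pure
6 Hz tone at 256 Hz puts 54% of its four-band energy in theta (the rest
leaks into the neighbouring octaves), and for noise confined to one
octave the matching detail level captures roughly half to three quarters
of the true in-band energy. The tests therefore assert what the
transform actually guarantees — exact energy conservation over the
complete decomposition (Parseval to 10⁻⁹ relative) and correct dominant
band — rather than sharp-filter behaviour it cannot have. Band power is
defined through the DFT of the reconstructed component, normalized so it
equals the time-domain mean square; the bulk extractor computes the same
quantity directly from the orthonormal coefficients.

Spectral entropy uses the one-sided periodogram of the mean-removed
segment (detrending prevents the DC bin from dominating the
distribution; the segment mean is *not* removed for the `mean`
attribute, which exists precisely to measure it). An all-zero spectrum
has entropy 0 by convention.

## The synthetic generator

`sim_config()` defaults describe one night of a severe-PLMD patient and
were fixed from typical PLMD-cohort statistics before any classifier was
run: 6-h recordings; stage mix Wake 0.15 / N1 0.06 / N2 0.49 / N3 0.17 /
REM 0.13 with geometric 30-s-page dwell times (mean 5 min); EEG as
band-limited Gaussian noise with stage-dependent amplitudes (delta
rising through N2/N3, alpha dominant in wake); respiration at 0.25 Hz
with 5 apnea/hypopnea events per hour followed 10–20 s later by SpO₂
desaturations of ~5%; an ECG pulse train driven by a 1-Hz heart-rate
series; 4 artefacts/hour on random channels; and 100 leg movements per
hour (10 series/h × 10 movements, onset intervals 10–30 s, durations
0.5–3 s, burst 20 µV above a 2 µV resting level) — the top of the range
seen in PLMD cohorts, chosen so that three simulated patients yield
roughly 4,000 balanced epochs.

Movement-to-channel **coupling** is the generator's key free parameter:
nothing quantitative is published about how PLM manifests in non-leg
channels, so effect sizes are explicit configuration, not estimates. The
"strong" defaults (an EEG alpha/beta burst of 2 × 10 µV, chin-EMG bursts
of 4 × 4 µV, a 4% movement-locked SpO₂ dip, a 15-bpm transient
heart-rate acceleration) give a clearly learnable problem; `coupling_none()`
removes every signature, making non-leg channels statistically
independent of movement placement. Consequently the end-to-end
benchmark is a *calibration of the pipeline*, not a reproduction of the
clinical accuracy: with strong coupling 1-NN reaches ≈ 0.95, with zero
coupling it sits at chance (≈ 0.5, slightly above due to the temporal
clustering of PLM epochs within series, which lets temporally stable
context features carry a trace of label information — real data would
show the same). What passing tests demonstrate is that the pipeline
recovers exactly the signal that is present and nothing when it is
absent; they cannot certify clinical performance, EEG morphology
(spindles, K-complexes are absent by design), or realistic artefact
physics.

## Numerical and interface choices

* EDF (16-bit) is written with 1-s records, per-channel physical ranges
  taken from the data, and padding to whole seconds by repeating the
  final sample; round-trip error is at most half a quantization step
  `(physMax − physMin)/65535`. Annotations live in a small documented
  XML dialect (JSON mirror): `<event kind onset duration channel value>`
  with seconds from recording start and half-open intervals, written at
  millisecond precision. Reads never mutate inputs.
* All randomness (generation, balancing, fold assignment, MLP
  initialization) flows through one seeded stream per call and restores
  the caller's RNG state; identical `(config, seed)` pairs are
  bit-identical.
* Problem sizes used by the shipped tests and the acceptance script —
  3 patients × 6 h for the benchmark (≈ 3,900 balanced epochs), 45-min
  single-patient nights for the coupling-monotonicity property, 1-h
  nights for scorer recovery — were chosen as the smallest sizes at
  which the respective statistics are stable.
* Sampling rates are per-channel metadata. EEG-band features require a
  power-of-two rate ≥ 64 Hz; the generator uses 128 Hz for
  EEG/EOG/EMG/ECG, 256 Hz for airflow and sound, 128 Hz for effort,
  1 Hz for SpO₂, heart rate and position.
* Stage codes: Wake 0, N1 1, N2 2, N3 3, REM 5; position codes 0–4
  (supine, left, right, prone, upright).

## Known limitations

* The 77-attribute registry is the published selection; the wider
  466-candidate pool it was chosen from is not published and is not
  reimplemented.
* Gain-ratio scores on synthetic data are not comparable in magnitude
  to published clinical scores (≈ 0.04 for the top oximetry attribute
  there); only the ranking machinery is reproducible.
* The MLP trains by per-sample SGD in pure R and is therefore slow at
  full benchmark size; the published hyperparameters are honored
  exactly, but the end-to-end benchmark uses 1-NN (the best model in
  the reference results) for tractability.
* Coleman scoring here uses a single leg-EMG channel; bilateral montages
  would need per-leg scoring and union of events.
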