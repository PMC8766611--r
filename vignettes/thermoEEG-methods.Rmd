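---
title: "thermoEEG: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{thermoEEG: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
knobs matter, what the synthetic-data generator does and does not emulate,
and where genuinely open design questions were settled.

## The analysis model

Five thermal stimuli applied to the right hand — very cold, cold, warm,
hot, very hot — are grouped by intensity into NOX (very intense), MOD
(moderate) and INNO (innocuous). Three signatures carry the analysis:

1. **Alpha-band ERD.** During stimulation the ongoing 8–12 Hz rhythm over
   contralateral-central electrodes loses power relative to the
   pre-stimulus baseline. The package quantifies this as the index
   $\mathrm{ERD} = (P_\text{base} - P_\text{stim}) / P_\text{base}$ on
   Welch band power; no formula for the index is canonical in the
   literature beyond this relative-power form, so the package fixes it and
   names it explicitly. The more intense the condition, the larger the
   index, which makes per-trial alpha power negatively correlated with
   discomfort ratings (Pearson's r).
2. **Evoked transients.** Each condition adds a stimulus-locked transient
   whose peak channel, latency and amplitude are summarized by
   `detectPeak()` (maximum absolute amplitude in a window; ties resolved
   to the earliest latency, then channel order) and by the global field
   power, the population standard deviation of the instantaneous
   potentials across electrodes. The GFP is implemented as that textual
   definition — $\sqrt{\tfrac1N \sum_i (\mu^i - \bar\mu)^2}$ — because the
   widely-reproduced typeset formula (dividing by $N$ outside the root,
   squaring $\bar\mu$ inside the sum) contradicts the definition in words;
   the implementation follows the words.
3. **Decodability.** Condition pairs are classified from 3 s crops by
   CSP → log-variance features → PCA(2) → LDA, evaluated with balanced
   accuracy under an 80/20 split with stratified k-fold cross-validation
   inside the training portion.

## The synthetic-data generator

No recordings are distributed with the paradigm, so the generator is a
first-class, tested module: it defines the study conditions under which
every downstream claim is verified.

**Signal model.** Per channel, the generated EEG is the sum of

* $1/f$ pink noise, RMS-normalized to 10 µV per channel;
* an ongoing 10 Hz alpha rhythm of amplitude 20 µV on posterior and
  central channels;
* a Gaussian-windowed biphasic (Gabor) evoked transient at stimulus onset
  plus the condition's latency, on the vertex channel Cz, with amplitude
  ordered by the condition's mean discomfort
  (warm 3 < hot 4.5 < cold 5 < very hot 6.5 < very cold 8 µV); the pulse
  center is snapped to the sample grid so peak recovery is exact;
* injected artifacts at 0.05 expected events per trial and kind:
  high-amplitude Gaussian excursions (180–300 µV) and 100–180 Hz EMG
  bursts at 1.5–5 mV, both recorded in a ground-truth table so the
  rejection stage can be checked exactly.

**ERD realization.** The condition's `alphaErdFraction` is the fraction of
alpha-band *power* removed during stimulation: the alpha amplitude at the
weighted channels is multiplied by $\sqrt{1 - w f}$. Scaling the amplitude
by $(1-f)$ instead would remove $1-(1-f)^2 = f(2-f)$ of the power and the
measured ERD index would not recover the injected fraction; the power
convention makes the generator's dial and the analysis's read-out the same
quantity. The default fractions (warm 0.05, hot 0.20, cold 0.30, very hot
0.45, very cold 0.55) increase strictly with the conditions' mean
discomfort ratings, so the negative alpha–discomfort correlation holds by
construction and the fractions are calibrated so that the NOX-vs-INNO
contrast is decodable from single crops.

**Spatial coherence of the alpha rhythm.** The alpha component uses one
common oscillator phase per trial plus a fixed per-channel phase offset
drawn once per session. Two properties follow. First, 10 Hz times any
whole-second window is a whole number of cycles, so per-channel alpha
variance is exactly $A^2/2$ (scaled by the ERD factor during stimulation)
— injected effect sizes are recovered without estimator noise. Second, the
cross-channel covariance of the alpha subspace is identical across trials,
so spatial filters fitted on training trials transfer to held-out trials.
An earlier variant with independent per-trial phases per channel was
rejected: it makes the within-trial cross-channel structure random from
trial to trial, which no spatial filter can generalize across — a property
real, volume-conducted scalp alpha does not have.

**Ratings.** Drawn from a normal with the condition's printed mean and SD,
clamped to the 0–9 scale. `generateRatings()` returns the continuous draws
by default (so distributional checks are exact) and the session CSV writer
rounds to integers, matching a discrete rating scale.

**Skin profiles.** Two sensor channels at 250 Hz start at the ambient
28 °C and relax exponentially toward the object temperature (default time
constant 1 s) plus Gaussian sensor noise (default SD 0.05 °C). Object
temperatures are drawn uniformly inside each condition's printed bin;
`driftC` shifts them toward ambient to emulate objects losing their
temperature over long sessions, which confuses the extreme classes with
the moderate ones exactly as a bin-based classifier predicts.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: non-stationary background spectra, imperfect
alpha coherence and subject-specific topographies, volume-conducted
artifact spread across channels, ocular artifacts (the corresponding
ICA-based cleaning is out of scope), anticipatory pre-stimulus activity,
and any source-space structure. Decoding accuracies on this synthetic data
are upper bounds that validate the pipeline's correctness, not a claim
about biology.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| band-pass | 0.5–70, order 4 | Hz | analysis band; normalized cutoffs 0.0019/0.273 at 512 Hz |
| notch | 50, Q = 30 | Hz | mains; only the frequency is canonical, Q chosen narrow |
| epoch length | 3000 | ms | analysis epochs; pre-stimulus epochs use the same op with window (−3, 0) |
| amplitude threshold | 100 | µV | rejection, read as absolute per-sample amplitude after filtering |
| EMG criterion | 50–200 Hz, 1–10 mV | | applied to raw epochs, since the band exceeds the band-pass |
| crop window/stride | 3 / 3 | s | non-overlapping; 10 crops per 30 s trial |
| CSP pairs | 2 | | 4 features; the filter count is otherwise unconstrained |
| covariance shrinkage | 1e-4 | | trace-scaled; regularization is otherwise unspecified |
| PCA components | 2 | | fixed by the protocol |
| split / folds | 80/20, 10 | | stratified; folds are capped (with a message) at the parent-trial count in group-aware mode |
| SSC/WA thresholds | 0.01 | °C | sensor-noise scale |
| QLDA shrinkage | 1e-3 | | per-class covariance regularization |

## Numerical choices

* **Zero-phase filtering.** Filters are applied forward-backward (odd
  reflection padding, step-response initial state), because peak latencies
  are interpreted to tens of milliseconds and a causal filter would bias
  them; the causal single-pass variant remains available
  (`zeroPhase = FALSE`). The kernel is a small C++ routine because an
  R-level loop dominates 64-channel sessions. An 8th-order band-pass with
  a corner at 0.0019 of Nyquist is numerically delicate: different
  textbook implementations of the same recursion disagree at the percent
  level in the passband. The designed responses are therefore verified
  behaviorally (50 Hz suppressed below 5%, 10 Hz preserved within 5%, DC
  removed, linearity and zero-phase symmetry) rather than against another
  implementation's samples.
* **Reporting convention for cutoffs** truncates (not rounds) the low
  fraction to 4 decimals and the high to 3.
* **Welch estimator**: 1 s Hann segments, 50% overlap, one-sided PSD
  normalized so the band integral equals mean-square amplitude. These
  parameters are fixed in the configuration for reproducibility.
* **Epoch windows** are half-open `[start, end)` in seconds relative to
  the stimulation onset sample (1-based indexing internally).
* **Ties** in peak detection go to the earliest latency, then channel
  order; PCA signs are fixed by making each axis's largest-magnitude
  loading positive; CSP filters are ordered extremes-first.
* **Degenerate inputs**: zero-variance CSP projections are floored at
  1e-12 before the log (reported via a message); zero baseline power makes
  the ERD index `NA`; zero-variance samples are errors for the normality
  test; temperatures in the gaps between bins go to the nearest boundary
  and are flagged (`gap = "unresolved"` returns `NA`).
* **Serialization** uses 9 significant digits everywhere, so identical
  inputs and seeds reproduce byte-identical result files; every artifact
  carries the MD5 hash of the configuration.

## Open design points and how they were settled

* **"Beyond 100 µV"** is read as absolute per-sample amplitude after
  filtering (not peak-to-peak, not pre-filter); the criterion is also
  applied to decoding crops, since crops are the epochs the classifier
  consumes and artifacts in seconds 3–30 of a trial would otherwise pass
  through.
* **EMG rejection is automated** (band-limited peak amplitude on raw
  epochs) although the original procedure was manual; manual review is
  out of scope and the automated criterion is exactly checkable against
  the generator's ground truth.
* **CSP is fitted inside each cross-validation fold** (and on the full
  training portion for the test phase). Fitting it once on all data is
  optimistically biased; the single-fit variant is switchable
  (`cspPerFold = FALSE`).
* **Splits are parent-trial-aware by default**: all crops of one trial
  stay on one side of every split. Naive per-crop stratification
  (available as `groupAware = FALSE`) leaks trial-specific structure into
  validation and test scores.
* **The post-hoc test** is Dunn-style pairwise z comparisons on the pooled
  ranks, uncorrected; descriptions of the original procedure are
  internally inconsistent (a Tukey HSD post-hoc is named while a
  Tukey–Kramer correction is denied), so both variants are implemented
  and neither is claimed canonical.
* **Plain KS vs Lilliefors**: the normality check tests against a normal
  with estimated parameters, which makes the plain KS p-value
  conservative; the Lilliefors correction is offered behind a flag and the
  documentation says so rather than silently substituting it.
* **EDF as interchange format** (16-bit, one-second records), with a
  documented columnar text dialect as fallback; events, ratings and
  ground truth travel in CSV sidecars rather than embedded annotations.
  The acquisition system's proprietary format is not supported.
* **Reference handling**: the recording stores an optional reference
  label but no re-referencing is applied by default — the vertex
  reference question (Cz is both the stated reference and an analyzed
  channel) has no clean resolution, and GFP is reference-free anyway.
* **The dual-stimulus (both hands) condition** is out of scope; its 10
  trials are counted in the 60-trial session total but never simulated or
  analyzed.

## Problem sizes used by the tests and the acceptance script

Most tests run on 8-channel sessions with the full 512 Hz rate and trial
layout — channel count does not change any counting or recovery property,
and 8 channels keep fixtures light. The end-to-end decoding checks use the
full 64-channel default montage with 10 trials per condition, 10 seeds in
the test suite and 5 in the acceptance script; ERD recovery uses 16 trials
with band power over the full 30 s stimulation and 10 s baseline windows,
where the band-power estimator's own variance is small against the ±0.05
recovery band; the Kruskal–Wallis type-I rate uses 5000 null simulations
of three groups of 10. These sizes are the package's choices for stable,
quickly reproducible checks.

## Known limitations

Single-session, single-"subject" semantics (no between-subject variance
model); no multi-class decoding (binary pairs only, as in the protocol);
no source localization, ICA cleaning, or time-frequency analysis; EDF
support is the minimal subset this package writes; the robot-skin module
reduces the real-time robotic loop to the pure classification and policy
functions.
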