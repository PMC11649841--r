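---
title: "Brain-heart coupling from neuromonitoring waveforms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-heart coupling from neuromonitoring waveforms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After severe traumatic brain injury, the autonomic nervous system (ANS) and
cerebral hemodynamics interact in ways that averaged monitoring values do not
capture: transient episodes where intracranial pressure (ICP) dynamics lead
or lag autonomic activity may carry prognostic information. This package
implements a pipeline that quantifies those transients with windowed
time-lagged cross-correlation (WTLCC) matrices between minute-resolution
neuromonitoring indices, classifies patient outcome from the matrices with a
compact convolutional network, and compares that against gradient-boosted
models on averaged indices adjusted for the CRASH clinical covariates (age,
GCS, pupil reactivity, major extracranial injury).

Because the clinical high-resolution databases this kind of analysis is run
on are access-restricted, the package ships a coupled brain-heart signal
simulator with known ground truth. Every stage of the pipeline is validated
as a parameter-recovery problem against that simulator: the baroreflex gain
planted in the waveforms must come back out of the baroreflex-sensitivity
estimator, a planted coupling lag must come back out of the WTLCC stage, a
planted class difference in coupling dynamics must come back out of the
classifier.

## Derived indices

All indices are produced at 1-minute resolution over at most the first 72 h
of monitoring (4320 minutes), with explicit missingness masks rather than
sentinel values, so that correlation windows can count valid pairs exactly.

* **ICP / mean ABP** — trapezoidal waveform time integration over 60-s
  intervals. A minute with more than 25% invalid samples is missing (the
  threshold is a declared default; artifact policy is not prescribed by the
  method).
* **CPP** — mean ABP minus ICP, minute-wise.
* **PRx** (pressure reactivity index) — Pearson correlation between 10-s
  means of ABP and ICP over a 5-min moving window updated every 10 s; the
  six updates within a minute are averaged. Zero-variance windows are
  undefined (missing), never zero: a zero would assert "no reactivity"
  where nothing was measured.
* **BRS** (baroreflex sensitivity, xBRS) — beat-wise systolic pressure and
  interbeat interval (IBI) resampled to a 1-s grid; per 10-s segment the
  IBI is correlated against pressure at delays of 0-5 s; the best positive
  delay, if significant, contributes its regression slope (ms/mmHg). The
  physiological gain is positive (a pressure rise lengthens the interval)
  and is reported as a positive slope; negative best correlations are
  rejected.
* **LF/HF** — Lomb-Scargle periodogram of the unevenly sampled IBI series
  per right-aligned 5-min window stepped by 1 min, integrated over
  0.04-0.15 Hz (LF) and 0.15-0.40 Hz (HF). The window length and step are
  conventions (a 5-min window is the shortest that resolves several LF
  cycles and yields the 1-min series the WTLCC stage needs); right
  alignment keeps the series causal. An HF floor of 1e-12 guards the ratio
  against division blow-ups. Beats come from ABP pulse peaks: pulse-interval
  variability stands in for RR variability, as no ECG enters the pipeline.

### Calibration of the xBRS significance rule

The textbook rule — accept a segment when the best-delay correlation is
significant at p < 0.01 for n = 10 — is anticonservative in this estimator
for two compounding reasons: the best of six overlapping delay candidates
is selected, and linear interpolation to the 1-s grid leaves serial
correlation in the segments, lowering the effective sample size. On the
independence null (no baroreflex, pure interval noise) the naive rule
accepted ~8% of segments instead of 1%. The significance of the best delay
is therefore Sidak-corrected with an effective number of looks
`m_eff = 12`, calibrated once on that null so the realized acceptance rate
matches the nominal level; with the correction, gain recovery on planted
data is unchanged (within ~2% noise-free). `m_eff` is exposed as an
argument for sensitivity analyses.

## The WTLCC stage

For two aligned minute series, an analysis window of `N` minutes is split
into `K` contiguous non-overlapping sub-windows of `w = N/K` minutes; entry
`(k, j)` of the matrix is the Pearson correlation between the first series
restricted to sub-window `k` and the second series shifted by `j - J/2`
minutes (`J = 240` columns: lags from -120 to +119 min). Successive windows
are placed every `S` minutes, giving `floor((T-N)/S) + 1` matrices per
gap-free panel. Grids of N in {360, 720, 1080}, S in {15, 30, 60, 90},
K in {15, 30, 60} are enforced in "paper mode".

Design choices that the method statement leaves open, fixed here:

* **Sub-window geometry** — `K` contiguous windows of `N/K` minutes is the
  minimal reading of "K rows spanning length N"; overlap is not assumed.
* **Lag sign** — positive lag means the first series leads (the second
  series is evaluated later). The convention is arbitrary but fixed and
  covered by a property test: swapping the pair negates the lag once the
  analysis window is re-anchored by the lag (under an anchored-window
  convention the naive "mirror the columns" identity does not hold exactly,
  because the pair set itself shifts with the lag).
* **Edges** — lagged samples are drawn from the full series beyond the
  analysis window where available; otherwise the pair is missing (no zero
  padding), and entries with fewer than `min_valid_frac = 0.8` of their
  pairs are missing. Correlations are Pearson (mean-removed, normalized),
  which keeps every entry in [-1, 1].
* **Missing entries** are stored as missing and imputed as 0 only at the
  model-input boundary, never earlier.

Numerically, both series are centred by their grand means before the moment
sums (per-window correlations are invariant to a common shift), which keeps
the single-pass formula accurate to the 1e-10 oracle-equivalence tolerance
against a naive two-loop recomputation.

## The CNN scorer

The scorer maps a WTLCC matrix to P(unfavourable outcome): conv blocks
(same-padding 3x3 convolutions, ReLU, 2x2 max pooling), the final feature
map **flattened** into a dense ReLU embedding, dropout, and a sigmoid head,
trained with Adam on class-balanced binary cross-entropy. Patient-level
scores are the mean over the patient's matrices, thresholded strictly at
0.5 ("exceeds"). Patient-level embeddings are the mean of per-matrix
penultimate-layer activations.

Flattening, not global average pooling, is deliberate and load-bearing: the
discriminative feature of a WTLCC matrix is the *lag position* of its
correlation ridge, and global pooling makes the network translation
invariant along exactly that axis — with global pooling the planted-lag
experiment stays at chance no matter how long the network trains. This was
measured, not conjectured, and the flattened variant is therefore the
package default.

Splits are patient-grouped structurally: the split operates on patient
identifiers and matrices follow their patient, so no patient can contribute
matrices to both sides. Class imbalance is handled with balanced class
weights by default. All randomness (initialization, shuffling, dropout)
flows through R's RNG, so a seed makes training bit-reproducible on a
single thread.

## Hyperparameter search

The search over signal pairs and WTLCC geometry is sequential model-based
optimization in the TPE style, adapted to an all-categorical space: an
initial design stratified across the signal pairs (every pair is tried once
before any is repeated — a space-filling start costs nothing and removes
the risk that a short search never visits the planted pair), then candidates
ranked by the ratio of Laplace-smoothed categorical densities fitted to the
top quartile versus the remainder of past trials. The objective is
patient-level validation AUC with validation log-loss as tie-break; small
validation cohorts make AUC coarse (granularity `1/(n_pos * n_neg)`), and
the loss tie-break resolves ties toward the stronger signal.

## The simulator

`simulateWaveforms()` produces a beat train: each beat is a stereotyped
pulse (raised-cosine systolic upstroke of fixed 120-ms duration, exponential
diastolic decay) scaled per beat; the interbeat interval responds to
delayed systolic pressure with gain `baro_gain`, carries LF (0.1 Hz) and HF
(0.25 Hz) oscillations plus white noise, and the LF envelope is modulated by
the lagged ICP slow wave with depth `coupling_strength`. ICP is a baseline
plus slow waves plus a small cardiac pulse. `simulateMinutePanel()` is the
fast path that emits the derived indices directly with the same statistical
structure; cohort tests use it, waveform tests use short (<= 1 h) snippets.

Two rendering details matter and were found the hard way:

* The systolic peak sits at a **fixed absolute delay** after beat onset,
  not at a fixed fraction of the beat. With a fractional peak position,
  measured peak-to-peak intervals are a two-tap smoothing of the true IBI
  sequence, which attenuates HF power by ~18% and biases LF/HF upward by
  about that much — an artifact of the renderer, not of the estimator.
* Slow waves (0.3-3 cycles/min, the B-wave band) are sums of five
  random-frequency sinusoids whose phases diffuse with a ~20-min coherence
  time. Pure tones stay coherent for hours and produce spurious
  cross-correlation ridges at large lags; phase diffusion gives the finite
  autocorrelation time real slow waves have, so a planted lag is the unique
  ridge.

The ABP slow mean carries its own independent slow component
(`abp_slow_amp`, default 3 mmHg). Without it, CPP = MAP - ICP would be a
deterministic mirror of ICP and every CPP pairing would duplicate the ICP
pairings; with it, coupling planted into ICP appears in CPP only diluted by
the arterial slow-wave variance, which is both more realistic and what makes
"the signal lives in the ICP-LF/HF pair" a falsifiable statement.

The minute-level noise defaults (ICP 0.5 mmHg, PRx 0.15, BRS 1 ms/mmHg,
LF/HF 10% multiplicative) are fixed, realistic magnitudes; `noise_scale`
scales them jointly and `noise_scale = 0` gives the analytic constructions
used as oracles. Clinical metadata are sampled from severe-TBI-like
distributions (age ~ N(46, 16) clipped to 18-85, GCS 3-12, pupils
76/18/6%, extracranial injury 40%) and carry no class signal unless
configured to.

What the simulator does **not** emulate: plateau waves, paroxysmal
sympathetic hyperactivity episodes, treatment interventions, sensor
artifacts beyond missingness, ECG morphology, or any claim about the
physiological mechanism of ICP-ANS coupling — the lagged-envelope coupling
is one plausible structure chosen for controllability. Passing
parameter-recovery tests therefore shows the pipeline is correct and
sensitive under this structure, not that real TBI data contain such
signals.

## Validation experiments and problem sizes

The test suite and the acceptance script run scaled-down experiments chosen
to be decisive yet quick on a single CPU:

* **Oracle equivalence** — 20 random 72-h series pairs; every matrix entry
  against a naive double-loop Pearson at 1e-10.
* **Lag recovery** — planted lags -60..+60 min at coupling 1 with default
  minute noise; per-row argmax within +/-1 min.
* **End-to-end** — 40 minute-fidelity patients over 24 h whose classes
  differ only in coupling lag (0 vs 60 min) at strength 0.8; geometry
  N = 360, S = 90, K = 30, J = 240; a compact 8/16-filter network trained
  25 epochs. Held-out patient AUC is compared against label-permuted
  retrainings (mean of three permutations, reducing the variance of the
  null estimate).
* **Pair selection** — 20 patients whose classes differ only in the
  ICP->LF/HF coupling (strength 0 vs 0.8), arterial slow-wave amplitude
  6 mmHg so the CPP leakage of the ICP signal is diluted; a 12-trial search
  over all six pairs and a small geometry grid, repeated over ten seeds.
* **Tabular ordering** — on the end-to-end cohort (class-equal index
  means), XGBoost on CNN embeddings + CRASH covariates versus averaged
  indices + CRASH covariates, same patient partition.

## Known limitations

* The CNN is intentionally small and trained briefly; it resolves planted
  couplings, and nothing here claims clinical performance.
* xBRS slope estimates are selection-biased upward in very low-SNR segments
  (the significance gate conditions on high correlation); the calibrated
  gate keeps this mild at realistic pressure variability.
* The Mann-Whitney exact path is used for group sizes up to 8 per side;
  beyond that the normal approximation with continuity correction is
  reported, which is the convention but differs from the exact p in the
  third decimal for mid-size groups.
* Waveform persistence is full-precision CSV; at 200 Hz over 72 h these
  files are large, and users with such data should prefer the minute-panel
  representation for storage.
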