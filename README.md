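# wtlcc

Windowed time-lagged cross-correlation (WTLCC) analysis of brain–heart
interactions in neurocritical care.

## What this package is for

After severe traumatic brain injury, cerebral hemodynamics and the autonomic
nervous system interact dynamically; transient episodes in which intracranial
pressure dynamics lead or lag autonomic activity are invisible to averaged
monitoring values but may carry prognostic information. `wtlcc` implements a
complete pipeline for quantifying and classifying those transients from
high-resolution arterial (ABP) and intracranial pressure (ICP) waveforms:

1. **Index derivation** at 1-min resolution over the first 72 h of
   monitoring:
   - ICP and mean ABP by trapezoidal waveform time integration over 60-s
     intervals;
   - cerebral perfusion pressure `CPP = mean ABP − ICP`;
   - pressure reactivity index `PRx` — Pearson correlation of 10-s means of
     ABP and ICP over 5-min windows updated every 10 s;
   - baroreflex sensitivity `BRS` (ms/mmHg) — Westerhof sequential
     cross-correlation (xBRS): interbeat interval regressed on systolic
     pressure over 10-s segments at the best of 0–5 s delays;
   - `LF/HF` — ratio of low (0.04–0.15 Hz) to high (0.15–0.40 Hz) frequency
     heart-rate-variability power from the Lomb–Scargle periodogram of the
     pulse-interval series.
2. **WTLCC matrices** between pairs of index series: an `N`-minute window
   split into `K` sub-windows (rows) correlated at `J = 240` lags of
   `j − J/2` minutes (columns, ±120 min), the window sliding with stride
   `S` — giving `floor((T−N)/S) + 1` matrices per patient.
3. **A compact CNN** mapping each matrix to P(unfavourable outcome), with
   patient-level aggregation: the patient score is the mean of matrix scores,
   unfavourable iff it strictly exceeds 0.5. Penultimate-layer activations
   provide per-patient embeddings.
4. **Gradient-boosted comparison** (XGBoost): outcome from averaged indices
   vs. from CNN embeddings, each adjusted for the CRASH clinical covariates
   (age, GCS, pupil reactivity, major extracranial injury).
5. **Evaluation**: GOS/GOS-E dichotomization (GOS ≥ 4, GOS-E ≥ 5 =
   favourable), rank-statistic AUC, accuracy, F1, confusion matrices, and
   Table-style cohort comparisons (Shapiro–Wilk, Mann–Whitney U,
   chi-squared/Fisher).
6. **A coupled brain–heart simulator** with known ground truth (baroreflex
   gain, LF/HF ratio, pressure-reactivity polarity, ICP→autonomic coupling
   lag and strength), used to validate every stage as a parameter-recovery
   problem. Clinical high-resolution TBI databases are access-restricted;
   the simulator is what makes this pipeline testable end to end.

Data interchange is plain CSV (waveforms as `time_s,value`; panels as
`time_min,icp,cpp,prx,brs,lfhf`; metadata as one row per patient).

## Worked example

Simulate a small cohort whose outcome classes differ *only* in the lag by
which the ICP slow trend leads the LF/HF modulation (0 vs 45 min), then
train the scorer on ICP–LF/HF matrices and evaluate on held-out patients:

```r
library(wtlcc)

spec <- simCohortSpec(
  n_patients = 16,
  class_params = list(
    favourable   = simPatientParams(coupling_lag = 0,  coupling_strength = 0.8,
                                    outcome_label = "favourable"),
    unfavourable = simPatientParams(coupling_lag = 45, coupling_strength = 0.8,
                                    outcome_label = "unfavourable")),
  duration_h = 24, fidelity = "minute", seed = 1)
cohort <- simulateCohort(spec)
names(cohort$panels) <- cohort$records$patient_id

labels <- setNames(cohort$records$outcome_short, cohort$records$patient_id)
split  <- patientSplit(labels, val_frac = 0.3, seed = 1)

res <- runWTLCCExperiment(
  cohort, pair = c("icp", "lfhf"),
  params = wtlccParams(N = 360, S = 90, K = 30, J = 240),
  config = cnnConfig(conv_blocks = list(list(filters = 8,  kernel = 3, pool = 2),
                                        list(filters = 16, kernel = 3, pool = 2)),
                     dense_width = 32, epochs = 25, seed = 1),
  split = split)

print(res$report)
round(res$patient_scores, 3)
```

Output:

```
EvalReport: n = 4, AUC = 1.000, accuracy = 1.000, F1 = 1.000
       pred
true    fav unfav
  fav     2     0
  unfav   0     2
 P001  P004  P010  P011
0.097 0.113 0.516 0.512
```

The four held-out patients are ranked perfectly: the two favourable patients
(coupling lag 0) receive mean matrix scores near 0.1 and the two unfavourable
patients (lag 45 min) land above the strict 0.5 threshold, because the
network has learned where the cross-correlation ridge sits along the lag
axis. `patientSplit()` operates on patient identifiers, so no patient ever
contributes matrices to both sides of the split.

A command-line wrapper over the same functions is installed at
`inst/scripts/wtlcc-cli.R`, with `simulate`, `derive`, `wtlcc` and `run`
subcommands.

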