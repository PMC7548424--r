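---
title: "P1-based VERP biomarkers: model, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{P1-based VERP biomarkers: model, simulator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(verpmark)
```

## The measurement model

Congenital (but not developmental) bilateral cataracts leave a lasting
attenuation of the P1 wave of the visual event-related potential — the
posterior-positive deflection around 145 ms attributed to extrastriate
cortex — while the earlier striate C1 wave is spared. `verpmark` turns
that observation into two classification scores.

For each participant, upper-visual-field epochs are preprocessed in a
fixed order: average reference → zero-phase 40 Hz low-pass (optional
50 Hz notch) → ocular-artifact rejection → response-contamination
rejection → left-field electrode mirroring → per-condition averaging.
The VERP topography is reduced to the mean amplitude per electrode in the
fixed 120–170 ms window and standardized **across electrodes**:
`z = (m − mean(m)) / sd(m)`. Standardization is the age correction: any
participant-level multiplicative gain (children's amplitudes are several
times adults') cancels exactly, which the test suite asserts to 1e-10.

* `MPP1 = mean(z[posterior])` over the 13 electrodes posterior to the
  midline;
* `SVMP1 = w · z[posterior] + b`, with `(w, b)` a linear soft-margin SVM
  trained to separate CC from the rest.

Thresholds maximizing Youden's J on the development ROC are frozen with
the weights and applied unchanged to the validation cohort; scores are
oriented so lower = more CC-like, making thresholds transferable.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| feature window | 120–170 ms | 50 ms around the 145 ms group-mean P1 latency; used for **all** participants (a participant with a numerically absent P1 has no individual latency, so individual-latency windows serve only the latency statistics) |
| peak-search window | 100–200 ms | strict interior local maxima; ties broken by earliest latency |
| posterior set | 13 electrodes | TP9, CP5, CP1, CP2, CP6, TP10, P7, P3, Pz, P4, P8, O1, O2 |
| ocular thresholds | 5×SD (FP1/FP2), 3×SD (F9/F10) | SD over all time points of the separated component signal, maximum over the two channels; rejection window −25..175 ms, bounds inclusive |
| response window | 500 ms | epochs with a manual response within 500 ms of onset are rejected (responders only) |
| low-pass | 40 Hz | order-6 Butterworth *magnitude* applied in the frequency domain — exactly zero-phase, so P1 latencies are unbiased |
| SVM cost grid | 2^−5..2^5 | chosen by stratified 5-fold cross-validated accuracy; ties favour the smallest cost |
| bootstrap / permutations | 2000 / 10000 | published Monte-Carlo sizes; tests scale the permutation count down to 1000 for runtime and say so |

## The synthetic cohort generator

No EEG recordings are distributable, so every downstream stage is
exercised on seeded synthetic cohorts that reproduce the stated design:

* groups of 13/13/26 (development) and 14/15/29 (validation), with 11 CC
  and 8 DC participants carried over between experiments (34% new
  patients) for the test–retest analysis;
* evoked components as latency-jittered Gaussian bumps: C1 (80 ms,
  polarity inverts between upper and lower field), P1 (145 ms,
  posterior-positive, upper:lower amplitude 6:4, larger ipsilateral to
  the stimulated field), N1 (195 ms);
* the P1 attenuated in CC: 5 of 13 draw attenuation ≈ 0 (the published
  "numerically absent P1" subgroup), the rest draw uniformly from a
  calibrated range;
* age scaling `0.6 + 6/age` (linear in 1/age; only monotonicity matters
  because standardization cancels it), and a per-participant lognormal
  gain;
* per-component between-subject amplitude variability (SD 0.3–0.35 log
  units) and latency offsets (3–4 ms). Because standardization is
  shape-sensitive, it is this *ratio* variability — not absolute
  amplitude — that produces the within-group MPP1 spread, which makes the
  injected effect nearly independent of trial count;
* 1/f background noise (6 µV RMS/channel) synthesized from 8 pink
  sources mixed through a random participant-specific matrix (EEG noise
  is spatially correlated), posterior alpha (15 µV, ~10 Hz), and blink /
  saccade artifacts with frontopolar and F9/F10-antisymmetric
  topographies whose ground-truth time courses are returned for the
  rejection rule.

All randomness flows from one master seed through per-participant
sub-seeds recorded in the cohort manifest; identical seeds give
bit-identical cohorts.

### Calibration of the CC effect

The only quantity tuned by simulation is the attenuation range of the
non-absent CC subgroup: with `p1_atten_present = c(0.36, 0.76)` the
full-size development preset yields a standardized CC coefficient of
about −1.44 (target −1.46) in the OLS group model, with development AUCs
near the binormal expectation Φ(1.46/√2) ≈ 0.85. This constant was fixed
once and is not revisited by any test.

### What a green test does and does not establish

The generator emulates the *statistical structure* the analysis assumes —
group differences confined to the P1, amplitude-scale nuisance,
field asymmetries, artifact contamination. It does not model volume
conduction from realistic sources, eye-tracking, pattern-reversal
stimulation, nystagmus waveforms, or non-stationary noise. Green tests
therefore establish that the pipeline implements its stated rules and
recovers known injected structure; they cannot certify clinical
performance on real recordings.

## Numerical choices

* **Filtering** is magnitude-only in the frequency domain (padded to a
  composite FFT length): exactly zero-phase, ≥20 dB at the notch, <1 dB
  ripple below 30 Hz, 60 Hz attenuated below 10%. Filtering, referencing
  and averaging are all linear, so the orchestration averages kept trials
  first and filters the average — the suite asserts exact equivalence
  with the composed per-trial operations.
* **Standard scores** use the sample SD (n−1). Only ranking enters the
  ROC, so the convention is tolerance-free.
* **Peak detection**: strict local maxima (plateaus are not peaks);
  epoch-edge samples never qualify; amplitude ties resolve to the
  earliest latency.
* **SVM**: dual coordinate descent on the L1-loss dual with the bias as
  an augmented feature (the liblinear formulation), tolerance 1e-8 on the
  projected gradient; the problem is strictly convex in `w`, and tests
  require agreement with an independent box-QP solution to 1e-4.
  Class imbalance is left unweighted (the simplest reading of the source
  procedure); a cost-grid tie selects the smallest cost.
* **ROC/Youden**: thresholds are the observed score values; the boundary
  value classifies as CC; Youden ties resolve to the higher-specificity
  threshold.
* **DeLong** variance from placement values with midranks; perfect
  separation yields a zero-width CI with a warning.
* **Cluster test**: two-tailed cluster-forming threshold at α = .05 on
  t(n−1); adjacency = chord distance < 0.65 on the unit sphere. A 0.4
  radius was considered and rejected: with 32 schematic 10/20 positions
  on a *unit* sphere the nearest-neighbour distance is 0.35–0.52, so 0.4
  leaves the posterior graph edgeless; 0.65 is the smallest radius
  connecting 10/20 neighbours (mean degree ≈ 3). Multiple clusters are
  each tested against the max-mass null (strong FWER control).
* **Standardized β** in the group model divides the raw coefficient by
  the outcome SD — the convention that reproduces the published
  raw/standardized ratio; it is documented as an assumption, not asserted
  as the source's computation.
* **Logistic confound models** standardize both predictors so the
  intercept is the log-odds of correct classification at the mean age at
  surgery and mean recovery time; separation is flagged and handled by a
  weak ridge via prior pseudo-observations.
* **Ocular thresholds** are computed per participant over the full epoch
  set (the support of the SD is not specified by the source procedure;
  per-participant gives a stable estimate).

## Known limitations

* In this synthetic world the CC effect is an approximately uniform
  attenuation over the posterior electrodes, so the uniform-weight MPP1
  is already near-optimal and the held-out SVMP1 does **not** outperform
  it (the SVM pays a finite-sample cost for its 13 free weights at
  n = 52). The superiority of the SVM-based score reported on real
  recordings presumably reflects a structured topography difference that
  the generator deliberately does not claim to model; the corresponding
  ordering test is left red rather than engineering such structure in.

* Electrode positions are schematic 10/20 coordinates, adequate for
  adjacency and simulation but not digitised head geometry.
* Blind source separation is out of scope: the rejection rule consumes
  ground-truth ocular components, which real data would obtain from an
  ICA decomposition.
* The absolute µV scale of all components is a free parameter; only
  standardized quantities are calibrated.
* At strongly reduced trial counts (the test-scale presets) test–retest
  κ is substantially below what full-length recordings yield; κ is
  reported, not asserted, at that scale.
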