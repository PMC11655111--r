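---
title: "Epoch-level sleep apnea detection and distinction: models and design choices"
author: "psgApnea"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Epoch-level sleep apnea detection and distinction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the pipeline

Sleep apnea-hypopnea syndrome is scored from overnight polysomnography
(PSG) in 30-second epochs. An epoch may be normal breathing (NORMAL), a
hypopnea (HYP, partial airflow reduction), or one of three apnea forms:
obstructive (OSA, respiratory effort continues against a collapsed
airway), central (CSA, effort absent), or mixed (MSA, a central phase
followed by an obstructive one). `psgApnea` implements an epoch
classification pipeline restricted to low-invasiveness channels —
thoracic respiratory-effort (RIP) belt, pulse oximetry (SpO2), a sound
level channel, two EOGs, one ECG and a body-position code, all sampled
at 100 Hz and band-limited below 30 Hz — and evaluates three dichotomous
case studies:

* **case i** — apnea (OSA/CSA/MSA) vs NORMAL + HYP,
* **case ii** — apnea vs NORMAL (HYP epochs dropped),
* **case iii** — OSA/MSA vs CSA (NORMAL/HYP dropped).

The stages are: synthetic recording generation (`generateRecording`,
`cohortFeatures`), epoch preparation (`prepareEpochs`), feature
extraction against fixed registries (`extractFeatures`), z-score +
covariance-PCA feature selection and MANOVA class-structure analysis
(`zscoreTable`, `pcaCovariance`, `selectByLoadings`,
`manovaDendrogram`), subject-wise splitting and case-wise balancing
(`subjectSplit`, `balanceDetection`, `balanceDistinction`), and tuned
classical classifiers with repeated balanced evaluation
(`tuneAndTrain`, `evaluateCase`).

Case ii drops hypopnea epochs entirely rather than merging them into
the negative class: "apnea vs normal" is read literally, and keeping
the intermediate phenotype out of both sides is what makes case ii
strictly easier than case i.

## The synthetic cohort generator

Clinical PSG archives with event-level annotations are access
restricted, so every stage here is exercised against a seeded generator
whose event physiology follows the clinical picture:

* **Events.** Counts are Poisson at the requested hourly rate; onsets
  are uniform with a 15-s minimum gap; durations follow a truncated
  log-normal (median 28 s, sigma 0.41, clipped to the clinical
  10–120 s), putting roughly 60% of durations in the typical 20–40 s
  band. The default class mix gives hypopneas a 0.45 share and splits
  the apnea remainder in the reported clinical ratios
  OSA:MSA:CSA = 84:15:0.4. Cohorts used for the distinction case pass
  an explicit mix with a usable CSA share (the tests use
  HYP/OSA/CSA/MSA = 0.35/0.40/0.10/0.15), since at clinical frequency
  CSA epochs are too rare to study at desk scale.
* **Thoracic effort.** A quasi-sinusoid at the subject's respiratory
  rate with slow multiplicative amplitude variability (CV ≈ 0.12).
  CSA collapses the envelope to 5%; HYP attenuates it to 40–70%; OSA
  preserves or increases it (floor 0.9) with a crescendo and a strong
  breath-to-breath frequency modulation (the "stuttering" of obstructed
  effort); MSA is central over its first 40–60% and obstructive
  afterwards. Transitions are 1-s raised cosines placed just outside
  the event window, so in-event statistics reflect the event state.
* **SpO2.** Baseline with ±0.5% slow noise. Each event produces a
  desaturation delayed 10–20 s after onset with depth
  `3 + 4*(1 - residual airflow)` percent — full apneas reach 7%,
  hypopneas (residual airflow 0.6–0.9) sit near the 3–4.6% scoring
  threshold — an 8-s fall, a nadir plateau lasting to 10 s past the
  event end, and exponential resaturation (tau = 15 s). The response is
  strictly confined to `[onset, onset + duration + 60 s]`, which gives
  the generator its event-locality property.
* **Audio.** A 100 Hz channel pre-filtered below 30 Hz cannot represent
  raw snore acoustics (hundreds of Hz), so the audio channel is
  modelled as a non-negative *sound-level* trace: breath bursts gated
  at the respiratory rate with multiplicative band-limited noise,
  amplified during obstructive events in proportion to the subject's
  snore propensity, reduced during hypopneas (quieter airflow) and
  collapsed during central phases. Like the oximetry trace it keeps its
  DC level (the hardware "stationary component" removal cannot apply to
  level-type channels), which is what makes the audio time-domain
  features informative.
* **ECG.** A template pulse train at the subject's heart rate with slow
  (3%) variability. The cyclic event response — RR lengthening toward
  event termination, shortening for ~15 s afterwards — is implemented
  as a local time warp with zero net shift, so the response is exactly
  confined to the event's neighbourhood; hypopneas provoke a milder
  warp than full apneas.
* **EOGs.** 1/f background with a 13–30 Hz burst in the 10 s after each
  event end (the arousal), amplitude scaled by event severity.
* **Position.** A piecewise-constant integer code (0 supine, 1 left,
  2 right, 3 prone, 4 upright) with 0–4 changes per night.
* **Acquisition chain.** Signals pass a zero-phase Butterworth band
  limit (low-pass order 4 at 30 Hz; additionally a high-pass order 2 at
  0.05 Hz for the signed channels), applied in the frequency domain as
  the squared analytic magnitude response with mirror padding — exactly
  the response a forward–backward recursive pass realises, and
  numerically robust at the ~1e-3 normalized high-pass corner — and are
  then quantized to a 16-bit midtread grid over the channel's physical
  range. The position code is stored as plain integers.
* **Hypnogram and detachments.** A configurable fraction of event-free
  epochs is flagged wake; because apneic events commonly terminate in
  an arousal or awakening, half of the wake budget is drawn from
  event-free epochs that start within 60 s of an event's end, the rest
  uniformly. Sensor detachments are Poisson-placed annotation intervals
  (20–90 s); they mark epochs for exclusion but do not corrupt the
  signals themselves — a deliberate simplification.
* **Randomness.** One root seed per subject is expanded into named
  per-channel streams, and each event draws from a stream keyed by its
  own identity, so adding a channel or removing one event never
  perturbs anything else. `effect_size` scales every event's deviation
  from baseline physiology; 0 removes the events' signature entirely
  (the null used for calibration), 1 is the full clinical effect.

What the generator does **not** emulate: real sleep architecture beyond
a wake flag, movement and electrode artefacts, inter-scorer label
noise, CPAP signatures, position-dependent event clustering, and the
physiological diversity of a clinical cohort. Passing tests on this
cohort therefore demonstrate that the pipeline recovers structure it is
designed to recover under clean, known physiology — not clinical
performance on real recordings.

## The feature bank

Features are organised as named registries. `subset_b_detection` (32
features: thoracic 16, SpO2 9, audio 4, EOG 3) backs the detection
cases; `subset_iii_distinction` (44 features: ECG 18, thoracic 12,
SpO2 9, audio 4, position 1) backs the distinction case; `full_bank`
is their union and is what the class-structure analysis uses.

Numerical definitions worth noting:

* **Welch spectra** use 4-s Hann segments with 50% overlap and density
  scaling (band power integrates to variance). The thoracic
  respiration band (0.05–1 Hz) alone uses 16-s segments: with 4-s
  segments the band contains four 0.25-Hz bins and the median/peak
  frequencies degenerate to constants across epochs.
* **Peak statistics** use local maxima with topographic prominence at
  least 10% of the epoch range and 1-s minimum separation; peak heights
  are measured from the epoch median (making them offset-invariant);
  inter-peak distances are in seconds, 0 and flagged with fewer than
  two peaks.
* **Renyi entropy** (order 2) is taken over the normalized Welch PSD —
  a deterministic, bin-free definition given the fixed Welch grid — so
  it measures spectral concentration: low for clean respiration, high
  for broadband or frequency-modulated effort.
* **Approximate entropy** follows the Pincus convention (self-matches
  included), with `r` a fraction (0.15 or 0.25) of the series SD. A
  30-sample epoch under-determines ApEn(m = 2), so the oximetry ApEn is
  computed on the 1 Hz SpO2 series over a sliding context of the
  current plus three preceding epochs (up to 120 samples), attributed
  to the current epoch.
* **Delta index** uses the conventional 12-s windows (consecutive,
  last partial window kept); **TSA95** is the fraction of the epoch
  below 95% saturation (a time fraction, not absolute seconds).
* **"M2"** is read as the second central moment of the SpO2 epoch, and
  **"min PH"** as the minimum prominence-qualified peak height.
* **The ECG wavelet block** uses a five-level Daubechies-4 (8-tap)
  decomposition with periodization, odd lengths extended by repeating
  the last sample; MAD is the mean absolute deviation from the median.
  The transform is hand-implemented (no wavelet package is declared)
  and is verified in the tests against an independent direct-summation
  oracle.
* **RR intervals** come from derivative-energy beat detection (squared
  first difference, 150-ms smoothing, adaptive threshold, 250-ms
  refractory period). Epochs with fewer than two beats yield NA,
  flagged; flagged values are imputed with training-split medians
  inside the modelling stage, and the imputation mask is retained in
  the `flagged` assay.

## Feature selection and the class-structure analysis

`zscoreTable` normalizes with training-split statistics only (n−1 SD;
zero-variance columns are dropped with a warning). `pcaCovariance`
eigendecomposes the sample covariance — after z-scoring this is the
correlation eigenproblem, and the tests assert that identity — with a
deterministic sign convention (largest-magnitude loading positive).
`selectByLoadings` takes the smallest set of leading components
reaching the cumulative-variance target (default 0.9) and retains the
union of each component's `top_k_per_pc` (default 10)
largest-|loading| features. The defaults are package choices — the
retention thresholds behind the published 78/32/44 subsets are not
derivable from the printed material, which is also why those subsets
are shipped as fixed registries rather than re-derived.

`manovaDendrogram` computes Mahalanobis distances between class mean
vectors under the pooled within-class covariance (ridged by
`1e-6 * trace/p` if singular) and agglomerates the five classes.
**Single linkage** is the default. Two reasons: it is the convention of
the standard MANOVA-dendrogram implementations; and with an
intermediate phenotype in the data it is the only linkage that behaves
sensibly here. MSA is by construction half central, half obstructive,
so it chains OSA to CSA, while OSA and CSA themselves sit at opposite
extremes of the thoracic and audio axes — under complete linkage the
apnea group's diameter (the OSA–CSA distance) always exceeds the
OSA-to-NORMAL distance and the apnea trio can never form first.
Wilks' lambda is computed and reported, but only the distance structure
feeds the pipeline.

## Splitting, balancing, models

Subjects are split 70/30 (train/test) at the subject level, so no
subject contributes epochs to both sides; cross-validation folds inside
the training set are likewise grouped by subject. Detection cases keep
every apnea epoch and subsample negatives to parity (if negatives are
the minority the direction flips, with a message). The distinction case
keeps all MSA epochs and subsamples OSA and CSA to preserve their
full-table ratios to MSA, rescaled so the largest class stays within
`cap` (default 5) times the MSA count — one concrete reading of an
ambiguous proportion rule, exposed as a parameter. Balancing is
re-drawn per evaluation repeat from a fresh substream, so the reported
SD reflects sampling (and search) variability.

Five families are tuned by random search — an open choice documented
here; each drawn configuration is scored by subject-grouped 5-fold CV
accuracy and the best is refit on all training rows:

| family | space |
|---|---|
| decision_tree | `maxdepth` 1–30, `minbucket` 1–50 (rpart, cp = 1e-4) |
| discriminant | linear vs quadratic (MASS) |
| naive_bayes | Gaussian (e1071) |
| svm | kernel linear/RBF, `cost` 10^[−2,2], `gamma` 10^[−3,1] (e1071) |
| knn | `k` 1–50, metric euclidean or cosine (class) |

The kNN cosine metric is realised exactly by L2-normalising rows before
the Euclidean backend; a city-block variant is not offered because no
declared backend provides it. The discriminant family exposes no
shrinkage parameter (MASS does not implement one); quadratic fits that
fail on a singular class covariance are scored as non-candidates.
Features are median-imputed and z-scored inside each fit using
training-rows-only statistics (per fold during CV).

`evaluateCase` aggregates the five metrics (sensitivity, specificity,
PPV, NPV, accuracy; zero-denominator ratios are NA, never 0) as
mean ± SD over repeats and selects the best family as the one
maximising min(sens, spec) among families whose mean accuracy is
within one SD of the best — a concrete reading of "best tradeoff
between diagnostic accuracy and balanced sensitivity and specificity".
On the exactly balanced test sets the identity ACC = (SENS + SPEC)/2
holds per repeat and is asserted in the tests.

## Problem sizes and calibration

The test suite exercises the full pipeline on a 40-subject cohort of
4-h nights at 15 events/h with full effect size (about 19,000 retained
epochs), on which the tuned linear SVM reaches ≥ 0.90 balanced
accuracy for case i, the label-shuffled null stays at chance within
3 SD, and the class-mean dendrogram's top split separates
{NORMAL, HYP} from {OSA, CSA, MSA}. A three-point sweep of
`effect_size` (0, 0.5, 1) on smaller cohorts checks that accuracy
degrades monotonically to chance as the planted effect vanishes —
the calibration that guards the whole pipeline against optimistic
leakage. Unit fixtures use one 0.5-h recording and a 6-subject,
0.75-h cohort. `scripts/acceptance.R` re-runs the three case studies
and the dendrogram check at the same 40-subject scale.

## Known limitations

* The generator's class geometry is a model of the described
  physiology, not of any archive; absolute accuracies on it say
  nothing quantitative about clinical recordings.
* The 78-feature intermediate subset cannot be reconstructed from the
  printed material and is not shipped.
* Hyperparameter search is random, not Bayesian; with the small spaces
  above the difference is immaterial at the budgets used.
* EDF+ support covers the package's own schema (seven named channels,
  one annotation channel) — it is not a general-purpose EDF reader.
* Detachment intervals annotate but do not corrupt signals; real
  artefact detection is out of scope.
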