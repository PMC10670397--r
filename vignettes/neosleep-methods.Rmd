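---
title: "Methods: simulating and classifying preterm-infant sleep states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying preterm-infant sleep states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Preterm infants in neonatal intensive care spend most of their time asleep, and
the distribution of **active sleep (AS)**, **quiet sleep (QS)** and
**caretaking/wake (CTW)** epochs is a clinically meaningful marker of brain
maturation. Behavioral sleep scoring is labor-intensive, so this package
implements an automated pipeline: 30-second epochs of routinely available
signals — ECG, respiratory effort, their interaction, and video-derived motion
— are summarized by 91 features and classified with extremely randomized
trees, evaluated under leave-one-subject-out (LOSO) cross-validation.

Because no real NICU recordings can ship with the package, a physiologically
structured simulator is a first-class component: it generates annotated
multimodal recordings whose state-conditional statistics mirror the
qualitative contrasts the classifier exploits, so the full pipeline can be
exercised, tested and calibrated end to end.

```{r setup}
library(neosleep)
```

# The recording simulator

`simulate_recording()` draws, in order:

1. **A hypnogram** (`generate_hypnogram()`): an epoch-level Markov chain whose
   bout lengths are geometric with configurable means and whose long-run state
   mix equals the configured fractions exactly. The transition matrix is built
   by Sinkhorn-balancing the inter-state exit flows `f_s = pi_s / L_s`
   (`pi` = stationary fraction, `L` = mean bout length), then setting
   `P(s -> s) = 1 - 1/L_s`. Defaults: AS 72% / QS 12% / CTW 16% with mean
   bouts of 20 / 10 / 5 epochs — the skewed state mix typical of preterm
   sleep, which is also why class balancing (SMOTE) is part of the pipeline.
2. **R-peak times** (`generate_rpeaks()`): truncated-Gaussian inter-beat
   intervals with state-specific mean and SD, plus Poisson-arriving heart-rate
   decelerations that prolong a short run of 3-6 intervals by a state-specific
   fraction. Decelerations are a hallmark of preterm HRV and give the
   deceleration features something real to detect.
3. **Respiratory effort** (`generate_respiration()`): concatenated breath
   cycles with jittered period and amplitude; each cycle is an asymmetric
   raised cosine (inhale 40% / exhale 60%) so peak/trough, flow and volume
   proxies are non-degenerate.
4. **Motion counts** (`generate_motion()`): Poisson-arriving Hann-shaped
   bursts (0.5-2 s) at a state-specific rate; zero between bursts, like a
   thresholded video-actigraphy count.
5. Optionally a **raw ECG waveform** (`generate_ecg_waveform()`): Gaussian
   baseline noise plus a Ricker-wavelet QRS template at each R time, enough
   structure for the R-peak detector and the waveform features to operate on.

Default state parameters (see `?state_params` and
`neosleep:::default_state_params`) encode the standard contrasts: QS has the
longest and most regular RR intervals, the most regular breathing and almost
no movement; AS has shorter, more variable RR and irregular breathing with
occasional movement; CTW is like AS cardiorespiratorily but with an order of
magnitude more movement. That makes AS vs QS mainly a cardiorespiratory
problem and sleep vs CTW mainly a motion problem — the structure the
directional acceptance tests check.

`simulate_cohort()` adds mild between-subject heterogeneity (lognormal jitter,
SD 8%, on six physiological parameters) so LOSO evaluation faces genuine
subject shift.

**What the simulator does not emulate:** waveform morphology beyond a QRS
spike (no P/T waves, no electrode artifacts), apneas and periodic breathing,
state-transition physiology (parameters switch instantaneously at epoch
boundaries), circadian/ultradian trends, or any correlation between movement
and cardiorespiratory disturbance within a state. Absolute classifier
performance on simulated data therefore does not transfer to real recordings;
relative statements (feature-set orderings, calibration) are the quantities of
interest.

# The 91 features

`feature_registry()` is the authoritative machine-readable inventory
(name, family, description, units). Counts per family: 34 cardiac, 41
respiratory, 8 cardiorespiratory-interaction, 8 motion.

## Cardiac (34)

From the epoch's R-peak train (detected from ECG by a Pan-Tompkins-style
detector when not supplied): time-domain HRV statistics (mean/median/SD/CV/
range/IQR of RR, RMSSD, SDSD, pNN20, pNN50, heart-rate mean and SD);
frequency-domain band powers of the 4-Hz-resampled tachogram over
VLF 0.01-0.04, LF 0.04-0.2, HF 0.2-1.0, plus extended sHF 1.0-1.5 and
uHF 1.5-2.0 Hz bands (neonatal breathing reaches ~1 Hz, hence the extended
bands), total power, LF/HF and normalized LF/HF; ECG line length (total and
per-1-s-window mean/SD); deceleration fraction and magnitude (runs of at
least 2 beats at least 10% above a 15-beat running-median baseline); sample
entropy (m = 2, r = 0.2 SD), its area under the tolerance curve over
r in {0.10, ..., 0.30} SD, and quadratic sample entropy of the RR series; and
Lempel-Ziv complexity of the binarized ECG (decimated to 125 Hz) and of the
RR series.

## Respiratory (41)

The effort signal is segmented into breaths by alternating peak/trough
detection with prominence pruning (threshold 0.2 epoch SD, minimum period
0.5 s). Features: breath-frequency statistics; breath-by-breath shape
correlations (each consecutive pair resampled to 40 points); Welch-spectrum
band powers over VLF 0.01-0.05, LF 0.05-0.15, HF 0.15-0.5 Hz (log,
normalized, ratios, dominant frequency); standardized peak/trough amplitudes
and their approximate entropies (m = 1, r = 0.2 SD); per-breath flow and
volume proxies (trapezoidal integrals of the rectified limbs) with
inhale:exhale time and flow ratios in both ratio-of-medians and
median-of-ratios forms; amplitude-ratio statistics; and sample entropy of the
2-Hz-downsampled signal.

## Cardiorespiratory interaction (8)

The CRI series samples the respiratory amplitude at each R-peak time
(`build_cri()`), capturing how breathing modulates the beat sequence. Its
**natural visibility graph** (strict criterion; real R times as the time
axis) is summarized by degree mean/SD, the same for the differenced series'
graph, Newman degree assortativity, local clustering mean/SD, and sample
entropy of the degree sequence. Epochs with fewer than 4 beats yield NA.

## Motion (8)

Per-epoch mean, SD, sum, and P25/P50/P75/P95 of the motion values, plus an
activity count (number of nonzero samples) smoothed **across epochs** by an
EWMA with alpha = 0.3 — the only feature with memory beyond its epoch,
mirroring how nurses judge "recent" activity. `motion_from_frames()` maps raw
grayscale video frames to motion values by 16x16-block differencing when
counts are not directly available.

# Numerical choices

* **Sample entropy** follows Richman-Moorman exactly: templates are the first
  N-m windows, distance strictly below r, self-matches excluded; verified
  against a brute-force oracle. **Approximate entropy** follows Pincus
  (<= r, self-matches included).
* **SampEn AUC**: at small tolerances short RR series often have length-m
  matches but none at length m+1; such grid points take the maximum
  resolvable value `-log(2/((N-m-1)(N-m)))` instead of poisoning the whole
  integral with NA. The AUC is NA only when some grid point has no length-m
  matches at all.
* **LZ76** uses the exhaustive production-history parsing. Note a constant
  series has complexity 2 (the innovative first symbol plus one reproducible
  run), and the classic example 0001101001000101 parses to 6 phrases; both
  are pinned in tests against a brute-force oracle. The ECG is decimated to
  125 Hz before parsing — the binarized-at-median sequence is dominated by
  QRS crossings, which survive decimation, and the exhaustive parse is
  quadratic in the worst case.
* **Welch PSD** (hand-rolled on `stats::fft`, since the installed stack lacks
  one): Hann window, 50% overlap, per-segment mean removal, one-sided density
  scaled so `sum(psd) * df` equals the variance; verified against analytic
  tones and white-noise Parseval checks.
* **Visibility graphs** use the strict inequality (collinear points block
  visibility) and run in O(n^2) via a running maximum slope; verified against
  an O(n^3) oracle and igraph for the derived statistics.
* **EDF storage** quantizes to 16-bit integers over the per-signal physical
  range; round trips are exact to one quantization step. Channel sampling
  rates must be integers per second (1-s records).
* Missing features propagate as NA out of the extractor; **median imputation
  is fitted per CV fold on the training partition only**.

# The classifier and evaluation

`run_experiment()` evaluates feature sets x tasks under LOSO:

* **Folds**: one per subject; the training partition never contains the test
  subject (asserted structurally).
* **SMOTE** (`smote_oversample()`): minority classes are raised to the
  majority count by interpolating between a minority row and one of its k = 5
  nearest same-class neighbors (Euclidean distance on globally standardized
  features, interpolation in original space). Applied after the split, to the
  training partition only — oversampling before splitting leaks synthetic
  copies of test information.
* **Extremely randomized trees** via `ranger`: `splitrule = "extratrees"`
  with 1 random split per candidate feature, no bootstrap
  (`replace = FALSE, sample.fraction = 1`), all features as candidates
  (`mtry = p`), 100 trees, probability forest, Gini importances. ET's random
  thresholds decorrelate trees without bootstrap resampling and are cheap in
  high feature dimensions.
* **Metrics**: Cohen's kappa (chance-corrected agreement; the primary metric
  because the 72/12/16 class mix makes accuracy misleading), accuracy,
  one-vs-rest AUC (rank statistic with mid-rank ties), pooled confusion
  matrices, and per-fold normalized Gini importances.
* **Tasks**: the 3-class problem AS-QS-CTW and the pairwise problems AS-QS,
  QS-CTW, AS-CTW and Sleep-CTW (AS+QS merged).
* `null_kappa()` re-runs the pipeline on globally shuffled labels as a
  leakage check; its mean LOSO kappa must sit near zero.

# Problem sizes

Defaults follow the study conditions the package models: recordings of 589
epochs (~4.9 h) at 500/16/8 Hz and cohorts of 8 subjects. The test suite uses
deliberately smaller sizes chosen for runtime, as the package's own choice:
single-state recordings of 1-300 epochs for feature unit tests, and for the
directional acceptance claims three cohorts (seeds 2001-2003) of 6 subjects x
100 epochs with 60-tree forests. `scripts/acceptance.R` runs the full-scale
default cohort.

# Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_epochs = 120, seed = 42)
cohort <- simulate_cohort(4, cfg, seed = 42)
features <- assemble_features(cohort)
ev <- run_experiment(features,
                     feature_sets = default_feature_sets(),
                     tasks = c("AS-QS-CTW", "AS-QS", "Sleep-CTW"),
                     seed = 42)
print(ev)
summary(ev, task = "AS-QS-CTW")
plot(ev, feature_set = "ECG-Resp-CRI-Motion", task = "AS-QS-CTW")
```

# Limitations

* Synthetic data only: all reported performance characterizes the simulator,
  not clinical recordings; only relative/structural claims should be read.
* The simulator's state contrasts are stylized; in real data AS/QS overlap is
  larger and annotations are noisy.
* The feature registry fixes one reasonable realization of the 91-feature
  inventory; several respiratory features come in closely related variants.
* LOSO with 8 subjects yields wide kappa SDs; fold-level numbers are noisy by
  construction.
* The EDF writer covers the minimal continuous 16-bit subset only (no
  annotations channel, integer samples-per-second).
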