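---
title: "Classifying resting-state EEG with time-frequency CNNs: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying resting-state EEG with time-frequency CNNs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`eegcnn` implements a complete two-group classification pipeline for
resting-state EEG: synthetic cohort generation, artifact-aware
preprocessing, Morlet time-frequency features, an epoch-level convolutional
network and a band-power SVM baseline evaluated under leave-one-subject-out
(LOSO) cross-validation with subject-level probability aggregation, and a
late-fusion stage that stacks the EEG score with clinical/demographic
covariates. This vignette explains the underlying models, the tunable
parameters, and the design decisions taken where the design was genuinely
open. It states no empirical results beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## The classification problem

Each subject contributes one multichannel resting (eyes-open) EEG recording
and a binary diagnosis label (0 = healthy control, 1 = patient). Because
cohorts in this setting are small (tens of subjects), the classifiers are
trained on 4-second *epochs* — overlapping segments treated as exchangeable
training instances — and evaluated at the subject level: under LOSO, every
epoch of exactly one subject is held out, the model trains on all epochs of
the remaining subjects, the held-out epochs receive class-1 probabilities,
and their arithmetic mean becomes the subject's *EEG score*. A subject is
predicted positive iff the score strictly exceeds 0.5 (a tied score maps to
the control class). Epochs of one subject are strongly dependent, which is
precisely why no epoch of the test subject may influence training,
standardization, or early stopping.

## Synthetic cohorts

No public data accompany this problem setting, so the package ships a
seeded generator (`generate_cohort()`) whose defaults mirror a small
case-control study: 10 + 10 subjects, 68 EEG + 2 EOG channels, 1024 Hz,
240 s. A `"test"` preset (8 EEG + 2 EOG, 256 Hz, 60 s) keeps the full
pipeline runnable in minutes on one core; all scaled-down results quoted by
the test suite and the acceptance script use this preset with 20 subjects,
a 16-frequency TFR grid, and the network trained for at most 12 passes
(early stopping with patience 3 after a 6-pass burn-in). Those problem
sizes are the package's chosen study conditions for desk-scale
reproducibility.

Each recording is a sum of:

* **1/f^β background noise** per channel (FFT-shaped white noise,
  β = 1.2 by default, ~9 µV RMS) plus 2 µV white sensor noise;
* an **occipital-dominant 10 Hz rhythm** with a slow waxing/waning
  amplitude envelope (~14 µV RMS at the occipital pole) — standard
  eyes-open phenomenology;
* **blink artifacts**: 300–500 ms raised-cosine transients with a
  frontal-dominant topography and 3× amplified copies on the EOG channels
  (`inject_blinks()`, default 12/min);
* **noise bursts**: sporadic high-amplitude transients whose spans are
  recorded as ground truth for rejection tests (`inject_noise_bursts()`).

Channel topography is abstracted to a normalized frontal→occipital axis;
no forward modeling is attempted (a stated non-goal). Covariates (DOCS,
MIS, BAI, BDI-II totals, age, sex, education) are drawn per group from
moment-matched scaled Beta distributions on each instrument's documented
range, so the configured group means and SDs are exact distribution moments
— a truncated Gaussian would bias the mean of the skewed instruments near
their floor. Values are kept continuous rather than integer-rounded for the
same reason. By default one subject lacks an age value and two lack MIS
scores, mirroring typical small-cohort missingness.

### The two group effects

`effect_kind = "band_power"` adds a narrowband 4–8 Hz component to a fixed
fronto-central channel subset, with class-1 power multiplied by
`1 + effect_size`. Both a band-power classifier and the CNN should detect
this.

`effect_kind = "spectrotemporal"` is the delicate one: a group effect that
time-frequency *patterns* can express but per-channel band power cannot.
Every channel receives four short (0.3 s) 6 Hz bursts per 2 s span on a
dipolar topography; in class 1 the burst onsets are shared across channels
(sub-second cross-channel synchrony), in class 0 each channel bursts at
independent times. Phases and per-burst amplitudes are independent per
channel in both groups, so each channel's marginal burst process is
identical in distribution across groups. Three guards keep the effect
band-power-neutral through the *whole* pipeline, each of which proved
necessary during development:

1. the burst topography sums to zero across channels and the burst field is
   projected to zero instantaneous channel mean, so common-average
   referencing attenuates neither group preferentially;
2. burst timing is uniformly distributed in both groups and many
   independent position draws occur per epoch, so the position-dependent
   Hann weighting of the Welch estimator averages out instead of inducing
   a group-specific covariance among band-power features;
3. after generation, every subject's long-run mean power in each canonical
   band and channel is rescaled to the cohort mean profile. The
   normalization is per subject rather than per group on purpose: any
   factor applied uniformly to one group becomes a group signature wherever
   referencing is sensitive to small topography perturbations (the
   common-average alpha weight nearly cancels on one channel, and a 2%
   rescaling there changes post-reference power by tens of percent). The
   resulting between-group band-power ratio is asserted within 2%, with an
   error on violation.

The generator also records every burst onset, and a synchrony statistic
(`burst_timing_statistic()`) separates the groups by construction — this is
the signal the CNN must find.

What the generator does *not* emulate: volume conduction and realistic
covariance between neighboring electrodes, heartbeat artifacts,
non-stationary drowsiness effects, impedance drift, or any clinically
validated link between covariates and EEG. Passing tests therefore show
that the pipeline recovers the *kind* of structure each classifier is
sensitive to — not that real patients are classifiable at these rates.

## Preprocessing

`preprocess_recording()` runs a fixed, audited order: filter → crop → ICA
ocular removal → common-average reference → segment → reject.

* **Filtering**: a 60 Hz notch (band-stop 55–65 Hz) followed by a
  0.5–50 Hz band-pass, both windowed-sinc (Hamming) FIR kernels convolved
  into one symmetric kernel and applied by FFT convolution with exact
  group-delay compensation — zero phase without the doubled attenuation of
  forward-backward filtering. Transition bandwidths follow common
  windowed-design auto-selection from the cutoffs. Edges are zero-padded;
  the first and last fraction of a second are therefore attenuated, which
  is immaterial after cropping and epoching.
* **ICA**: `ica::icafast` (FastICA, deterministic initialization) yields
  `n_ica_components` sources (default 15). Each source is scored by its
  maximum absolute correlation with any EOG channel. A component is removed
  when its score is an outlier relative to the *other* components — a
  leave-one-out z-score above `eog_match_threshold` (default 3.0) — and
  exceeds an absolute floor of 0.15. The leave-one-out form matters: with
  few components, a single strong ocular component caps the ordinary
  z-score below 3 (at 8 components the maximum attainable is ≈ 2.5), so the
  conventional rule can never fire at reduced channel counts. The absolute
  floor keeps pure-noise outliers from being flagged on blink-free data.
* **Referencing**: every EEG channel minus the instantaneous channel mean.
* **Epoching**: 4 s windows with 2 s overlap; `floor((T − L)/S) + 1` fully
  contained windows (240 s yields 119).
* **Rejection**: an epoch is kept iff the peak-to-peak amplitude of every
  EEG channel is ≤ 300 µV. EOG channels are excluded from the criterion.
  Separately, `subject_exclusion_report()` flags subjects failing a
  stricter 250 µV screen on most epochs — the two thresholds play distinct
  roles (epoch hygiene vs subject exclusion) and are kept distinct.

## Time-frequency features

`tfr_features()` computes complex Morlet wavelet power at 40
logarithmically spaced frequencies from 1 to 45 Hz with
`n_cycles = f / 2`, decimates the temporal axis by 16 (sample picking,
matching the transform's `decim` semantics, not low-pass resampling), adds
no baseline correction, and log-transforms as `10·log10(power + 1e-10)`.
Output is channels-last: `(epochs, frequencies, time points, channels)` —
40 × 256 × 68 per epoch at the default scale.

Because `n_cycles` is proportional to frequency, every wavelet shares one
temporal envelope width, `σ_t = 1/(2π·2) ≈ 0.08 s`; the implementation
exploits this to compute all frequencies at the decimated sample points
with a single windowed matrix product per epoch, exactly equal to
full-resolution convolution subsampled at those points (a tested
invariant). Wavelets are zero-mean corrected and L2-normalized, so power is
in arbitrary dB-like units. Two caveats are inherited deliberately rather
than repaired: at 1 Hz the rule gives 0.5 cycles, i.e. very poor spectral
resolution at the lowest frequencies, and no edge trimming is applied, so
the outermost ~0.25 s of each epoch sits inside the wavelet's
cone of influence.

## The epoch-level classifiers

**CNN.** Two convolutional blocks — conv(16, 3×5) → ReLU → batch
normalization → max-pool(2×2) → dropout(0.4), then the same with 32 filters
— followed by flatten and a single sigmoid unit; binary cross-entropy loss;
Adam (lr 0.001), batch size 32. Valid (no) padding is used, the usual
default where unstated. The activation-before-normalization order is
implemented as specified even though conv→BN→ReLU is more common; a flag
(`activation_before_bn = FALSE`) swaps it. With no deep-learning framework
in the dependency set, the network is implemented in the package itself:
im2col + BLAS matrix products with C++ helpers for data movement, exact
backpropagation (validated against finite differences in the test suite),
inverted dropout, and batch-norm running statistics for deterministic
inference. Training is bit-reproducible from the seed in `cnn_spec()`.

Early stopping was genuinely open: the number of passes is unstated in the
protocol being modeled, and monitoring the held-out subject leaks test data
into the stopping decision. The default (`early_stop = "internal_val"`)
therefore carves a validation split from *training* subjects (~15% of
subjects per fold), stops after `patience` non-improving passes once a
burn-in of `min_train_epochs` passes has elapsed, and restores the best
weights. The burn-in exists because the synchrony signal is found only
after a few passes; without it, patience can expire while the validation
loss is still flat. A clearly labeled
`early_stop = "paper_faithful_test_monitor"` mode reproduces the leaky
test-monitoring protocol for comparison, and `"none"` trains for a fixed
number of passes.

**SVM baseline.** Per epoch and channel, mean Welch power (2 s Hann
segments, 50% overlap, constant detrend, one-sided density) in delta,
theta, alpha, beta and gamma bands — 5 features per channel, channel-major
order — feeds an RBF SVM (`e1071`): C = 1, the `1/(n_features·var(X))`
gamma rule, inverse-frequency class weights, Platt probability outputs.
No installed R package exposes a Welch estimator, so the segment-averaged
periodogram is implemented directly on `stats::fft` and cross-checked
against a direct periodogram oracle in the tests.

**Per-fold standardization.** Features are z-scored elementwise over the
flattened feature vector (frequency × time × channel for the CNN; columns
for the SVM), with mean and population SD estimated on training epochs only
and applied frozen to the held-out epochs. Zero-variance features are
centered but not divided. Whether the standardization being modeled acted
elementwise on flattened tensors or per channel is unknowable from the
protocol description; elementwise-flattened is this package's documented
assumption.

## LOSO orchestration and leakage control

`run_loso()` builds one fold per subject (ordered by id), derives the fold
seed as `seed + fold_id` so results are independent of execution order,
fits scaler and classifier on training subjects only, and aggregates
held-out epoch probabilities into subject scores. Per-fold records
(epoch probabilities, scaler, fit metadata) are persisted in the result so
every downstream report — including the fusion stage — is recomputable
without retraining. The test suite includes mutation oracles: altering the
held-out subject's data must leave the fold's scaler and (under internal
validation) the trained weights bit-identical.

## Late fusion

`run_fusion_loso()` stacks the subject-level EEG score with one covariate
at a time: per fold, numeric inputs are z-scored and categorical inputs
one-hot encoded with parameters from the training rows (categories unseen
in training map to all-zero rows — likely at n = 20), then a
ridge-penalized logistic regression (Newton/IRLS, intercept unpenalized,
unit penalty semantics equivalent to the conventional C = 1 default)
predicts the held-out subject. glmnet cannot fit a single-column design,
which the EEG-only baseline requires, so the solver lives in the package.
Missing covariate values are handled by listwise deletion per feature; the
remaining N is reported. Change labels (`Improved`/`None`/`Worse`) compare
AUCs at two-decimal reporting precision.

One property discovered while testing deserves emphasis: pooled-LOSO
probabilities of a one-feature logistic model sit systematically *below*
the raw score's pairwise-concordance AUC when the score is weakly
separating, because each held-out subject's fold trains with one fewer
member of its own class, biasing the intercept against it. The equality of
pooled AUC and concordance holds only for clearly separated scores; the
tests assert equality there and a no-inflation bound elsewhere.

## Metrics

Confusion counts, per-class precision/recall/F1 with support, accuracy,
macro and support-weighted averages, and Mann–Whitney AUC (ties counted ½,
required for the all-equal degenerate case). Zero-denominator metrics are
reported as 0 and flagged. Display rounding is half-even at two decimals;
internal values keep full precision. Where a published-style table reports
a single precision/recall/F1 per model, the macro average is used —
consistent with a balanced-cohort baseline row whose three values equal its
accuracy.

## Numerical and engineering choices

* Scaled Beta covariate sampling solves `α, β` from the exact mean/SD;
  infeasible SDs (σ² ≥ μ(1−μ) in unit scale) are shrunk to the boundary.
* The EDF writer/reader is a minimal 16-bit dialect (ASCII headers,
  one-second records, per-channel physical scaling) sufficient for
  round-tripping synthetic cohorts with CSV/JSON sidecars; it is not a
  general-purpose EDF implementation.
* BN uses ε = 1e-5, momentum 0.9; Adam uses the conventional
  (0.9, 0.999, 1e-8).
* Batches of size 1 are skipped (batch-norm variance is undefined);
  the last partial batch is otherwise used.
* The rejection boundary is inclusive (`p2p ≤ threshold` keeps the epoch),
  matching a strict reading of "exceeded ... was discarded".

## Known limitations

* The generator's channel axis is a 1-D abstraction; spatial filters
  learned on it do not transfer to real montages.
* The CNN is small but still heavily over-parameterized for scaled-down
  cohorts; per-fold training can memorize training subjects, which is why
  only subject-level held-out metrics are meaningful.
* The spectrotemporal effect's band-power neutrality is enforced to 2% on
  long-run means; higher-order epoch-feature statistics differ slightly
  between groups in principle (an RBF kernel could in theory exploit
  residual covariance structure), so the SVM's chance-level behavior is a
  property of the chosen amplitudes and burst counts, verified empirically
  by the acceptance tests, not a theorem.
* Nested cross-validation and hyperparameter search are out of scope.
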