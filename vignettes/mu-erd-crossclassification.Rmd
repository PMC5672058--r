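---
title: "Mu-rhythm ERD and cross-classification: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mu-rhythm ERD and cross-classification: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mucross)
```

## The scientific question

When a brain–computer interface decodes *motor commands* from the
sensorimotor mu rhythm (8–13 Hz), how much of what it decodes is really
efferent motor activity, and how much is the processing of *afferent
somatosensory feedback*?  Both attenuate the mu rhythm over sensorimotor
cortex.  The package implements the complete analysis that addresses this
question with two experimental conditions against a rest baseline:

* **MT** — an isometric grip motor task at two force levels
  (2.5 N ± 20% and 6.5 N ± 10% per finger), which mixes efferent and
  afferent activity;
* **SS** — electrical fingertip stimulation at two intensities, which
  provides afferent input without any motor command;
* **REST** — no task; rest trials recorded within motor blocks and within
  stimulation blocks are kept apart and serve as *individual baselines*
  for their own block type.

Analysis proceeds in five stages, each a module of this package:
preprocessing, trial epoching, spectral ERD quantification, linear
discriminant decoding with cross-classification, and group statistics.
Because no public recordings exist for this design, a synthetic-data
generator reproduces the statistical structure the analysis assumes, with
known ground truth, so every stage is verifiable end to end.

## ERD quantification

For each successful trial, the 2-s window starting 0.5 s after action-phase
onset is Fourier transformed per electrode (rectangular window, 0.5 Hz
bins at 128 Hz).  The *activation* of electrode $q$ in a condition is the
double average of the amplitude spectrum over the $M$ band bins and the
$L$ trials,

$$E_q = \frac{1}{M}\frac{1}{L}\sum_{n=1}^{M}\sum_{k=1}^{L} x_{nk},$$

and the relative power change against the origin-matched rest baseline is

$$\%\text{Power}_E = \frac{\mathrm{exp}_E - \mathrm{rest}_E}{\mathrm{rest}_E},$$

negative values being event-related desynchronization (ERD), positive
event-related synchronization (ERS).  Bands are alpha 8–13 Hz and beta
14–30 Hz with inclusive bin edges: a 13.0 Hz bin belongs to alpha, 13.5 Hz
to neither band.  The band edges change $M$, so this convention is part of
the estimator's definition.  "Amplitude" is the FFT magnitude (the
equation's convention); a power-spectral reading and a Hann taper are
available as options but all defaults and tests use magnitude and the
rectangular window.

Per-electrode significance in `erd_scalp_map()` is a Welch t-test on the
per-trial log band amplitudes — a pragmatic single-subject annotation, not
the group-level inference (which is the ANOVA module's job).

## Preprocessing

The stage order is fixed: band-pass + notch filter → decimation to 128 Hz
→ artifact masking → ocular subtraction → common average reference.

**Filter.**  The nominal band is 0.5–40 Hz with a 36–39 Hz notch against
narrowband interference at 37.5 Hz.  The realization is a *zero-phase
frequency-domain* filter whose amplitude response is the forward–backward
(magnitude-squared) response of a Butterworth cascade: high-pass order 2
at 0.4 Hz, low-pass order 8 at 41 Hz, band-stop order 3 at 36.2–38.8 Hz.
Two remarks on why these are not the nominal numbers.  First, a
forward–backward 4th-order band-pass at exactly 0.5/40 Hz cannot
simultaneously keep 1–35 Hz within ±1 dB and attenuate ≥20 dB above
48 Hz — the squaring steepens the skirt but also doubles the pass-band
droop; the cutoffs therefore sit slightly outside the nominal band and the
low-pass order is raised.  Second, applying the exact squared magnitude in
the frequency domain (with reflection padding) is numerically identical to
filtfilt of that cascade but has no stability concerns at high order and
costs one FFT per channel.  The designed response is itself under test:
pass band 1–35 Hz within 1 dB, ≥20 dB at 37.5 Hz and everywhere above
48 Hz, zero group delay.

**Decimation** keeps every 4th sample (the signal is already band-limited
far below the new Nyquist frequency).  Event indices are integer-divided;
the validity mask is decimated conservatively (a target sample is invalid
if *any* source sample was).

**Artifact masking** is an automated stand-in for the visual artifact
screening such experiments use: a sample is flagged at |amplitude| >
100 µV or a sample-to-sample jump > 40 µV, padded by ±0.2 s, per channel.
Channels with more than 50% of samples flagged are excluded entirely; no
channel is hard-coded as bad — exclusion emerges from the rule.  The jump
threshold deserves a note: at 128 Hz, clean high-amplitude rhythmic
activity (alpha bursts of tens of µV) produces jumps approaching
25 µV/sample, so a 25 µV default would clip genuine rhythms and —
worse — selectively discard high-amplitude trials, biasing the rest
baseline.  40 µV/sample is unreachable by band-limited activity of
realistic amplitude yet far below electromyographic or movement
transients.  Both thresholds are configurable.

**Ocular subtraction** follows the calibration-template idea: before the
experiment, three eye-movement sequences (blinks, vertical, horizontal)
are recorded; the artifact subspace is the three leading principal
components of the calibration restricted to frontal channels, and
propagation coefficients to every channel are least-squares estimates.
At application time the sources are re-estimated by projecting the frontal
channels onto the calibration subspace.  Two safeguards keep the
subtraction from consuming neural signal, which a plain projection does
measurably (it removed ~15% of total RMS on artifact-free synthetic data):
the source estimates are low-passed at 8 Hz (ocular potentials are slow;
mu/beta rhythms pass through untouched), and subtraction is gated to
segments where a source exceeds 4 robust standard deviations — the
"automatic recognition" step — padded by 0.2 s.  On clean data the
recording passes through essentially unchanged; on data with injected
artifacts the correction removes most of the artifact energy (both
properties are tested against held-out clean copies).

**Common average reference** subtracts, per sample, the mean over
non-excluded channels valid at that sample.  It is idempotent and tested
against manual column-mean subtraction.

## Trial bookkeeping

A motor trial succeeds if the grip force stays inside the target interval
for at least 80% of the 3-s action phase — total time, on discrete samples,
with a `>=` comparison at the boundary (determinism at exactly 80%).  The
published criterion's "average force per finger" admits two readings; the
default compares the across-finger mean at each sample, and
`per_finger_strict = TRUE` requires each finger individually in range.
Failed trials produce no epoch; the generator re-queues them so the target
count of successes is reached, as the emulated protocol did.

## The synthetic subject

Each channel is a sum of three Gaussian processes plus transients:

* **1/f background**: one-sided PSD $c^2 (10/f)^{1.2}$ µV²/Hz, flattened
  below 0.5 Hz, with $c = 0.55$ µV/√Hz at 10 Hz (broadband RMS ≈ 4 µV);
* **mu/alpha** and **beta** oscillations: white noise shaped to
  4th-order Butterworth bands 8–13 Hz and 14–30 Hz, with per-electrode
  baseline RMS amplitudes (5 µV alpha over the scalp, 7 µV occipitally,
  3 µV frontally; 2.5 µV beta at sensorimotor sites, 1.5 µV elsewhere);
* **ocular transients**: blink and saccade templates with amplitudes
  decaying exponentially from the frontal row (80 µV peak, decay constant
  0.3 head radii), injected as a Poisson process (10/min blinks), plus a
  30-s calibration recording with the three canonical eye-movement
  sequences.

No dipole or forward head model is used: the published effect sizes are
electrode-level, so ERD is parameterized directly per electrode.  Trials
follow the protocol's timing (cue 0.3 s, break 2–4 s — 2 s in stimulation
blocks —, orientation 2.5 s, action 3 s, inter-trial 3 s) across six
blocks, motor and stimulation trials never mixed within a block.

**ERD injection.**  The defining subtlety: the published table entries are
*measured* relative decreases — oscillation plus in-band noise — whereas
the generator controls only the oscillator envelope.  During the action
phase of a non-rest trial the envelope at electrode $e$ is multiplied by a
gain $g$ chosen numerically (by `uniroot`) such that the *expected measured
band amplitude* equals $(1-d)$ times its rest expectation, where $d$ is the
table fraction.  The expectation accounts for the preprocessing filter
response, the Fejér-kernel smoothing of the 2-s rectangular analysis
window, the in-band 1/f noise floor, and the trial-to-trial lognormal
envelope variability (integrated by quadrature).  This makes parameter
recovery unbiased in expectation; what remains is sampling noise (≈1 pp
SEM over 20 × 50-trial runs) and two small uncorrected effects — the
common average reference mixes ~1/64 of the other channels into each
channel, and ocular correction perturbs frontal channels — both well
inside the ±3 pp acceptance band.  An ERD too deep for the noise floor
(the measured amplitude cannot fall below the background) raises an error
rather than silently clamping.

**Heterogeneity.**  Trial-to-trial amplitude variability is lognormal with
a global (all-electrode) log-SD of 0.20 and an independent per-channel
log-SD of 0.10.  These two numbers are the model's only free noise knobs;
the published study does not state them, so they were calibrated once so
that the synthetic cohort lands in the published decoding regime (motor
regular classifiers ≈ 75%, stimulation ≈ 61%, with ~90 trials per
classification) and then frozen.  Per-subject effect-size gain is
$\mathcal N(1, 0.15^2)$ truncated at 0.5; three of the thirteen cohort
subjects are simulated with gain 0, reproducing the observed fraction of
able-bodied subjects without usable mu modulation.  Those null subjects
are included in every cohort mean, as in the emulated study.

**What the generator does not emulate** — and therefore what passing tests
do *not* show about real recordings: no volume-conduction correlation
between channels (channels are independent up to the common reference),
no electrical stimulation artifact (stimulation trials differ from rest
only via their ERD pattern; the analysis band excludes the notch region
anyway), no non-stationarities such as drowsiness drift or impedance
changes, no harmonics or mu-rhythm arc shape.  Results on synthetic data
bound the pipeline's correctness, not real-world decoding performance.

## Decoding

Features are the per-trial alpha-band amplitudes at the 20 sensorimotor
electrodes (FC3…P3 in fixed order), optionally plus the same 20 beta-band
values.  (Published electrode lists sometimes print "CF3"; there is no CF
row in the 10-10 system and the package resolves it to FC3.)  The
classifier is closed-form two-class LDA with pooled covariance and
empirical priors; shrinkage is off by default, with automatic diagonal
loading only on numerical singularity (logged in the model object).  Ties
on the discriminant score go to REST.  Regular classifiers are evaluated
with stratified five-fold cross-validation (folds shuffled once from a
seed; fold confusion matrices summed).  Cross-classifiers train once on
condition-vs-rest of one modality and evaluate once on the other
modality's trials against *that* modality's own rest baseline — the
individual-baseline convention again.

Chance level is binomial: the smallest $k$ with
$F_{\mathrm{Binom}(n,0.5)}(k) \ge 0.95$, reported as $k/n$.  At $n = 90$
this is $53/90 \approx 58.9\%$, the conventional figure; the package
always computes it from each classification's actual $n$.  The cohort
default of 45 trials per condition keeps $n \approx 90$ precisely so that
the conventional threshold applies.

## Group statistics

`two_way_anova()` fits fixed-effects models: classical sequential sums of
squares when balanced (where the decomposition is unique), hierarchical
Type II otherwise; the interaction enters when every cell is replicated.
The factor structure is configurable because the original factor coding is
not recoverable from the text; defaults are condition × electrode for
power changes and classifier × feature-set for accuracies, and outputs are
labelled with the design used.  `tukey_kramer()` implements
studentized-range pairwise comparisons with the unequal-$n$ correction,
using R's numerical `ptukey` (valid for arbitrary df, no table lookup);
with equal group sizes it reproduces classical Tukey HSD exactly, and its
adjusted p-values are never smaller than the unadjusted pairwise t-test —
both properties are under test, along with a 1000-replicate null
simulation of the type-I error rate.

## Problem sizes and determinism

All randomness flows from a single integer seed per entry point; child
seeds for subjects and folds are derived arithmetically (and kept below
2³¹).  Identical configuration and seed give bit-identical recordings and
reports.  The problem sizes used by the shipped analyses were chosen as
the smallest that leave the estimators' sampling noise well inside the
tolerances they are compared against:

* *Parameter recovery* (`recover_erd()`): one subject, 50 trials per
  condition, 20 independent seeds, synthesized at 256 Hz with shortened
  inter-trial dead time.  The band-amplitude estimator is independent of
  the synthesis rate and dead time carries no signal, so this preserves
  the estimand while still exercising the decimation stage; the 512 Hz
  default and full trial timing remain the generator defaults.
* *Cohort study* (`scaled_study_config()`): 13 subjects, 45 trials per
  condition, synthesized directly at the 128 Hz analysis rate.  Subject-
  level replication (13 independent simulations, 3 of them null) provides
  the averaging for the qualitative cohort-level claims.

## Known limitations

* Electrode positions are a schematic 2D projection adequate for
  topography and spatial rules, not measured coordinates.
* The ocular model is three fixed spatial patterns; real ocular artifacts
  vary in topography, and the gated regression will not catch artifacts
  that never cross the detection threshold.
* Single-subject ERD p-values assume log-amplitudes approximately normal;
  they are annotations, not corrected inference.
* The EDF writer emits 16-bit EDF+ with 1-s records; recordings are
  zero-padded to whole seconds and the pad is visible on re-import.
* `fit_eog()` assumes the calibration and experimental recordings share
  the channel set and preprocessing state; the pipeline enforces this,
  manual use must.
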