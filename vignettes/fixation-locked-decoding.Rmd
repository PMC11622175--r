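---
title: "Fixation-locked multivariate decoding of free visual exploration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixation-locked multivariate decoding of free visual exploration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixdecode)
```

## The analysis problem

During free viewing, the eyes move about three times per second, leaving
roughly 200 ms of fixation in which the brain must identify the fixated
(foveal) object and select the next saccade goal from the parafovea
(2–5° of eccentricity). `fixdecode` implements the full analysis chain for
asking *what* the brain extracts about foveal and parafoveal objects within
that interval, from co-registered eye-tracking and multichannel sensor
(MEG-style) recordings:

1. detect saccades, blinks and fixations from gaze traces,
2. assign each fixation to an image of the display and derive four condition
   roles per fixation — the **foveal** image, the **upcoming** parafoveal
   image (next saccade goal), the **past** parafoveal image (previous
   fixation), and one **remaining** parafoveal image (never the previous or
   next target) — with the exclusion rules described below,
3. cut fixation-locked epochs from the continuous recording and clean them,
4. decode the color scale (gray vs color) and the category (animal vs food
   vs object) of each role's image, over time, with a sliding-window linear
   classifier,
5. test the group decoding curves against chance with a sign-flip
   max-t permutation procedure, and contrast peak latencies between roles.

Because no public dataset accompanies this design, the package ships a
first-class synthetic-study generator with known ground truth
(`simulate_study()`, `simulate_epochs()`): every stage can be validated by
parameter recovery rather than by eyeballing.

## The synthetic study

`synth_config()` encodes the study conditions: 36 participants, 10 blocks of
30 trials, 4-s trials showing seven 3°×3° images (one central, six on a ring
at 0–300° with a 1° border gap, hence 4° center-to-center), color scale and
category balanced across the seven slots as evenly as 7 slots allow (4/3 and
3/2/2), gaze and sensors at 1,000 Hz.

**Scan paths.** Fixation durations are gamma-distributed with mean 240 ms
and SD 36 ms — gamma because durations are positive and right-skewed, as
fixation data are. Saccades follow a minimum-jerk position profile. Their
nominal durations are drawn around `1000/rate − 240` ms (≈67 ms at the
default 3.26 saccades/s) but are capped at the longest duration for which
the profile's peak acceleration `5.77·A/T²` still exceeds the 8,000°/s²
detection threshold, so every simulated saccade is detectable by both the
velocity and the acceleration criterion. With the default geometry this cap
binds for most amplitudes, and the emergent rate is ≈3.4 saccades/s with
13–14 fixations per 4-s trial — inside the reported spreads
(3.26 ± 0.44 /s; 13.1 ± 1.6 fixations). Landing positions are jittered
around image centers (SD 0.5°, a free parameter: landing distributions
within images are not constrained by any reported value), and within-fixation
tremor is 0.02° by default.

**Sensor data.** The forward model is linear: at each fixation, each
configured `effect_spec()` adds `amplitude × spatial pattern × temporal
kernel(latency)` to the recording, where the spatial pattern is a unit-norm
Gaussian random vector per (role, dimension, class), fixed per participant.
Fresh patterns per participant create the across-participant pattern
variability that motivates time-delay embedding. The kernel is a Gaussian
bump (FWHM `width_ms`, transient codes) or a smoothed plateau (sustained
codes); the two reproduce, respectively, diagonal and square temporal
generalization. Noise is Gaussian, optionally mixed through a random channel
matrix so it is spatially correlated — the property that matters for a
multivariate classifier. The default effect latencies are the reported group
peaks: foveal color 100 ms, foveal category 145 ms (sustained), upcoming
color 112 ms, upcoming category 165 ms, past color 88 ms, past category
170 ms. Default amplitudes are chosen so that group decoding peaks fall in
the 0.6–0.8 AUC range observed empirically rather than saturating at 1.

What the generator does **not** emulate: 1/f spectral structure and
oscillations, eye-movement artifacts in the sensors, head movement, sensor
unit heterogeneity (all synthetic channels share one scale), and saliency-
or memory-driven scan-path statistics. Passing tests therefore demonstrate
correctness of the *analysis machinery* (labeling rules, calibration of the
statistics, latency recovery), not robustness to every pathology of real
recordings.

**Behavior.** One change-detection response per trial; the probability of a
correct response follows a logistic link in the number of fixations on the
target image around the base rate of 66.8%, and reaction times are
log-normal with slower incorrect responses (medians ≈2.8 s vs ≈4.0 s).

## Eye events

Velocity and acceleration are estimated by Savitzky–Golay differentiation
(cubic, 9-sample window) — noise-robust and standard. A sample is saccadic
when speed exceeds 30°/s **or** |acceleration| exceeds 8,000°/s². We read
the two-threshold rule as a disjunction, as in the EyeLink parser these
thresholds come from: with ≈250 ms fixations at ≈3.3 saccades/s, saccades of
4° lasting ≈50–65 ms peak near 5,000°/s², short of the acceleration
criterion, so a conjunctive rule would discard kinematically ordinary
saccades. Candidate spans are merged across gaps <4 ms, spans <6 ms are
dropped (one-sample crossings), and each boundary is refined by walking down
the velocity flank to its foot (local minimum below 7.5°/s with a 3°/s
floor), which locates movement onset rather than threshold crossing: on
noiseless synthetic traces, onsets and offsets agree with ground truth
within ±4 ms for >99% of saccades. Blinks are spans where the pupil is
missing or below 10% of the trace median, padded by 50 ms (pupil estimates
are unreliable around lid closure); both constants are detector decisions,
not reported values. Fixations are the exact complement of saccades and
blinks.

## Role labeling

For every image fixation, the four roles are derived with these rules, and
excluded candidates carry a reason (precedence: `none_available`,
`out_of_band`, `revisited`, `feature_match`):

* eccentricity is measured from the **current gaze position** to the
  candidate image center (the parafovea is gaze-relative; measuring to the
  image center rather than its nearest edge is the stricter reading and is
  applied uniformly); the parafoveal band is 2–5°;
* revisits are judged against all earlier fixations of the same trial,
  resetting across trials;
* a parafoveal candidate sharing **either** the color scale **or** the
  category with the foveal image is discarded (`feature_match`): with a
  grayscale animal in the fovea, any grayscale image and any animal image
  is disqualified, which limits the possibility that parafoveal
  classification is driven by ongoing foveal processing. Every labeled
  parafoveal image therefore differs from the foveal image in *both*
  features;
* when several images qualify as the remaining image, one is chosen
  uniformly at random under the run seed (there is no principled way to
  prefer one qualifying image over another).

The implementation is validated against an independent brute-force
enumerator on 1,000 random scan paths (exact match required).

## Epoching

Epochs are cut at −1..+1 s around fixation onset, then filtered in a fixed
order: fixation-duration filter (80–1,000 ms) first, amplitude rejection on
the full −1..+1 s window (5,000 fT/cm for gradiometer-tagged channels,
5,000 fT for magnetometers; synthetic channels are unbounded by default),
then muscle-artifact overlap. The order of the duration filter and amplitude
rejection is not dictated by anything we reproduce; applying both before any
resampling is the conservative choice. Surviving epochs are zero-phase
low-pass filtered at 200 Hz (anti-aliasing; the resampling method itself is
a free choice), decimated to 500 Hz, and cropped to −0.5..+0.5 s (501
samples). Muscle artifacts are annotated on the continuous recording as
110–140 Hz envelope excursions with robust z > 10; the median/MAD z-score is
used so bursts do not inflate their own yardstick.

## Decoding

At each time point, the feature vector concatenates a 50-ms window — 25
samples at 500 Hz — across all channels (time-delay embedding), which buys
tolerance to activation-latency differences. Within each of 10 repetitions:
classes are balanced by subsampling the majority class; epochs are split
into 10 stratified folds **on raw epochs** (folds over super-trials would
be the other reading; splitting raw epochs first matches the order in which
the two operations are described and keeps test epochs disjoint from
training epochs at the trial level); within each side, random groups of
k = 10 same-class epochs are averaged into super-trials (`floor(n/k)` groups
per class, leftovers discarded for that repetition — a fresh partition each
repetition uses all epochs in expectation); a linear max-margin classifier
(hinge loss, L2, C = 1 — the library-default strength) is fit on training
super-trials and scored by the AUC of its signed decision values on test
super-trials. If a test fold holds fewer than k epochs of a class, that
side's group size shrinks to what the fold holds (training folds must
satisfy k, or the decoder raises an insufficient-data error naming the
class). Features are standardized per column with training-fold statistics
applied to both sides: standardizing across all epochs couples the folds
and visibly biases the null (super-trial class means are anti-correlated
between train and test through the global constraint), whereas training-fold
standardization leaves the null calibrated at AUC 0.500 ± 0.02. The
three-class category problem is the unweighted mean of the three pairwise
AUCs (exposed in the `pairwise` attribute). Fold assignments are fixed
across time points within a repetition, so curves are smooth and the
temporal-generalization diagonal equals the sliding curve exactly under a
shared seed.

The classifier itself is a compact SMO solver for the binary C-SVC dual on
the linear Gram matrix (`linsvm()`): with a dozen-odd super-trials the dual
has few variables and fitting is dominated by one BLAS cross-product, which
is what makes a 251-point × 10-fold × 10-repetition sweep per participant
tractable; its decision values are checked against `e1071::svm` (libsvm) in
the test suite.

Statistics are computed on the −250..+250 ms window (interpretation beyond
it is contaminated by neighbouring saccades); evaluated time points are
those where the full 25-sample window fits.

## Group statistics

`signflip_maxt()` tests group curves (or generalization matrices) against
chance: per permutation, each participant's chance-subtracted curve is
multiplied by one random sign — one sign per participant for the whole
curve, which preserves temporal autocorrelation under the null — and the
maximum one-sample t over time points is recorded; 1,500 permutations give
the null max-t distribution, whose 95th percentile thresholds the observed
t field. Consecutive supra-threshold points are reported as clusters; the
significance statement is pointwise at the corrected threshold (no
cluster-mass statistic), and two-dimensional fields use 4-connected
components. The test is one-sided above chance for decoding-vs-chance (only
above-chance decoding is interpretable) and two-sided for condition
contrasts (`two_condition_perm()`), which can be restricted to time points
where both conditions beat chance. A zero-variance time point yields t = 0
when the mean is also zero (all curves exactly at chance) and ±Inf when all
participants coincide away from chance (saturated decoding); an entirely
constant non-chance input is an error. Family-wise error calibration is
checked by simulation: over 500 pure-noise group datasets the rate of any
significant point stays at or below ~5%.

Peak latencies are per-participant argmaxes within the window where group
decoding beats chance (color 60–235 ms, category 160–200 ms by default),
ties to the earliest time. Contrasts use a two-tailed paired t computed from
first principles (`paired_ttest()`, checked against `stats::t.test`), with
Cohen's d as `mean(diff)/sd(diff)` — reported effect sizes in this
literature rarely disambiguate between d variants, so the simplest paired
form is used — and a JZS Bayes factor (`jzs_bf10()`): the non-central t
likelihood integrated over a Cauchy(0, 0.707) prior on the standardized
effect, by adaptive quadrature. The reference values BF10 = 1,863 and 0.4
(for t = 5.12 and t = 1.33 at n = 36) are reproduced to within 1%. (Raw
BF10 is reported, not log10 BF10: log10(1,863) ≈ 3.3 would be inconsistent
with the ">100" reading that accompanies such values.)

## Numerical and design notes

* Coordinates are degrees of visual angle, screen-centered, y-up; event
  times in ms; epoch and curve times in seconds; spans are half-open
  `[onset, offset)`.
* Continuous recordings and epoch arrays are cached as RDS; all tabular
  interfaces (gaze, events, layouts, behavior, curves, clusters) are TSV
  with documented headers, and `write_study()` / `write_report()` emit them
  alongside JSON provenance (config hash, seeds). There is no shell entry
  point: the exported functions *are* the pipeline, and `run_pipeline()` is
  the one-call orchestration.
* Every simulation-facing function takes a `seed`; `run_pipeline()` derives
  stage seeds from the master seed, so a `results_bundle` is reproducible
  hash-for-hash.
* The permutation threshold uses the ordinal `ceiling((1−alpha)·n_perm)`
  statistic of the max distribution; `n_perm < 100` warns.
* The alpha governing cluster annotation is exposed (`alpha = 0.05`
  default) rather than fixed: published analyses of this kind annotate
  clusters at varying levels (1% or 5%) around a procedure-wide 5%.

## Problem sizes used in validation

The packaged tests validate at desk scale, chosen so properties are sharp
but the suite stays quick: chance calibration with 10 participants × 200
epochs × 30 channels at the full 10-fold × 10-repetition setting;
latency recovery with 12 participants × 200 epochs × 30 channels per role
(amplitude 0.3, where group peaks reach ≈0.8 AUC — high enough that every
effect clears the max-t threshold in each participant group, low enough
that curves do not saturate, since a saturated curve has no localizable
peak); family-wise error with 500
null group datasets of 36 participants × 251 time points; generalization
morphology with 8 participants on a 10-ms grid. The label-rule oracle runs
on 1,000 full-length scan paths.

## Known limitations

* The generator's scan paths are statistically, not behaviorally, realistic
  (no saliency, no inhibition of return beyond the unvisited-slot
  preference).
* Synthetic channels share one unit; the per-channel-type amplitude
  thresholds are exercised via tagged fixtures rather than the generator.
* Sub-chance bias of cross-validated AUC under label permutation on finite
  data (a known property of balanced CV nulls, strongest when large
  class-agnostic signal directions exist) is documented rather than
  corrected; the calibration target is the no-signal null, which is
  unbiased.
* `latency_contrast()` assumes paired, same-length latency vectors; missing
  participants must be handled upstream.

## A worked example

```{r example, eval = FALSE}
library(fixdecode)

cfg <- run_config(
  synth = synth_config(n_participants = 6, n_trials = 60, n_channels = 24,
                       effects = default_effects(0.25), seed = 42),
  roles = c("foveal", "upcoming"),
  n_folds = 5, n_reps = 3, k_super = 5, time_step = 2,
  n_perm = 1000, seed = 42
)
bundle <- run_pipeline(cfg, progress = TRUE)

glance(bundle$cluster_tests[["foveal.color"]])
bundle$latency_contrasts$color
plot_decoding_curves(bundle$curves, bundle$cluster_tests)
write_report(bundle, "results/run-042")
```
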