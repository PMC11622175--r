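# fixdecode

Fixation-locked multivariate decoding of free visual exploration, for
cognitive neuroscientists who co-register eye tracking with multichannel
sensor recordings (MEG/EEG-style) while participants freely inspect
multi-object displays.

During natural viewing the eyes move ~3 times per second. Within each
~200 ms fixation the visual system must identify the foveal object *and*
preview the parafoveal object it will saccade to next. `fixdecode`
implements the analysis that measures both processes in sensor data:

* **eye events** — saccade detection by velocity/acceleration thresholds
  (30°/s, 8,000°/s²), blink detection from the pupil channel, fixations as
  their complement;
* **role labeling** — each fixation is assigned the *foveal* image and up
  to three parafoveal images (*upcoming* saccade target, *past* fixation
  target, one *remaining* image), restricted to the 2–5° parafoveal band,
  excluding revisited images and any parafoveal image sharing the foveal
  image's color scale or category;
* **epoching** — fixation-locked −1..+1 s epochs, amplitude and
  fixation-duration (80–1,000 ms) rejection, 110–140 Hz muscle-artifact
  annotation (robust z > 10), decimation to 500 Hz, cropping to ±0.5 s;
* **decoding** — for each role and time point *t*, a linear support-vector
  classifier on time-delay-embedded features (25 samples × N channels per
  50 ms window) with 10-trial super-trial averaging, 10-fold stratified
  cross-validation and 10 repetitions, scored as AUC; the three-class
  category problem is the mean of its three pairwise AUCs; temporal
  generalization (train at *t*, test at all *t′*) distinguishes transient
  (diagonal) from sustained (square) neural codes;
* **group statistics** — sign-flip max-t permutation tests against chance
  (1,500 permutations, one sign per participant per permutation,
  `t_crit` = 95th percentile of the max-t null), two-condition permutation
  contrasts, per-participant peak latencies, paired t tests with Cohen's d
  and CI95, and JZS Bayes factors
  `BF10 = ∫ f(t; ν, δ√n) Cauchy(δ; 0, 0.707) dδ / f(t; ν, 0)`;
* **synthetic studies** — a generator that emulates the full design (7-image
  hexagonal displays, gamma-distributed 240 ± 36 ms fixations, ~3.3
  saccades/s, class-specific evoked patterns injected at configurable
  latencies per role) with known ground truth, so every stage is validated
  by parameter recovery.

## Worked example

Simulate a small study with decodable color/category responses injected at
the latencies reported for free viewing (foveal color 100 ms, upcoming
parafoveal color 112 ms, ...), run the full pipeline — detection, labeling,
epoching, decoding, permutation statistics — and inspect the results:

```r
library(fixdecode)

cfg <- run_config(
  synth = synth_config(n_participants = 6, n_trials = 60, n_channels = 24,
                       effects = default_effects(0.25), seed = 42),
  roles = c("foveal", "upcoming"),
  n_folds = 5, n_reps = 3, k_super = 5, time_step = 2,
  n_perm = 1000, seed = 42
)
bundle <- run_pipeline(cfg)

glance(bundle$cluster_tests[["foveal.color"]])
#> # A tibble: 1 × 5
#>   threshold_t n_clusters alpha n_perm n_participants
#>         <dbl>      <int> <dbl>  <dbl>          <int>
#> 1        6.88          2  0.05   1000              6

tidy(bundle$cluster_tests[["foveal.color"]])
#> # A tibble: 2 × 5
#>   cluster  onset offset n_points peak_t
#>     <int>  <dbl>  <dbl>    <int>  <dbl>
#> 1       1 -0.194 -0.162        9   21.9
#> 2       2  0.05   0.146       25   32.1
```

The foveal color curve carries a significant cluster at 50–146 ms after
fixation onset, bracketing the injected 100 ms latency — decoding exceeds
the corrected threshold (`t > 6.88`) only where class information was
actually placed. The second, pre-onset cluster (−194 to −162 ms) is an
emergent feature, not an artifact: the currently foveated image was the
*upcoming* parafoveal image of the previous fixation, so its color is
already decodable before the eyes land on it — the parafoveal-previewing
signature this analysis is designed to expose. The upcoming-vs-foveal
peak-latency contrast at this small scale:

```r
as.data.frame(bundle$latency_contrasts$color) # upcoming minus foveal peaks
#>   n mean_diff sd_diff      t df     p cohen_d  ci_lo  ci_hi  bf10
#> 1 6  -0.00667  0.0216 -0.757  5 0.483  -0.309 -0.029  0.016 0.469

```

is correctly inconclusive (p = 0.48, BF10 = 0.47): six participants at
moderate SNR cannot resolve the injected 12 ms foveal-to-parafoveal lag,
and neither the t test nor the Bayes factor pretends otherwise.
`write_report(bundle, dir)`
writes the tidy TSVs (curves, clusters, latency contrasts, behavioral
summaries) plus a JSON provenance record, and
`plot_decoding_curves(bundle$curves, bundle$cluster_tests)` draws the group
curves with their significance bars.

See the methods vignette (`vignettes/fixation-locked-decoding.Rmd`) for the
model, the exclusion rules, all tunable parameters and the package's design
decisions.

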