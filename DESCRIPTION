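Package: fixdecode
Title: Fixation-Locked Multivariate Decoding of Free Visual Exploration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying foveal and parafoveal object processing during
    free visual exploration with co-registered eye tracking and multichannel
    (MEG-style) sensor recordings. Provides a synthetic study generator with
    known ground truth, saccade/blink/fixation detection from gaze traces by
    velocity and acceleration thresholds, fixation role labeling (foveal,
    upcoming, past, remaining parafoveal) with eccentricity-band and
    feature-overlap exclusion rules, fixation-locked epoch extraction with
    artifact rejection, time-resolved multivariate decoding (time-delay
    embedding, super-trial averaging, linear support-vector classification,
    AUC scoring, temporal generalization), and group-level inference by
    sign-flip max-t permutation tests, peak-latency contrasts, and JZS Bayes
    factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
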