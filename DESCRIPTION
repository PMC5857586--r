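Package: gazeval
Title: Infant Action-Prediction and Pupillometric Action-Evaluation Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores infant eye-tracking experiments in which action prediction
    (anticipatory gaze to the goal of an observed feeding action), action
    evaluation (baseline-corrected pupil dilation to inappropriate social
    interactions), and prospective reaching are measured in the same cohort
    and related through an individual-differences correlation analysis.
    Provides a sliding-window velocity-threshold fixation filter with
    centroid-distance merging, area-of-interest latency scoring with trial
    and participant inclusion rules, a four-step pupil preprocessing chain
    (range clamp, inter-sample step rejection, short-gap linear
    interpolation, moving average) with baseline-corrected difference
    scores, reach-latency scoring, a statistics layer (one-sample, paired
    and pooled two-sample t-tests, pairwise-complete Pearson correlations,
    adjusted skewness, predictive/reactive/excluded classification), and a
    synthetic-cohort generator with known latent traits for end-to-end
    parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    e1071,
    jsonlite,
    MASS,
    Rcpp,
    readr,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
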