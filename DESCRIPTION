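Package: cagematch
Title: Tube-Test Ethograms, Fiber Photometry Normalization, and
    Social-Defeat Avoidance Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for social-competition experiments in mice
    that combine pose tracking with fiber photometry.  Classifies tube-test
    behaviors (body push, nose push, resist, retreat) from nose/tailbase
    keypoint tracks with rule-based predicates, derives within-cage
    dominance hierarchies from round-robin outcomes with a multi-day
    stability criterion, normalizes two-channel photometry to dF/F by
    isosbestic least-squares regression or a sliding-median baseline,
    extracts event-locked trace matrices and mean amplitudes under
    task-specific window rules, computes open-field social-interaction
    zone occupancy and the composite social-avoidance score with
    susceptible/resilient classification, and compares groups with
    trial-level linear mixed-effects models.  A synthetic-data generator
    produces keypoint tables, two-channel photometry and arena
    trajectories with known ground truth for validation.
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
    lme4,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
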