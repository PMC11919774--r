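Package: salgaze
Title: Salience-Guided Gaze Analysis for Free-Viewing Eye Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for testing whether gaze during free viewing of static
    images follows bottom-up visual salience. Computes Itti-Koch saliency
    maps (luminance, color and orientation channels and their equal-weight
    combination) as 80x64 density grids, segments 1 kHz eye-position
    recordings into blinks, saccades and fixations, scores each subject by
    the mean map density at regular-saccade endpoints, and runs the
    multi-site statistics used in cross-disorder gaze studies: per-site
    covariate-adjusted unbiased d, fixed-effects meta-analysis, and
    cross-disorder general linear models with Bonferroni-corrected
    marginal-mean contrasts. Includes a synthetic-data generator that
    emulates the category-structured stimuli, saccade mixtures, and
    group- and site-structured cohorts such studies assume, so the full
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    EBImage,
    emmeans,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
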