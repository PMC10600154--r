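Package: calfmove
Title: Personality, Plasticity and Pen-Mate Conformity in Calf Movement
Version: 0.1.0
Authors@R:
    person("Calfmove", "Developers", email = "calfmove@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying animal personality and behavioural
    plasticity from indoor positional tracking of dairy calves. Includes a
    synthetic-data generator for daily movement panels and 1 Hz
    ultra-wideband-like trajectories with known ground truth, trajectory
    cleaning (exclusion intervals, out-of-pen filtering, moving-average
    smoothing), movement metrics (daily distance travelled, residence time)
    and static-tag validation statistics (CEP, DIST), random-intercept and
    random-slope linear mixed models with adjusted repeatability and
    bootstrap confidence intervals, the intercept-slope (personality-
    plasticity) correlation, a pen-mate similarity permutation test on the
    coefficient of variation of pair differences, and a carry-over model for
    pen-mate effects after regrouping. A command-line pipeline orchestrates
    simulate, preprocess, metrics, analyze and penmate stages reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
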