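Package: loomdyn
Title: Behavioral-Pupillary State Dynamics Under Looming Threat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated analysis pipeline for looming-threat time-to-collision
    experiments with concurrent pupillometry. Provides a synthetic-data generator
    emulating a 5 x 4 x 2 factorial looming paradigm; behavioral preprocessing and
    Stevens power-law modeling of judged time-to-collision with AIC/BIC model
    comparison and mixed-effects tests on the fitted parameters; pupil trace
    cleaning, downsampling, baseline correction and phase-window summaries;
    piecewise-linear time normalization with penalized cubic B-spline smoothing;
    functional principal component analysis of the normalized trajectories;
    two-level k-means profiling of trials (log response time, then component
    scores) with bootstrap stability and cross-validation; and first-order
    Markov-chain analysis of profile sequences (stationary distributions,
    transition contrasts with bootstrap confidence intervals, block entropy).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    car,
    mgcv,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
RoxygenNote: 7.3.3
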