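Package: microstatr
Title: Resting-State EEG Microstate Segmentation and Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete pipeline for resting-state EEG microstate analysis:
    preprocessing (re-referencing, zero-phase band-pass filtering,
    anti-aliased downsampling), global field power (GFP) computation and
    peak selection, polarity-invariant modified k-means clustering of
    peak topographies with global explained variance (GEV) and
    cross-validation model selection, back-fitting of template maps to
    continuous EEG with temporal smoothing, microstate parameters
    (duration, coverage, occurrence, transition probabilities), and the
    statistical layer used in pre/post stimulation designs (paired and
    two-sample t tests with Cohen's d, chi-squared, one-way and
    mixed-design ANOVA, Dunn's post hoc test, topographic permutation
    ANOVA, and change-rate regressions). Includes a semi-Markov synthetic
    EEG generator with matched ground truth so every stage is testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
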