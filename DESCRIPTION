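Package: pitchonset
Title: Stimulus Synthesis and Evoked-Response Inference for Pitch-Relevant
    Temporal Regularity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying cortical responses to the onset of
    pitch-evoking temporal regularity. Synthesizes the three classic
    regular stimulus families (Schroeder-phase harmonic complexes, click
    trains, and regular-interval noise built by iterated delay-and-add)
    embedded in noise-regular-noise sequences, simulates multi-subject
    evoked sensor epochs with planted condition-dependent components,
    extracts the dominant evoked component by denoising source separation
    (DSS), and tests Frequency-by-StimulusType effects with mass-univariate
    repeated-measures ANOVA under cluster-based permutation inference with
    Bonferroni-Holm control over planned contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    Rcpp,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
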