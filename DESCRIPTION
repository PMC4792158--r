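Package: srtlearn
Title: Information-Theoretic Analysis of Serial Reaction Time Sequence Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing sequence learning in the serial reaction
    time (SRT) task through the lens of information theory. Builds circular
    transition sets from stimulus-location sequences and computes joint and
    conditional probabilities and entropies of the transitions; generates
    random, repetitive, probabilistic (Markov) and entropy-graded stimulus
    sequences; simulates trial-by-trial reaction times with sigmoid
    stimulus-uncertainty tuning, block-wise learning dynamics and
    multiplicative noise; and compares linear against sigmoid descriptions of
    the reaction-time/predictor relationship by explained variance, including
    block-wise sigmoid parameter trajectories with the slope fixed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
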