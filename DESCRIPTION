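Package: turnload
Title: Word-Frequency Structure and Processing Load in Conversational Turns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the positional structure of word frequency
    within conversational turns-at-talk and its coupling to interlocutors'
    pupil-indexed processing load. Reads part-of-speech tagged transcripts in
    vertical (one token per row) format, computes subset-internal word-tag
    frequency tables and positional frequency profiles, classifies tokens into
    content words, function words, and inserts, detects hapax legomena,
    preprocesses raw two-eye pupil streams into word-aligned baselined bin
    means, fits per-turn slope statistics, and runs the polynomial
    mixed-effects inference stage with estimated-marginal-means post-hoc
    contrasts. Ships a synthetic-data generator producing joint transcript and
    pupillometry bundles with known ground truth, so the whole pipeline can be
    exercised and validated by parameter-recovery simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
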