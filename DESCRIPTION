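Package: forumstylo
Title: Stylometric User-Group Identification and Emotion-Expression
    Analysis for Online Peer-Support Forums
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies peer-support user groups in online mental-health
    forums from their writing style and compares their emotional
    expression. Implements Burrows' Delta over four stylometric feature
    types (frequent tokens, emotion-lexicon words, each optionally with
    pronouns), logistic calibration of delta scores into same-group
    probabilities, and ROC/AUC evaluation across a grid of feature-set
    sizes. A companion suite computes group-by-emotion count tables from
    an NRC-style emotion lexicon, polarity aggregates and ratios,
    pairwise chi-square tests with Benjamini-Hochberg correction, odds
    ratios with Woolf confidence intervals, and per-post radar profiles.
    A seeded synthetic forum-post generator with group-specific length
    and emotion-usage profiles makes the whole pipeline testable without
    access to non-public forum data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
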