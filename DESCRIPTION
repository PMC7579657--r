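Package: emomine
Title: Lexicon Coding, Association Rules, and Co-Occurrence Networks for
    Health Social-Media Posts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for dictionary-based emotion analysis of
    channel-tagged social-media posts about cancer. Posts are matched
    against an ontology-derived lexicon, filtered through an
    inclusion/exclusion funnel (cancer topic, emotion mention, stop and
    advertising keywords), and coded into 47 binary analysis items (4
    emotion groups and 43 emotion-related factor groups). The coded
    transactions feed frequency tables, Apriori association-rule mining
    with support, confidence, and lift, and per-stratum co-occurrence
    network analysis. A synthetic corpus generator with a logistic
    factor-to-emotion effect model and a closed-form lift oracle
    provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
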