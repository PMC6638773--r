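Package: symptweet
Title: Semi-Supervised Relevance Filtering of Symptomatic Social-Media Posts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for syndromic surveillance from short social-media posts:
    corpus cleaning (retweets, duplicates, URL tokenisation, bot heuristics,
    coarse location filtering), compound feature extraction combining word
    n-grams with curated word classes, sentiment word counts and
    emoji/emoticon indicators, confidence-based self-training and two-view
    co-training on top of five interchangeable base learners, an evaluation
    suite (F-beta, Fleiss' kappa, feature ablation, word informativeness,
    keyword retrieval assessment), and daily-signal extraction with Pearson
    correlation against a reference health-indicator time series. A seeded
    synthetic-corpus generator provides ground-truthed fixtures for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    e1071,
    rpart,
    glmnet,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
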