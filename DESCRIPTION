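Package: vaxcred
Title: Credibility Scoring and Exposure Analysis for Health Web Pages
    Shared on Social Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A surveillance pipeline for the credibility of vaccine-related
    Web pages shared on social media. Filters a corpus of page texts
    (language, length, near-duplicate removal), trains per-criterion text
    classifiers (linear support vector machines and random forests on tf-idf
    features) for a 7-item credibility checklist, combines them into a
    best-per-criterion ensemble, converts criterion predictions into a 0-7
    credibility score with low/medium/high bands, identifies terms
    over-represented in low-credibility pages with exact tests, and estimates
    potential exposure and sharer subpopulations from a tweet log and
    follower network. A synthetic-data module emulates the corpus and social
    structure so the whole pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    e1071,
    randomForest,
    igraph,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
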