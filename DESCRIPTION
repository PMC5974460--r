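Package: needgap
Title: Mining Unmet Information Needs from Peer-to-Peer Health Forums
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterising expressions of unmet
    information need in peer-to-peer health-forum conversations, and for
    quantifying the gap between those needs and a corpus of patient-education
    pages. Provides sentence segmentation and tokenization for informal forum
    text, a ten-category information taxonomy, rule induction of minimal
    bigram-pattern detectors over a question-cue vocabulary, one-vs-rest
    sentence classifiers (multinomial naive Bayes, linear SVM, random forest)
    with bag-of-words, bigram, local-context, topic-model and word-embedding
    features, frequency-ranked concept profiling through a pluggable lexicon,
    tf-idf query construction with referential resolution, Okapi BM25 retrieval
    over indexed education pages, and inter-rater agreement and coverage
    statistics. A synthetic-forum generator emulates the statistical structure
    of annotated survivor-forum corpora so the whole pipeline can be exercised
    and validated without access to restricted forum data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    jsonlite,
    ranger,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
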