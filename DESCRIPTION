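Package: supstatus
Title: Classification of Dietary Supplement Use Status in Clinical Sentences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sentence-level classification of dietary-supplement use status in
    clinical text into four classes (Continuing, Discontinued, Started,
    Unclassified). Provides a window-based indicator rule engine with negation
    handling, a feature-engineered supervised-learning harness (nine
    bag-of-words/TF-IDF/indicator feature sets crossed with five classifier
    families), full per-class and weighted evaluation including Cohen's kappa
    and pairwise classifier comparison, and a seeded synthetic clinical-sentence
    generator emulating a 25-supplement annotated corpus so the whole system is
    buildable and testable without protected clinical notes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    ranger,
    rpart,
    e1071,
    methods,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
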