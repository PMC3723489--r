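Package: hypofinder
Title: Dictionary-Based Detection of Speculative Statements in
    Biomedical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects speculative (hedged) statements in biomedical
    abstracts using a curated dictionary of multi-word speculation cues
    matched case-insensitively under word-order-sensitive, longest exact
    match semantics. Provides offset-anchored sentence segmentation and
    tokenization, readers and writers for plain abstract corpora,
    standoff annotations and BioScope-style speculation-cue XML,
    pattern-strength profiling by percent efficacy, rule-based
    adjudication of dual annotations with Cohen's kappa agreement,
    span- and sentence-level precision/recall/F evaluation, a
    maximum-entropy sentence-classification baseline with switchable
    algorithms and three feature families, and a synthetic corpus
    generator for controlled benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Matrix,
    stats,
    utils,
    xml2
Suggests:
    class,
    e1071,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
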