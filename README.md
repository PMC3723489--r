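# hypofinder

Dictionary-based detection of speculative (hedged) statements in
biomedical abstracts.

Scientific abstracts are full of sentences that propose rather than
report — "CSF tau and Abeta(1-42) *may be* useful biomarkers", "amyloid
clearance *seems to* fail early". Collected systematically, such
statements form an inventory of working hypotheses in a field.
`hypofinder` is for text-mining and curation teams who want to extract
that inventory reproducibly: it labels a sentence **POSITIVE**
(hypothetical) iff it contains at least one cue from a curated dictionary
of speculative patterns, matched **case-insensitively**, **word-order
sensitively**, and by **longest exact match** over contiguous token
sequences.

Around that core the package provides:

* offset-anchored sentence segmentation and tokenization
  (0-based, half-open character offsets; `text[start:end] == surface`
  everywhere),
* readers/writers for PMID-tagged plain-text corpora, standoff TSV
  annotations, a pipe-delimited pattern dictionary, and BioScope-style
  speculation-cue XML,
* per-pattern **percent efficacy** profiling (capped seeded sampling of
  matched sentences against curated labels) and strong/moderate/weak
  strength classes,
* four-rule adjudication of dual annotations (partial overlaps shrink to
  their intersection) and two-rater Cohen's kappa,
* span- and sentence-level precision/recall/F evaluation (exact and
  overlap criteria),
* a maximum-entropy sentence-classification baseline (L2 logistic
  regression, with naive Bayes / k-NN / decision-tree / SVM alternatives)
  over three feature families: all-words (`base`), dictionary-pattern
  indicators (`spec`) and lexico-syntactic features (`lex`),
* a synthetic corpus generator that plants cues into shared sentence
  skeletons, with four negative-control categories and near-miss
  distractor salting.

The bundled seed dictionary (`seed_dictionary()`) is a **synthetic
reconstruction** — every published example pattern verbatim, padded with
systematic modal-verb compositions to 156 representative and 392
synonymous patterns; bare weak terms ("potential", "possibility",
"should", "would") appear only in composed forms such as "could be a
potential". See `vignettes/hypothesis-detection.Rmd` for the method and
its assumptions.

## Worked example

```r
library(hypofinder)

idx <- compile_index(build_patterns(seed_dictionary()))
doc <- new_document("14699432", paste(
  "Our findings support the notion that CSF tau and Abeta(1-42) may be",
  "useful biomarkers in the early identification of AD in MCI subjects.",
  "Whether T2D can cause late onset Alzheimer disease remains to be",
  "elucidated."))
res <- classify_corpus(as_corpus(list(doc)), idx)

res$labels
#>     doc_id sentence_index    label
#> 1 14699432              1 POSITIVE
#> 2 14699432              2 NEGATIVE

res$matches
#>     doc_id sentence_index start end pattern surface
#> 1 14699432              1    61  67  may be  may be
```

The first sentence is flagged as hypothetical because the cue "may be"
matches at characters [61, 67); the open question in the second sentence
contains no dictionary cue ("remains to be elucidated" is deliberately
not one) and stays NEGATIVE. Scoring against a gold labeling uses the
usual positive-class metrics:

```r
gold <- data.frame(doc_id = "14699432", sentence_index = 1:2,
                   label = c("POSITIVE", "NEGATIVE"))
sentence_prf(res$labels, gold)
#> <hf_eval sentence> TP=1 FP=0 FN=0  P=1.000 R=1.000 F=1.000
```

A command-line interface covering segmentation, matching, classification,
profiling, evaluation, agreement, adjudication, format conversion and
fixture generation is installed at
`system.file("cli", "hypofinder", package = "hypofinder")`.

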