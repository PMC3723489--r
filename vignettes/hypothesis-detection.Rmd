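---
title: "Detecting speculative statements in biomedical abstracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting speculative statements in biomedical abstracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypofinder)
```

## The problem

Scientific abstracts mix established findings with *speculative*
(hedged) statements — "CSF tau and Abeta(1-42) **may be** useful
biomarkers", "amyloid clearance **seems to** fail early". Collected
systematically, such statements form an inventory of working hypotheses in
a field. `hypofinder` detects them with a dictionary method: a curated
lexicon of multi-word speculation cues is matched in every sentence under
case-insensitive, word-order-sensitive, longest-exact-match semantics, and
a sentence is labeled `POSITIVE` (hypothetical) iff it contains at least
one cue. The package also implements the apparatus around the detector:
offset-anchored segmentation, corpus and annotation I/O, cue-strength
profiling, dual-annotation adjudication with Cohen's kappa, span- and
sentence-level evaluation, a maximum-entropy machine-learning baseline for
comparison, and a synthetic corpus generator used throughout the tests.

## The cue dictionary

A dictionary entry is a *representative* pattern plus pipe-delimited
*synonymous* patterns — inflectional and combinatorial variants grouped
under one head, e.g. `appear to` with `appeared to be|appears to
be|appear that|…`. The originally curated lexicon this method was
developed with is not publicly available, so the package ships a
**synthetic reconstruction**
(`seed_dictionary()`, file `seed_dictionary_synthetic.tsv`): every
published example pattern verbatim, padded with systematic modal-verb
compositions ("may/might/could" × a verb inventory) to the documented size
of 156 representative and 392 synonymous patterns. It is a faithful
stand-in for testing the machinery, not a copy of the original lexicon;
scores obtained with it on external corpora such as BioScope will differ
from published ones.

Two policies shape the lexicon. First, *bare weak terms* — "potential",
"possibility", "should", "would" — are excluded standalone because they
frequently occur non-speculatively; they appear only inside composed
patterns built with `strengthen_weak()` ("could be a potential", "raising
the possibility that"). Second, matching is contiguous: every published
pattern is a gap-free token sequence, so gapped patterns are out of scope.

```{r}
dict_stats(seed_dictionary())
strengthen_weak("possibility", "raising the", trailing = "that")
```

## Matching semantics

Sentences are tokenized into word and punctuation tokens (hyphens and
parentheses are boundaries) with exact character offsets. The matcher
scans left to right; at each token it takes the **longest** dictionary
form (in tokens, character span then dictionary order as tie-breaks)
whose case-folded token sequence matches contiguously, then resumes after
the match, so matches never overlap and never cross sentence boundaries.
"Longest" is measured in tokens because the search is word-order
sensitive and operates on word units. A second implementation,
`brute_force_matches()`, enumerates every candidate by direct comparison
and applies the same selection; the test suite requires the two to agree
on thousands of randomized dictionary/sentence pairs.

```{r}
idx <- compile_index(build_patterns(seed_dictionary()))
s <- segment_sentences(new_document(
  "14699432",
  "CSF tau and Abeta(1-42) may be useful biomarkers in early AD."))[[1]]
find_matches(s, idx)
```

## Segmentation and offsets

The splitter is rule-based: a sentence ends at `.`, `!` or `?` followed by
whitespace and an uppercase letter, digit or opening bracket, unless the
preceding word is on a fixed abbreviation list (`e.g.`, `i.e.`, `et al.`,
`Fig.`, `vs.`, …). All offsets in the package are 0-based, half-open
character offsets into the normalized document text, the standard standoff
convention; every emitted token, sentence, match and annotation satisfies
`text[start:end] == surface`, which the tests assert. A learned splitter
would handle pathological punctuation better, but a deterministic one
keeps offsets reproducible, which matters more here.

## Pattern strength and percent efficacy

Cues differ in reliability. `profile_efficacy()` quantifies this per
pattern: collect the sentences the pattern matches, cap at 50 by seeded
uniform sampling without replacement, and report the percentage of the
sample curated as truly speculative. Curation is an input (it was a manual
step), not something the package fabricates. `assign_strength()` maps
efficacy to classes; the numeric thresholds were never published, so the
package defaults to **strong ≥ 90 %**, **weak < 50 %**, moderate between
— consistent with the observation that modal-verb patterns are
near-always speculative while bare "potential"/"possibility" often are
not. Both thresholds and the cap are arguments. The 50-sentence cap is
applied per pattern, after deduplicating the sentences that pattern
matched; sentences matched by several patterns enter each pattern's pool.

## Adjudication and agreement

Dual annotations are merged under four rules: spans marked identically by
both annotators are kept; partially overlapping pairs are replaced by
their character intersection snapped to token boundaries (only the
conflicting words are removed, so "might be involved" vs "might be"
merges to "might be"); spans marked by one annotator are kept only with
an explicit `accept` decision; and no span absent from both inputs is
ever created. Agreement is measured by two-rater Cohen's kappa on the
binary sentence label — the standard two-rater statistic for this design;
when both raters are constant and identical (expected agreement 1) kappa
is reported as 1. Undefined precision/recall ratios (0/0) are reported as
0 with a warning rather than NaN, so degenerate corpora still produce
comparable reports.

## The machine-learning baseline

`build_instances()` labels every sentence `POSITIVE` iff a gold span
overlaps it (a span straddling sentence boundaries is treated as a data
error, not silently split). Three namespaced feature families keep
experiments separable:

* `base:` — one binary feature per case-folded word ("all words"),
* `spec:` — one binary feature per dictionary pattern matching the sentence,
* `lex:` — lemma uni/bi/trigrams, 2/3/4-character prefixes and suffixes of
  noun tokens, and dependency triples when a provider supplies them.

Lemmas, noun flags and dependencies come from a pluggable
*linguistic provider*; the bundled `rule_linguistic_provider()` is a
deterministic suffix-stripping baseline and a null dependency function is
legal, so the core stays dependency-free. Tests use a fixed-lexicon
provider.

The required algorithm, maximum entropy, is L2-regularized binomial
logistic regression fit with `glmnet` along a decreasing lambda path
(single-lambda ridge fits converge poorly), with predictions taken at
`lambda = 1/(C·n)`. The default is **C = 10**, deliberately weaker than
C = 1: a cue-indicator feature occurring a handful of times must be able
to push a sentence past the decision threshold, and at C = 1 its
coefficient (~2 against an intercept near −1.7) cannot, which silently
disables the speculative features the comparison is about. `C` remains an
argument. Naive Bayes, k-NN, decision trees and linear SVM are available
behind the same contract (`e1071`, `class`, `rpart`). No feature or
hyperparameter optimization beyond this default is attempted — the
baseline exists for comparison, not for leaderboard performance.

## The synthetic corpus generator

`generate_corpus()` emulates the structure the detector assumes. Sentences
are rendered from a shared pool of skeleton templates in four
non-speculative control categories — *inferences*, *results and
conclusions*, *argumentative sentences*, *open questions* — with entities,
conditions and verbs drawn from fixed pools. A positive sentence is the
same skeleton with exactly one uniformly chosen dictionary surface form
inserted at a recorded offset; a salted negative appends a near-miss
distractor clause (bare "potential", "possibility", "should", "would",
"remains to be elucidated", modal tokens in non-cue configurations).
Because the two classes share templates and vocabulary, individual word
features do not determine the label — only the contiguous cue does — which
is what makes the pattern/ML comparison on these corpora informative.
The generator verifies its own contract at build time: every negative
must contain zero dictionary matches and every positive exactly the
planted one, so dictionary classification recovers gold labels and spans
perfectly by construction, and the tests assert it.

Default study conditions, chosen once: 5 sentences per abstract, positive
rate 0.2 (the roughly 1:4 class imbalance typical of speculation-annotated
abstract corpora), distractor rate 0.5 where salting is exercised, equal
category weights, exact-count planting for test stability (Bernoulli
planting available). Test corpora are 250–2,500 sentences; the ML
comparison uses 2,500 with a seeded 80/20 held-out split.

What passing on fixtures does and does not show: it validates the
matching semantics, the offset bookkeeping and the end-to-end pipeline
exactly; it does not measure real-text recall, where cue inventories are
open-ended — a curated lexicon inevitably misses some annotated patterns
— and sentence structure is richer than templates. One expected ordering
illustrates the gap: on real abstracts lexico-syntactic features tend to
beat raw words, but on these fixtures the closed template vocabulary
makes unigram features near-sufficient, so that ordering does not
reproduce and is not asserted. The orderings that do carry over —
adding `spec` features helps any feature set, and the dictionary
classifier dominates every ML variant — are asserted in the tests.

## Numerical and degenerate-input choices

* Offsets 0-based half-open; all surfaces validated against text.
* Duplicate surface forms across entries: first entry wins, with a warning.
* Matcher ties: token length, then character span, then entry order.
* A pattern with zero matching sentences gets efficacy `NA` flagged
  not-computable — never 0, which would mean "always wrong".
* Empty dictionaries cannot be compiled; empty corpora read as empty
  sequences, not errors.
* Sampling (efficacy cap, corpus generation, splits) is always behind an
  explicit seed; identical seeds give byte-identical corpora.

## Known limitations

Gapped cue patterns ("raising the … that") are not matched; the resolved
published examples are contiguous. The rule lemmatizer and noun heuristic
are crude — they exist to exercise the `lex` feature code paths, and a
POS-capable provider can be plugged in. BioScope reading extracts
speculation *cues* only, not their scopes. The seed dictionary is a
reconstruction; results with it are comparable across runs of this
package but not to published scores.
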