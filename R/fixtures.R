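# Synthetic labeled corpora with the statistical structure the detector
# assumes: positive sentences carry exactly one planted dictionary surface
# form at a recorded offset; negative sentences come from four
# non-speculative control categories (inferences, results and conclusions,
# argumentative sentences, open questions) and may be salted with near-miss
# distractor phrases that are absent from the dictionary. Positive and
# negative sentences share the same skeleton templates and vocabulary, so
# the only systematic difference between the classes is the contiguous cue.

CONTROL_CATEGORIES <- c("inferences", "results_conclusions",
                        "argumentative", "open_questions")

FIXTURE_ENTITIES <- c(
  "tau phosphorylation", "amyloid deposition", "synaptic loss",
  "oxidative stress", "microglial activation", "hippocampal atrophy",
  "neuroinflammation", "mitochondrial dysfunction", "cholinergic signaling",
  "axonal transport", "calcium homeostasis", "cerebral perfusion",
  "cognitive decline", "memory consolidation")

FIXTURE_CONDITIONS <- c(
  "early Alzheimer's disease", "mild cognitive impairment",
  "late onset dementia", "transgenic mouse models", "sporadic disease",
  "aged cohorts")

# Inflected verbs for the open verb slot; none is a dictionary token.
FIXTURE_VERBS <- c("reduced", "elevated", "lowered", "worsened", "improved",
                   "restored", "normalized", "delayed", "blunted",
                   "magnified", "reshaped", "eroded")

# Base verbs reachable inside negative constructions ("did not X",
# "failed to X"); drawn from the verbs the dictionary combines with modal
# cues, so cue-internal verb tokens also occur in negative sentences.
FIXTURE_BASE_VERBS <- c("contribute", "involve", "play", "serve", "represent",
                        "reflect", "explain", "underlie", "modulate",
                        "mediate", "regulate", "influence", "affect",
                        "promote", "facilitate", "attenuate", "enhance",
                        "trigger", "drive", "alter", "impair", "protect")

# Near-miss distractor clauses: bare weak terms and modal tokens in
# configurations that never form a dictionary surface form.
FIXTURE_DISTRACTORS <- c(
  "and the potential of this approach warrants further study",
  "although the possibility of confounding was not excluded",
  "and future trials should adopt stricter criteria",
  "as earlier cohorts would not permit direct comparison",
  "and the mechanism remains to be elucidated",
  "as may occur in normal aging",
  "as might arise from vascular comorbidity",
  "although the effect could not be separated from ageing",
  "which seems unrelated to disease staging",
  "which appears unrelated to disease staging",
  "despite efforts to modulate it pharmacologically",
  "and it suggests no such effect in controls")

FIXTURE_TEMPLATES <- list(
  inferences = c(
    "Taken together these data demonstrate that {E1} {CUE}{V} {E2} in {C}.",
    "Collectively the findings establish that {E1} {CUE}{V} {E2} across {C}.",
    "These experiments confirm that blocking {E1} {CUE}{V} {E2} during {C}.",
    "Together the results show that {E1} {CUE}{V} {E2} in {C}.",
    "This transgenic model proves that {E1} {CUE}{V} {E2}."),
  results_conclusions = c(
    "Treatment targeting {E1} {CUE}{V} {E2} in patients with {C}.",
    "Galantamine {CUE}{V} {E2} in patients with {C}.",
    "In our cohort {E1} {CUE}{V} {E2}.",
    "Chronic administration of donepezil {CUE}{V} {E1} across {C}.",
    "Longitudinal follow up showed that {E1} {CUE}{V} {E2}."),
  argumentative = c(
    "There is increasing evidence that {E1} {CUE}{V} {E2} in {C}.",
    "It has long been argued that {E1} {CUE}{V} {E2}.",
    "A growing body of work contends that {E1} {CUE}{V} {E2} during {C}.",
    "Many investigators maintain that {E1} {CUE}{V} {E2}.",
    "There is broad consensus that {E1} {CUE}{V} {E2} in {C}."),
  open_questions = c(
    "Whether {E1} {CUE}{V} {E2} remains to be determined.",
    "Whether {E1} {CUE}{V} {E2} in {C} remains an open question.",
    "It remains unclear whether {E1} {CUE}{V} {E2}.",
    "How {E1} {CUE}{V} {E2} has not been resolved.",
    "The extent to which {E1} {CUE}{V} {E2} is still debated."))

#' Sentence templates for the four negative-control categories
#'
#' Returns the raw skeleton templates (with `{E1}`, `{E2}`, `{C}`, `{V}`
#' and `{CUE}` placeholders) for one control category. Rendered without a
#' cue they contain no surface form of the seed dictionary; with a planted
#' cue the same skeletons serve as positive sentences, keeping the two
#' classes lexically comparable.
#'
#' @param category One of `"inferences"`, `"results_conclusions"`,
#'   `"argumentative"`, `"open_questions"`.
#' @return Character vector of at least five templates.
#' @export
negative_control_templates <- function(category) {
  if (!category %in% CONTROL_CATEGORIES) {
    stopf("unknown negative-control category '%s' (expected one of %s)",
          category, paste(CONTROL_CATEGORIES, collapse = ", "))
  }
  FIXTURE_TEMPLATES[[category]]
}

#' Specify a synthetic corpus
#'
#' @param n_documents Number of abstracts to generate.
#' @param sentences_per_document Sentences per abstract.
#' @param positive_rate Fraction of sentences receiving a planted cue.
#' @param dictionary `hf_dictionary` supplying the cues (default the seed
#'   dictionary); must be non-empty when `positive_rate > 0`.
#' @param negative_control_mix Named non-negative weights over the four
#'   control categories.
#' @param distractor_rate Fraction of negative sentences salted with a
#'   near-miss distractor clause.
#' @param seed Mandatory integer seed; generation is fully deterministic
#'   given this specification.
#' @param exact_counts If `TRUE` (default) exactly
#'   `round(positive_rate * total)` sentences are positive; otherwise each
#'   sentence is positive independently with probability `positive_rate`.
#' @return An object of class `hf_fixture_spec`.
#' @export
synthetic_corpus_spec <- function(n_documents = 50L,
                                  sentences_per_document = 5L,
                                  positive_rate = 0.2,
                                  dictionary = seed_dictionary(),
                                  negative_control_mix = c(
                                    inferences = 1, results_conclusions = 1,
                                    argumentative = 1, open_questions = 1),
                                  distractor_rate = 0,
                                  seed,
                                  exact_counts = TRUE) {
  if (missing(seed)) stopf("a seed is mandatory for corpus generation")
  stopifnot(positive_rate >= 0, positive_rate <= 1,
            distractor_rate >= 0, distractor_rate <= 1,
            n_documents >= 1, sentences_per_document >= 1)
  if (positive_rate > 0 && length(dictionary) == 0L) {
    stopf("positive_rate > 0 requires a non-empty dictionary")
  }
  mix <- negative_control_mix[CONTROL_CATEGORIES]
  if (any(is.na(mix)) || any(mix < 0) || sum(mix) <= 0) {
    stopf("negative_control_mix must give non-negative weight to the four categories")
  }
  structure(list(n_documents = as.integer(n_documents),
                 sentences_per_document = as.integer(sentences_per_document),
                 positive_rate = positive_rate, dictionary = dictionary,
                 negative_control_mix = mix / sum(mix),
                 distractor_rate = distractor_rate,
                 seed = as.integer(seed), exact_counts = exact_counts),
            class = "hf_fixture_spec")
}

#' Generate a synthetic labeled corpus
#'
#' Positive sentences carry exactly one uniformly chosen dictionary surface
#' form planted at a recorded offset; negatives are rendered from the four
#' control-category templates, optionally salted with distractor phrases.
#' The generator verifies its own contract: every rendered negative is
#' required to contain zero dictionary matches and every positive exactly
#' the planted match, so dictionary classification recovers the gold
#' labels and spans perfectly by construction.
#'
#' @param spec An `hf_fixture_spec`.
#' @return List with `documents` (`hf_corpus`), `gold_spans` (data.frame
#'   `doc_id`, `start`, `end`, `surface`, `pattern`, `label`) and
#'   `gold_labels` (data.frame `doc_id`, `sentence_index`, `label`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "hf_fixture_spec"))
  patterns <- if (length(spec$dictionary)) build_patterns(spec$dictionary) else NULL
  forms <- list()
  if (!is.null(patterns)) {
    for (p in patterns) {
      for (f in p$forms) {
        forms[[length(forms) + 1L]] <- list(text = f$text,
                                            representative = p$representative)
      }
    }
  }
  total <- spec$n_documents * spec$sentences_per_document
  with_rng_seed(spec$seed, {
    positive <- if (spec$exact_counts) {
      slots <- rep(FALSE, total)
      npos <- round(spec$positive_rate * total)
      if (npos > 0L) slots[sample.int(total, npos)] <- TRUE
      slots
    } else {
      stats::runif(total) < spec$positive_rate
    }
    docs <- vector("list", spec$n_documents)
    spans <- list()
    labels <- list()
    slot <- 0L
    for (d in seq_len(spec$n_documents)) {
      doc_id <- sprintf("SYN%05d", d)
      sents <- character(spec$sentences_per_document)
      offset <- 0L
      for (s in seq_len(spec$sentences_per_document)) {
        slot <- slot + 1L
        category <- sample(CONTROL_CATEGORIES, 1L,
                           prob = spec$negative_control_mix)
        template <- sample(FIXTURE_TEMPLATES[[category]], 1L)
        if (positive[slot]) {
          form <- forms[[sample.int(length(forms), 1L)]]
          rendered <- render_template(template, cue = form$text)
          sents[s] <- rendered$text
          spans[[length(spans) + 1L]] <- data.frame(
            doc_id = doc_id, start = offset + rendered$cue_start,
            end = offset + rendered$cue_start + nchar(form$text),
            surface = form$text, pattern = form$representative,
            label = "speculative_pattern", stringsAsFactors = FALSE)
          lab <- "POSITIVE"
        } else {
          rendered <- render_template(template, cue = NULL)
          txt <- rendered$text
          if (stats::runif(1) < spec$distractor_rate) {
            clause <- sample(FIXTURE_DISTRACTORS, 1L)
            txt <- paste0(substr(txt, 1L, nchar(txt) - 1L), ", ", clause, ".")
          }
          sents[s] <- txt
          lab <- "NEGATIVE"
        }
        labels[[length(labels) + 1L]] <- data.frame(
          doc_id = doc_id, sentence_index = s, label = lab,
          stringsAsFactors = FALSE)
        offset <- offset + nchar(sents[s]) + 1L
      }
      docs[[d]] <- new_document(doc_id, paste(sents, collapse = " "))
    }
    corpus <- as_corpus(docs)
    gold_spans <- if (length(spans)) do.call(rbind, spans) else {
      cbind(empty_spans()[0, ], pattern = character(0))
    }
    gold_labels <- do.call(rbind, labels)
    rownames(gold_labels) <- NULL
    if (!is.null(patterns)) {
      check_fixture_contract(corpus, gold_spans, gold_labels, patterns)
    }
    list(documents = corpus, gold_spans = gold_spans,
         gold_labels = gold_labels)
  })
}

render_template <- function(template, cue = NULL) {
  fill <- function(txt, tag, value) {
    sub(tag, value, txt, fixed = TRUE)
  }
  txt <- template
  txt <- fill(txt, "{E1}", sample(FIXTURE_ENTITIES, 1L))
  txt <- fill(txt, "{E2}", sample(FIXTURE_ENTITIES, 1L))
  txt <- fill(txt, "{C}", sample(FIXTURE_CONDITIONS, 1L))
  verb_kind <- sample.int(5L, 1L)
  verb <- if (verb_kind <= 3L) {
    sample(FIXTURE_VERBS, 1L)
  } else if (verb_kind == 4L) {
    paste("did not", sample(FIXTURE_BASE_VERBS, 1L))
  } else {
    paste("failed to", sample(FIXTURE_BASE_VERBS, 1L))
  }
  txt <- fill(txt, "{V}", verb)
  cue_start <- NA_integer_
  if (is.null(cue)) {
    txt <- fill(txt, "{CUE}", "")
  } else {
    cue_start <- regexpr("{CUE}", txt, fixed = TRUE)[[1L]] - 1L  # 0-based
    txt <- fill(txt, "{CUE}", paste0(cue, " "))
  }
  list(text = txt, cue_start = cue_start)
}

# Defensive verification of the generator contract: the planting dictionary
# must recover gold labels and spans exactly.
check_fixture_contract <- function(corpus, gold_spans, gold_labels, patterns) {
  index <- compile_index(patterns)
  res <- classify_corpus(corpus, index)
  ok_labels <- identical(
    paste(res$labels$doc_id, res$labels$sentence_index, res$labels$label),
    paste(gold_labels$doc_id, gold_labels$sentence_index, gold_labels$label))
  got <- res$matches[order(res$matches$doc_id, res$matches$start), , drop = FALSE]
  want <- gold_spans[order(gold_spans$doc_id, gold_spans$start), , drop = FALSE]
  ok_spans <- nrow(got) == nrow(want) &&
    all(got$doc_id == want$doc_id) && all(got$start == want$start) &&
    all(got$end == want$end)
  if (!ok_labels || !ok_spans) {
    stopf("fixture generation violated its contract (a template or entity collides with a dictionary form)")
  }
  invisible(TRUE)
}
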