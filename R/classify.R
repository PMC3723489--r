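# Sentence-level hypothesis classification and pattern-strength profiling.

empty_labels <- function() {
  data.frame(doc_id = character(0), sentence_index = integer(0),
             label = character(0), stringsAsFactors = FALSE)
}

#' Label a sentence as hypothetical or not
#'
#' A sentence is POSITIVE iff at least one speculative pattern was
#' recognized in it, NEGATIVE otherwise; the matches are carried along as
#' evidence.
#'
#' @param sentence An `hf_sentence`.
#' @param matches Match data.frame for this sentence (as returned by
#'   [find_matches()]); matches referencing another sentence are an error.
#' @return List with `doc_id`, `sentence_index`, `label`
#'   (`"POSITIVE"`/`"NEGATIVE"`) and `matches`.
#' @export
classify_sentence <- function(sentence, matches) {
  if (nrow(matches) > 0L &&
      (any(matches$doc_id != sentence$doc_id) ||
       any(matches$sentence_index != sentence$index))) {
    stopf("matches reference a different sentence than %s#%d",
          sentence$doc_id, sentence$index)
  }
  list(doc_id = sentence$doc_id, sentence_index = sentence$index,
       label = if (nrow(matches) > 0L) "POSITIVE" else "NEGATIVE",
       matches = matches)
}

#' Classify every sentence of a corpus
#'
#' Segments each document, matches the dictionary index in every sentence
#' and labels sentences POSITIVE iff they contain at least one match.
#'
#' @param corpus An `hf_corpus`.
#' @param index An `hf_matcher_index`.
#' @return List with `labels` (data.frame `doc_id`, `sentence_index`,
#'   `label`, in document order), `matches` (all matches) and `sentences`
#'   (the segmented `hf_sentence` objects).
#' @export
classify_corpus <- function(corpus, index) {
  sentences <- corpus_sentences(corpus)
  labels <- list()
  matches <- list()
  for (s in sentences) {
    m <- find_matches(s, index)
    labels[[length(labels) + 1L]] <-
      data.frame(doc_id = s$doc_id, sentence_index = s$index,
                 label = if (nrow(m) > 0L) "POSITIVE" else "NEGATIVE",
                 stringsAsFactors = FALSE)
    if (nrow(m) > 0L) matches[[length(matches) + 1L]] <- m
  }
  list(labels = if (length(labels)) do.call(rbind, labels) else empty_labels(),
       matches = if (length(matches)) do.call(rbind, matches) else empty_matches(),
       sentences = sentences)
}

#' Profile the percent efficacy of one pattern
#'
#' Collects the sentences in which the pattern matched, caps them at
#' `cap` by uniform sampling without replacement (seeded, deterministic),
#' and computes the percentage of the sample curated as truly speculative.
#'
#' @param representative Pattern representative to profile.
#' @param matches Corpus-wide match data.frame (see [classify_corpus()]).
#' @param curated Curation table: data.frame with columns `doc_id`,
#'   `sentence_index`, `speculative` (logical). Must cover the sampled
#'   sentences.
#' @param cap Maximum number of sentences curated per pattern (default 50).
#' @param seed Integer seed for the sampling step.
#' @return One-row data.frame with `representative`, `sentence_count`,
#'   `sampled_count`, `speculative_count`, `percent_efficacy`, `computable`,
#'   `strength`. A pattern with zero matching sentences yields
#'   `sentence_count` 0 and `percent_efficacy` `NA` flagged not-computable
#'   (never 0).
#' @export
profile_efficacy <- function(representative, matches, curated,
                             cap = 50L, seed = 1L) {
  hits <- matches[matches$pattern == representative, , drop = FALSE]
  keys <- unique(sentence_key(hits$doc_id, hits$sentence_index))
  n <- length(keys)
  if (n == 0L) {
    return(data.frame(representative = representative, sentence_count = 0L,
                      sampled_count = 0L, speculative_count = 0L,
                      percent_efficacy = NA_real_, computable = FALSE,
                      strength = "unclassified", stringsAsFactors = FALSE))
  }
  sampled <- if (n > cap) {
    with_rng_seed(seed, sample(keys, cap))
  } else {
    keys
  }
  cur_keys <- sentence_key(curated$doc_id, curated$sentence_index)
  missing <- setdiff(sampled, cur_keys)
  if (length(missing) > 0L) {
    stopf("curated labels missing for %d sampled sentence(s) of pattern '%s'",
          length(missing), representative)
  }
  spec <- sum(curated$speculative[match(sampled, cur_keys)])
  pct <- 100 * spec / length(sampled)
  data.frame(representative = representative, sentence_count = n,
             sampled_count = length(sampled), speculative_count = spec,
             percent_efficacy = pct, computable = TRUE,
             strength = assign_strength(pct), stringsAsFactors = FALSE)
}

#' Assign a strength class from percent efficacy
#'
#' Patterns at or above the strong threshold are `strong`, below the weak
#' threshold `weak`, otherwise `moderate`. Non-computable efficacies map to
#' `unclassified`. Default thresholds (90, 50) reflect that modal-verb
#' patterns are near-always speculative while bare terms like "potential"
#' frequently are not; both are configurable.
#'
#' @param percent_efficacy Numeric vector in `[0, 100]` (NA allowed).
#' @param thresholds Numeric `c(strong, weak)` with
#'   `0 <= weak < strong <= 100`.
#' @return Character vector of strength classes.
#' @export
assign_strength <- function(percent_efficacy, thresholds = c(strong = 90, weak = 50)) {
  t_strong <- unname(thresholds[[1L]])
  t_weak <- unname(thresholds[[2L]])
  if (!(t_weak >= 0 && t_weak < t_strong && t_strong <= 100)) {
    stopf("thresholds must satisfy 0 <= weak < strong <= 100")
  }
  out <- ifelse(is.na(percent_efficacy), "unclassified",
                ifelse(percent_efficacy >= t_strong, "strong",
                       ifelse(percent_efficacy < t_weak, "weak", "moderate")))
  as.character(out)
}
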