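# Feature extraction for the sentence-classification baseline. Three
# namespaced families keep the feature sets separable:
#   base: one binary feature per case-folded word token
#   spec: one binary feature per dictionary pattern matching the sentence
#   lex:  lemma uni/bi/trigrams, 2/3/4-character prefixes and suffixes of
#         noun tokens, and dependency triples when a provider supplies them

#' Linguistic providers for lexico-syntactic features
#'
#' A provider supplies per-token lemmas and noun flags (and optionally
#' dependency triples) to [extract_features()]. `rule_linguistic_provider()`
#' is a deterministic, dependency-free baseline: lemmas by suffix stripping
#' (plural `-s`/`-ies`, `-ed`, `-ing`) and noun detection by a nominal
#' suffix heuristic plus a small biomedical noun list.
#' `lexicon_linguistic_provider()` looks tokens up in a fixed lexicon
#' (`data.frame(surface, lemma, is_noun)`), falling back to the folded
#' surface and `FALSE`; its determinism makes it the provider of choice in
#' tests. `dependencies`, if not `NULL`, must be
#' `function(tokens) data.frame(gov, rel, dep)`.
#'
#' @param lexicon For the lexicon provider, a data.frame with columns
#'   `surface`, `lemma`, `is_noun`.
#' @param dependencies Optional dependency function (see above).
#' @return An `hf_linguistic_provider`.
#' @export
rule_linguistic_provider <- function(dependencies = NULL) {
  noun_suffix <- "(tion|sion|ment|ness|ity|osis|emia|itis|ase|ein|ide|oid|cyte|gene|some)s?$"
  noun_list <- c("tau", "amyloid", "protein", "proteins", "gene", "genes",
                 "patients", "patient", "disease", "brain", "neuron",
                 "neurons", "biomarkers", "biomarker", "symptoms", "plaque",
                 "plaques", "model", "models", "mice", "cohort", "cohorts")
  analyze <- function(tokens) {
    lemma <- vapply(tokens$folded, lemmatize_rule, character(1), USE.NAMES = FALSE)
    is_noun <- grepl(noun_suffix, tokens$folded) | tokens$folded %in% noun_list
    data.frame(lemma = lemma, is_noun = is_noun, stringsAsFactors = FALSE)
  }
  structure(list(analyze = analyze, dependencies = dependencies),
            class = "hf_linguistic_provider")
}

lemmatize_rule <- function(w) {
  n <- nchar(w)
  if (n > 4L && endsWith(w, "ies")) return(paste0(substr(w, 1L, n - 3L), "y"))
  if (n > 5L && endsWith(w, "ing")) return(substr(w, 1L, n - 3L))
  if (n > 4L && endsWith(w, "ed")) return(substr(w, 1L, n - 2L))
  if (n > 3L && endsWith(w, "s") && !endsWith(w, "ss") && !endsWith(w, "us")) {
    return(substr(w, 1L, n - 1L))
  }
  w
}

#' @rdname rule_linguistic_provider
#' @export
lexicon_linguistic_provider <- function(lexicon, dependencies = NULL) {
  stopifnot(all(c("surface", "lemma", "is_noun") %in% names(lexicon)))
  key <- tolower(lexicon$surface)
  analyze <- function(tokens) {
    idx <- match(tokens$folded, key)
    data.frame(lemma = ifelse(is.na(idx), tokens$folded, lexicon$lemma[idx]),
               is_noun = ifelse(is.na(idx), FALSE, lexicon$is_noun[idx]),
               stringsAsFactors = FALSE)
  }
  structure(list(analyze = analyze, dependencies = dependencies),
            class = "hf_linguistic_provider")
}

#' Extract a sparse feature vector from a sentence
#'
#' @param sentence An `hf_sentence`.
#' @param modes Subset of `c("base", "spec", "lex")`.
#' @param index `hf_matcher_index`; required for `spec` features.
#' @param provider `hf_linguistic_provider`; required for `lex` features
#'   (requesting `lex` without one is a configuration error).
#' @return Named numeric vector of binary features; names are namespaced
#'   (`base:`, `spec:`, `lex:`), so removing a mode removes exactly its
#'   features.
#' @export
extract_features <- function(sentence, modes = c("base"),
                             index = NULL, provider = NULL) {
  bad <- setdiff(modes, c("base", "spec", "lex"))
  if (length(bad)) stopf("unknown feature mode(s): %s", paste(bad, collapse = ", "))
  toks <- sentence$tokens
  words <- toks[grepl("[[:alnum:]]", toks$surface), , drop = FALSE]
  feats <- character(0)
  if ("base" %in% modes) {
    feats <- c(feats, paste0("base:", unique(words$folded)))
  }
  if ("spec" %in% modes) {
    if (is.null(index)) stopf("spec features require a matcher index")
    m <- find_matches(sentence, index)
    if (nrow(m) > 0L) feats <- c(feats, paste0("spec:", unique(m$pattern)))
  }
  if ("lex" %in% modes) {
    if (is.null(provider)) {
      stopf("lex features require a configured linguistic provider")
    }
    if (nrow(words) > 0L) {
      ana <- provider$analyze(words)
      lem <- ana$lemma
      feats <- c(feats, paste0("lex:uni:", unique(lem)))
      if (length(lem) >= 2L) {
        feats <- c(feats, paste0("lex:bi:", unique(paste(lem[-length(lem)],
                                                         lem[-1L], sep = "|"))))
      }
      if (length(lem) >= 3L) {
        k <- length(lem)
        feats <- c(feats, paste0("lex:tri:", unique(paste(lem[1:(k - 2L)],
                                                          lem[2:(k - 1L)],
                                                          lem[3:k], sep = "|"))))
      }
      nouns <- words$folded[ana$is_noun]
      for (w in unique(nouns)) {
        for (k in 2:4) {
          if (nchar(w) >= k) {
            feats <- c(feats, paste0("lex:pre", k, ":", substr(w, 1L, k)),
                       paste0("lex:suf", k, ":",
                              substr(w, nchar(w) - k + 1L, nchar(w))))
          }
        }
      }
      if (!is.null(provider$dependencies)) {
        deps <- provider$dependencies(words)
        if (NROW(deps) > 0L) {
          feats <- c(feats, paste0("lex:dep:", paste(deps$gov, deps$rel,
                                                     deps$dep, sep = "|")))
        }
      }
    }
  }
  feats <- unique(feats)
  stats::setNames(rep(1, length(feats)), feats)
}
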