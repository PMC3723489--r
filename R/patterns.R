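# Speculative patterns and the token-sequence index used by the matcher.

#' Build speculative patterns from a parsed dictionary
#'
#' Each dictionary entry becomes one pattern whose surface forms are the
#' case-folded token sequences of the representative and all synonyms
#' (tokenized with [tokenize()], duplicates removed). Strength defaults to
#' `"unclassified"` when the file does not provide it.
#'
#' @param dictionary An `hf_dictionary`.
#' @return An `hf_patterns` object: list of patterns with elements
#'   `representative`, `strength` and `forms` (each form a list with `text`
#'   and folded `tokens`).
#' @export
build_patterns <- function(dictionary) {
  patterns <- lapply(dictionary, function(entry) {
    texts <- c(entry$representative, entry$synonyms)
    forms <- list()
    seen <- character(0)
    for (tx in texts) {
      toks <- tokenize(tx)$folded
      if (length(toks) == 0L) {
        stopf("dictionary entry '%s': form '%s' has no tokens",
              entry$representative, tx)
      }
      key <- paste(toks, collapse = "\x1f")
      if (key %in% seen) next
      seen <- c(seen, key)
      forms[[length(forms) + 1L]] <- list(text = tx, tokens = toks)
    }
    list(representative = entry$representative,
         strength = entry$strength %||% "unclassified",
         forms = forms)
  })
  structure(patterns, class = "hf_patterns")
}

#' Compose a weak speculative term with strengthening modifiers
#'
#' Weak terms ("potential", "possibility", ...) are unreliable speculation
#' cues on their own; they enter the dictionary only combined with
#' additional speculative words, auxiliary verbs or adjectives. This returns
#' the cross-product compositions, e.g. `"could be a" + "potential"` gives
#' `"could be a potential"`. The bare weak term itself is never returned.
#'
#' @param weak_term Non-empty string.
#' @param modifiers Character vector of strengthening phrases; if empty the
#'   result is empty (the term stays excluded).
#' @param placement `"prefix"` places modifiers before the term, `"suffix"`
#'   after it.
#' @param trailing Optional string appended after each composition (e.g.
#'   `"that"` for `"raising the possibility that"`).
#' @return Character vector of composed surface strings.
#' @export
strengthen_weak <- function(weak_term, modifiers,
                            placement = c("prefix", "suffix"),
                            trailing = NULL) {
  placement <- match.arg(placement)
  if (!is.character(weak_term) || length(weak_term) != 1L ||
      !nzchar(trimws(weak_term))) {
    stopf("weak_term must be a non-empty string")
  }
  modifiers <- modifiers[nzchar(trimws(modifiers))]
  if (length(modifiers) == 0L) return(character(0))
  composed <- if (placement == "prefix") {
    paste(trimws(modifiers), trimws(weak_term))
  } else {
    paste(trimws(weak_term), trimws(modifiers))
  }
  if (!is.null(trailing) && nzchar(trimws(trailing))) {
    composed <- paste(composed, trimws(trailing))
  }
  composed
}

#' Compile patterns into a matcher index
#'
#' Builds a first-token hash over every surface form so that, at a given
#' token position, all dictionary forms starting there can be enumerated.
#' A form duplicated across entries is owned by the earliest entry; later
#' occurrences are dropped with a warning.
#'
#' @param patterns An `hf_patterns` object (non-empty).
#' @return An `hf_matcher_index`.
#' @export
compile_index <- function(patterns) {
  if (!length(patterns)) stopf("cannot compile an empty pattern set")
  buckets <- new.env(hash = TRUE, parent = emptyenv())
  owner <- new.env(hash = TRUE, parent = emptyenv())
  n_forms <- 0L
  for (i in seq_along(patterns)) {
    pat <- patterns[[i]]
    for (j in seq_along(pat$forms)) {
      form <- pat$forms[[j]]
      key <- paste(form$tokens, collapse = "\x1f")
      if (!is.null(owner[[key]])) {
        warnf("surface form '%s' duplicated across entries '%s' and '%s'; keeping first",
              form$text, owner[[key]], pat$representative)
        next
      }
      owner[[key]] <- pat$representative
      first <- form$tokens[[1L]]
      cand <- list(tokens = form$tokens, n = length(form$tokens),
                   text = form$text, nchar = nchar(form$text),
                   representative = pat$representative, entry = i)
      buckets[[first]] <- c(buckets[[first]], list(cand))
      n_forms <- n_forms + 1L
    }
  }
  structure(list(buckets = buckets, n_forms = n_forms, patterns = patterns),
            class = "hf_matcher_index")
}

#' @export
print.hf_matcher_index <- function(x, ...) {
  cat(sprintf("<hf_matcher_index: %d patterns, %d surface forms>\n",
              length(x$patterns), x$n_forms))
  invisible(x)
}
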