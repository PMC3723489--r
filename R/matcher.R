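# Dictionary matching under the search constraints of the method:
# case-insensitive, word-order-sensitive, longest exact match, never
# crossing sentence boundaries.

empty_matches <- function() {
  data.frame(doc_id = character(0), sentence_index = integer(0),
             start = integer(0), end = integer(0),
             pattern = character(0), surface = character(0),
             stringsAsFactors = FALSE)
}

match_row <- function(sentence, i, len, representative) {
  toks <- sentence$tokens
  start <- toks$start[i]
  end <- toks$end[i + len - 1L]
  data.frame(doc_id = sentence$doc_id, sentence_index = sentence$index,
             start = start, end = end, pattern = representative,
             surface = slice_text(sentence$text, start - sentence$start,
                                  end - sentence$start),
             stringsAsFactors = FALSE)
}

#' Find speculative-pattern matches in a sentence
#'
#' Scans tokens left to right; at each position the longest dictionary form
#' (in tokens) whose case-folded token sequence matches exactly and
#' contiguously is taken, ties broken by longer character span then by
#' dictionary entry order. After a match, scanning resumes at the following
#' token, so matches never overlap. Deterministic.
#'
#' @param sentence An `hf_sentence`.
#' @param index An `hf_matcher_index` from [compile_index()].
#' @return Match data.frame with columns `doc_id`, `sentence_index`,
#'   `start`, `end` (document coordinates), `pattern` (representative),
#'   `surface`.
#' @export
find_matches <- function(sentence, index) {
  stopifnot(inherits(index, "hf_matcher_index"))
  toks <- sentence$tokens
  n <- nrow(toks)
  out <- list()
  i <- 1L
  while (i <= n) {
    bucket <- index$buckets[[toks$folded[i]]]
    best <- NULL
    if (!is.null(bucket)) {
      for (cand in bucket) {
        L <- cand$n
        if (i + L - 1L > n) next
        if (!identical(toks$folded[i:(i + L - 1L)], cand$tokens)) next
        span <- toks$end[i + L - 1L] - toks$start[i]
        if (is.null(best) ||
            L > best$L ||
            (L == best$L && span > best$span) ||
            (L == best$L && span == best$span && cand$entry < best$entry)) {
          best <- list(L = L, span = span, entry = cand$entry,
                       representative = cand$representative)
        }
      }
    }
    if (is.null(best)) {
      i <- i + 1L
    } else {
      out[[length(out) + 1L]] <- match_row(sentence, i, best$L,
                                           best$representative)
      i <- i + best$L
    }
  }
  if (length(out) == 0L) return(empty_matches())
  do.call(rbind, out)
}

#' Reference matcher by direct enumeration
#'
#' Test oracle for [find_matches()]: enumerates every (position, form)
#' candidate by direct token-sequence comparison against the uncompiled
#' pattern list, then applies the identical leftmost-longest non-overlapping
#' selection. Output must equal [find_matches()] on any input.
#'
#' @param sentence An `hf_sentence`.
#' @param patterns An `hf_patterns` object.
#' @return Same shape as [find_matches()].
#' @export
brute_force_matches <- function(sentence, patterns) {
  toks <- sentence$tokens
  n <- nrow(toks)
  if (n == 0L || length(patterns) == 0L) return(empty_matches())
  # enumerate candidates; first entry owns duplicated forms
  owned <- character(0)
  cands <- list()
  for (e in seq_along(patterns)) {
    for (form in patterns[[e]]$forms) {
      key <- paste(form$tokens, collapse = "\x1f")
      if (key %in% owned) next
      owned <- c(owned, key)
      L <- length(form$tokens)
      if (L > n) next
      for (pos in seq_len(n - L + 1L)) {
        if (identical(toks$folded[pos:(pos + L - 1L)], form$tokens)) {
          cands[[length(cands) + 1L]] <-
            list(pos = pos, L = L,
                 span = toks$end[pos + L - 1L] - toks$start[pos],
                 entry = e, representative = patterns[[e]]$representative)
        }
      }
    }
  }
  out <- list()
  i <- 1L
  while (i <= n) {
    here <- Filter(function(c) c$pos == i, cands)
    if (length(here) == 0L) { i <- i + 1L; next }
    best <- here[[1L]]
    for (c in here[-1L]) {
      if (c$L > best$L ||
          (c$L == best$L && c$span > best$span) ||
          (c$L == best$L && c$span == best$span && c$entry < best$entry)) {
        best <- c
      }
    }
    out[[length(out) + 1L]] <- match_row(sentence, i, best$L,
                                         best$representative)
    i <- i + best$L
  }
  if (length(out) == 0L) return(empty_matches())
  do.call(rbind, out)
}
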