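# Rule-based sentence segmentation and tokenization. Both are deterministic
# and offset-faithful: every emitted unit carries 0-based half-open character
# offsets into the document text, and text[start:end] always reproduces the
# surface form.

# Abbreviations whose trailing period never ends a sentence. Compared case-
# insensitively against the word immediately preceding a candidate break.
ABBREVIATIONS <- c("e.g", "i.e", "et al", "al", "vs", "cf", "ca", "fig",
                   "figs", "eq", "ref", "refs", "no", "approx", "dr", "prof")

#' Tokenize text into offset-anchored word and punctuation tokens
#'
#' Tokens are maximal runs of alphanumeric characters (internal apostrophes
#' allowed); every other non-space character is emitted as a single
#' punctuation token, so hyphens and parentheses are token boundaries:
#' `"Abeta(1-42)"` yields `Abeta ( 1 - 42 )`.
#'
#' @param text Character scalar to tokenize.
#' @param base_offset Offset of `text` within its document (0-based); token
#'   offsets are reported in document coordinates.
#' @return A data.frame with columns `surface`, `start`, `end`, `folded`.
#' @export
tokenize <- function(text, base_offset = 0L) {
  empty <- data.frame(surface = character(0), start = integer(0),
                      end = integer(0), folded = character(0),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("[[:alnum:]'’]+|[^[:alnum:][:space:]'’]", text,
                perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  surface <- substring(text, starts, starts + lens - 1L)
  start0 <- base_offset + starts - 1L
  data.frame(surface = surface, start = start0, end = start0 + lens,
             folded = tolower(surface), stringsAsFactors = FALSE)
}

new_sentence <- function(doc_id, index, start, end, text) {
  structure(list(doc_id = doc_id, index = index, start = start, end = end,
                 text = text, tokens = tokenize(text, base_offset = start)),
            class = "hf_sentence")
}

#' Split a document into offset-anchored sentences
#'
#' Splits on sentence-final punctuation (`.`, `!`, `?`) followed by
#' whitespace and an uppercase letter, digit or opening bracket/quote, while
#' protecting a fixed abbreviation list (`e.g.`, `i.e.`, `et al.`, `Fig.`,
#' `vs.`, ...). Text without terminal punctuation yields one sentence.
#' Deterministic: identical input bytes give identical segmentation.
#'
#' @param document An `hf_document`.
#' @return List of `hf_sentence` objects; each carries its tokens
#'   ([tokenize()]) in document coordinates. Sentence `index` is 1-based.
#' @export
segment_sentences <- function(document) {
  text <- document$text
  m <- gregexpr("[.!?]+(?=[[:space:]]+[\"'(\\[]?[A-Z0-9])", text,
                perl = TRUE)[[1L]]
  break_ends <- integer(0)
  if (m[1L] != -1L) {
    for (k in seq_along(m)) {
      p <- as.integer(m[k])                       # 1-based punct position
      len <- attr(m, "match.length")[k]
      before <- substr(text, 1L, p - 1L)
      wm <- regmatches(before, regexpr("[[:alpha:]]+$", before))
      protected <- FALSE
      if (length(wm) == 1L) {
        w <- tolower(wm)
        protected <- w %in% ABBREVIATIONS
        if (identical(w, "al")) protected <- TRUE  # et al.
      }
      if (!protected) break_ends <- c(break_ends, p + len - 1L)
    }
  }
  bounds <- c(0L, break_ends, nchar(text))        # 1-based inclusive ends
  sentences <- list()
  idx <- 0L
  for (k in seq_len(length(bounds) - 1L)) {
    lo <- bounds[k] + 1L
    hi <- bounds[k + 1L]
    # trim surrounding whitespace but keep offsets anchored
    while (lo <= hi && grepl("^[[:space:]]$", substr(text, lo, lo))) lo <- lo + 1L
    while (hi >= lo && grepl("^[[:space:]]$", substr(text, hi, hi))) hi <- hi - 1L
    if (lo > hi) next
    idx <- idx + 1L
    sentences[[idx]] <- new_sentence(document$doc_id, idx,
                                     start = lo - 1L, end = hi,
                                     text = substr(text, lo, hi))
  }
  sentences
}

#' @export
print.hf_sentence <- function(x, ...) {
  cat(sprintf("<hf_sentence %s#%d [%d,%d)> %s\n", x$doc_id, x$index,
              x$start, x$end, x$text))
  invisible(x)
}

# Segment every document of a corpus; returns a flat list of sentences.
corpus_sentences <- function(corpus) {
  unlist(lapply(corpus, segment_sentences), recursive = FALSE, use.names = FALSE)
}
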