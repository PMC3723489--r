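#' Construct a document
#'
#' A document is an identifier (typically a PMID) plus the abstract text it
#' labels. Sentences are attached lazily by [segment_sentences()].
#'
#' @param doc_id Non-empty identifier string, unique within a corpus.
#' @param text Non-empty abstract text (title may be a prefix).
#' @return An object of class `hf_document`.
#' @export
new_document <- function(doc_id, text) {
  if (!is.character(doc_id) || length(doc_id) != 1L || !nzchar(doc_id)) {
    stopf("doc_id must be a non-empty string")
  }
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    stopf("document '%s': text must be a non-empty string", doc_id)
  }
  structure(list(doc_id = doc_id, text = text, sentences = NULL),
            class = "hf_document")
}

#' Construct a corpus from a list of documents
#'
#' @param documents List of `hf_document` objects with unique ids.
#' @return An object of class `hf_corpus` (a named list of documents).
#' @export
as_corpus <- function(documents) {
  ids <- vapply(documents, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids)) {
    stopf("duplicate doc_id in corpus: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(documents) <- ids
  structure(documents, class = "hf_corpus")
}

#' @export
print.hf_corpus <- function(x, ...) {
  cat(sprintf("<hf_corpus: %d documents>\n", length(x)))
  invisible(x)
}

#' Read a PMID-tagged plain-text abstract corpus
#'
#' The format is one record per block: a first line `PMID<TAB>id`, then one
#' or more lines of abstract text, blocks separated by blank lines. Line
#' breaks inside a block are joined with a single space so that character
#' offsets over the joined text are stable.
#'
#' @param path Path to a UTF-8 text file.
#' @return An `hf_corpus`. An empty file yields an empty corpus.
#' @export
read_plain_corpus <- function(path) {
  if (!file.exists(path)) stopf("corpus file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blank <- !nzchar(trimws(lines))
  if (length(lines) == 0L || all(blank)) return(as_corpus(list()))
  block_id <- cumsum(c(TRUE, blank[-length(blank)])) # blanks open a new block
  docs <- list()
  for (b in split(seq_along(lines), block_id)) {
    blk <- lines[b]
    blk <- blk[nzchar(trimws(blk))]
    if (length(blk) == 0L) next
    header <- strsplit(blk[[1L]], "\t", fixed = TRUE)[[1L]]
    if (length(header) < 2L || toupper(trimws(header[[1L]])) != "PMID" ||
        !nzchar(trimws(header[[2L]]))) {
      stopf("block %d: first line must be 'PMID<TAB>id', got '%s'",
            length(docs) + 1L, blk[[1L]])
    }
    body <- trimws(blk[-1L])
    if (length(body) == 0L) {
      stopf("block %d (PMID %s): no abstract text", length(docs) + 1L,
            trimws(header[[2L]]))
    }
    docs[[length(docs) + 1L]] <- new_document(trimws(header[[2L]]),
                                              paste(body, collapse = " "))
  }
  as_corpus(docs)
}

#' Write a corpus in the PMID-tagged plain-text format
#'
#' Inverse of [read_plain_corpus()] for single-line document texts.
#'
#' @param corpus An `hf_corpus`.
#' @param path Output path.
#' @export
write_plain_corpus <- function(corpus, path) {
  blocks <- vapply(corpus, function(d) {
    paste0("PMID\t", d$doc_id, "\n", d$text)
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = FALSE)
  invisible(path)
}
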