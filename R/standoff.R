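# Standoff TSV annotations: doc_id, sentence_index, start, end, pattern,
# surface. Offsets are 0-based half-open character offsets into the
# normalized document text.

empty_spans <- function() {
  data.frame(doc_id = character(0), start = integer(0), end = integer(0),
             surface = character(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' Write matches as a standoff TSV file
#'
#' Columns: `doc_id`, `sentence_index`, `start`, `end`, `pattern`,
#' `surface`. Zero matches produce a header-only file. Writing then reading
#' with [read_annotations()] is the identity on the span fields.
#'
#' @param matches Match data.frame (see [find_matches()]).
#' @param path Output path.
#' @export
write_matches <- function(matches, path) {
  cols <- c("doc_id", "sentence_index", "start", "end", "pattern", "surface")
  out <- matches[, cols, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read standoff annotations
#'
#' Reads the TSV format written by [write_matches()] (the `pattern` and
#' `sentence_index` columns are optional for externally produced gold
#' annotations). When `corpus` is supplied, every span is validated against
#' the named document: `surface` must equal the text slice at
#' `[start, end)`.
#'
#' @param path Path to a TSV file with at least `doc_id`, `start`, `end`,
#'   `surface` columns.
#' @param corpus Optional `hf_corpus` for consistency checking.
#' @return Data.frame of annotation spans with a `label` column
#'   (`"speculative_pattern"`).
#' @export
read_annotations <- function(path, corpus = NULL) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8",
                           colClasses = NA)
  needed <- c("doc_id", "start", "end", "surface")
  miss <- setdiff(needed, names(tab))
  if (length(miss)) stopf("annotation file lacks column(s): %s",
                          paste(miss, collapse = ", "))
  tab$doc_id <- as.character(tab$doc_id)
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab$surface <- as.character(tab$surface)
  if (!"label" %in% names(tab)) tab$label <- "speculative_pattern"
  if (any(tab$start < 0L) || any(tab$start >= tab$end)) {
    stopf("invalid span offsets: need 0 <= start < end")
  }
  if (!is.null(corpus)) validate_spans(tab, corpus)
  tab
}

# Check every span lies inside its document and reproduces its surface.
validate_spans <- function(spans, corpus) {
  for (k in seq_len(nrow(spans))) {
    id <- spans$doc_id[k]
    doc <- corpus[[id]]
    if (is.null(doc)) stopf("span references unknown document '%s'", id)
    if (spans$end[k] > nchar(doc$text)) {
      stopf("span [%d,%d) exceeds document '%s' (length %d)",
            spans$start[k], spans$end[k], id, nchar(doc$text))
    }
    got <- slice_text(doc$text, spans$start[k], spans$end[k])
    if (!identical(got, spans$surface[k])) {
      stopf("span surface mismatch in document '%s' at [%d,%d): file says '%s', text says '%s'",
            id, spans$start[k], spans$end[k], spans$surface[k], got)
    }
  }
  invisible(spans)
}

#' Write annotation spans as standoff TSV
#'
#' @param spans Span data.frame (`doc_id`, `start`, `end`, `surface`, and
#'   optionally `label`).
#' @param path Output path.
#' @export
write_annotations <- function(spans, path) {
  if (!"label" %in% names(spans)) spans$label <- "speculative_pattern"
  cols <- c("doc_id", "start", "end", "surface", "label")
  utils::write.table(spans[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
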