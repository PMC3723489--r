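# Reader for BioScope-dialect XML: documents containing <sentence> elements
# whose speculation cues are marked as <cue type="speculation">...</cue>.
# Negation cues and scope (<xcope>) elements contribute their character data
# but produce no annotations.

#' Read a BioScope-style speculation corpus
#'
#' Reconstructs each document's text by concatenating its sentences
#' (separated by a single space) and converts every speculation-typed cue
#' into an annotation span whose offsets index the reconstructed text.
#' Cue elements may be nested (inside scopes or other cues); each
#' speculation cue yields its own span. Negation cues are ignored.
#'
#' Accepted structure: one or more `<Document>` elements (id taken from a
#' `DocID` child or an `id` attribute, else assigned sequentially), each
#' containing `<sentence>` elements anywhere below it. A file whose root
#' holds sentences directly is treated as a single document.
#'
#' @param path Path to a BioScope-dialect XML file.
#' @return List with `documents` (an `hf_corpus`) and `annotations` (span
#'   data.frame `doc_id`, `start`, `end`, `surface`, `label`).
#' @export
read_bioscope <- function(path) {
  if (!file.exists(path)) stopf("BioScope file not found: %s", path)
  xml <- tryCatch(xml2::read_xml(path),
                  error = function(e) stopf("malformed XML in %s: %s",
                                            path, conditionMessage(e)))
  doc_nodes <- xml2::xml_find_all(xml, "//Document")
  if (length(doc_nodes) == 0L) doc_nodes <- list(xml)
  docs <- list()
  spans <- list()
  for (d in seq_along(doc_nodes)) {
    node <- doc_nodes[[d]]
    id <- bioscope_doc_id(node, d)
    sent_nodes <- xml2::xml_find_all(node, ".//sentence")
    if (length(sent_nodes) == 0L) next
    text_parts <- character(0)
    offset <- 0L
    for (s in sent_nodes) {
      walk <- bioscope_walk(s)
      stext <- walk$text
      # trim outer whitespace, shifting cue offsets accordingly
      lead <- nchar(stext) - nchar(sub("^[[:space:]]+", "", stext))
      stext <- trimws(stext)
      if (!nzchar(stext)) next
      if (nrow(walk$cues) > 0L) {
        walk$cues$start <- walk$cues$start - lead + offset
        walk$cues$end <- walk$cues$end - lead + offset
        walk$cues$doc_id <- id
        spans[[length(spans) + 1L]] <- walk$cues
      }
      text_parts <- c(text_parts, stext)
      offset <- offset + nchar(stext) + 1L   # single joining space
    }
    if (length(text_parts) == 0L) next
    docs[[length(docs) + 1L]] <- new_document(id, paste(text_parts, collapse = " "))
  }
  corpus <- as_corpus(docs)
  annotations <- if (length(spans)) do.call(rbind, spans) else empty_spans()
  if (nrow(annotations) > 0L) {
    annotations <- annotations[, c("doc_id", "start", "end", "surface", "label")]
    rownames(annotations) <- NULL
    validate_spans(annotations, corpus)   # consistency error on crossing cues
  }
  list(documents = corpus, annotations = annotations)
}

bioscope_doc_id <- function(node, ordinal) {
  id_child <- xml2::xml_find_first(node, "./DocID")
  if (!inherits(id_child, "xml_missing")) {
    id <- trimws(xml2::xml_text(id_child))
    if (nzchar(id)) return(id)
  }
  attr_id <- xml2::xml_attr(node, "id")
  if (!is.na(attr_id) && nzchar(attr_id)) return(attr_id)
  sprintf("bioscope_%d", ordinal)
}

# Depth-first accumulation of a sentence's character data; records the
# [start, end) extent of every speculation cue relative to sentence start.
bioscope_walk <- function(sentence_node) {
  acc <- new.env(parent = emptyenv())
  acc$text <- ""
  acc$cues <- list()
  recurse <- function(node) {
    for (child in xml2::xml_contents(node)) {
      type <- xml2::xml_type(child)
      if (type == "text" || type == "cdata") {
        acc$text <- paste0(acc$text, xml2::xml_text(child))
      } else if (type == "element") {
        name <- xml2::xml_name(child)
        if (identical(name, "cue")) {
          from <- nchar(acc$text)
          recurse(child)
          to <- nchar(acc$text)
          if (identical(xml2::xml_attr(child, "type"), "speculation") &&
              to > from) {
            acc$cues[[length(acc$cues) + 1L]] <-
              list(start = from, end = to,
                   surface = substr(acc$text, from + 1L, to))
          }
        } else {
          recurse(child)   # xcope, DocID removal handled upstream, etc.
        }
      }
    }
  }
  recurse(sentence_node)
  cues <- if (length(acc$cues)) {
    data.frame(doc_id = NA_character_,
               start = vapply(acc$cues, `[[`, integer(1), "start"),
               end = vapply(acc$cues, `[[`, integer(1), "end"),
               surface = vapply(acc$cues, `[[`, character(1), "surface"),
               label = "speculative_pattern", stringsAsFactors = FALSE)
  } else {
    empty_spans()
  }
  list(text = acc$text, cues = cues)
}
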