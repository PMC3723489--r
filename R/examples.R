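#' Published reference sentences for the speculation detector
#'
#' A small set of sentences from published PubMed abstracts used as
#' reference examples: speculative sentences the seed dictionary must label
#' POSITIVE, and non-speculative controls (inferences, results and
#' conclusions, argumentative sentences, open questions, and bare weak-term
#' sentences) it must label NEGATIVE. `doc_id` is the source PMID where one
#' applies.
#'
#' @return Data.frame with columns `doc_id`, `expected`
#'   (`"POSITIVE"`/`"NEGATIVE"`) and `text`.
#' @export
example_sentences <- function() {
  path <- system.file("extdata", "example_sentences.tsv",
                      package = "hypofinder", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}
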