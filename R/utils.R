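# Internal helpers shared across modules.

# All character offsets in this package are 0-based, half-open [start, end)
# over the normalized document text. substr() is 1-based, hence the shift.
slice_text <- function(text, start, end) {
  substr(text, start + 1L, end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.
with_rng_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

sentence_key <- function(doc_id, sentence_index) {
  paste(doc_id, sentence_index, sep = "\r")
}

span_key <- function(doc_id, start, end) {
  paste(doc_id, start, end, sep = "\r")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
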