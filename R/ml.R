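# Sentence-classification baseline: instance construction from gold spans,
# a maximum-entropy (L2-regularized logistic regression) classifier, and
# switchable alternative algorithms behind the same contract.

ALGORITHMS <- c("maxent", "naive_bayes", "knn", "decision_tree", "svm")

#' Build labeled training instances from gold annotations
#'
#' Every sentence of every document yields exactly one instance; the label
#' is POSITIVE iff at least one gold span overlaps the sentence's character
#' range. A span lying outside every sentence, or straddling a sentence
#' boundary, is a consistency error.
#'
#' @param corpus An `hf_corpus`.
#' @param gold_spans Span data.frame (`doc_id`, `start`, `end`).
#' @return List with `instances` (data.frame `doc_id`, `sentence_index`,
#'   `label`) and `sentences` (the segmented sentences, aligned by
#'   position).
#' @export
build_instances <- function(corpus, gold_spans) {
  sentences <- corpus_sentences(corpus)
  skey <- vapply(sentences, function(s) sentence_key(s$doc_id, s$index),
                 character(1))
  label <- rep("NEGATIVE", length(sentences))
  for (k in seq_len(nrow(gold_spans))) {
    id <- gold_spans$doc_id[k]
    s0 <- gold_spans$start[k]
    e0 <- gold_spans$end[k]
    hit <- which(vapply(sentences, function(s) {
      s$doc_id == id && s0 < s$end && s$start < e0
    }, logical(1)))
    if (length(hit) == 0L) {
      stopf("gold span %s[%d,%d) lies outside every sentence", id, s0, e0)
    }
    inside <- which(vapply(sentences, function(s) {
      s$doc_id == id && s0 >= s$start && e0 <= s$end
    }, logical(1)))
    if (length(inside) == 0L) {
      stopf("gold span %s[%d,%d) straddles a sentence boundary", id, s0, e0)
    }
    label[inside[[1L]]] <- "POSITIVE"
  }
  instances <- data.frame(
    doc_id = vapply(sentences, `[[`, character(1), "doc_id"),
    sentence_index = vapply(sentences, `[[`, integer(1), "index"),
    label = label, stringsAsFactors = FALSE)
  rownames(instances) <- NULL
  stopifnot(!anyDuplicated(skey))
  list(instances = instances, sentences = sentences)
}

feature_matrix <- function(sentences, modes, index, provider, vocab = NULL) {
  feats <- lapply(sentences, extract_features, modes = modes,
                  index = index, provider = provider)
  if (is.null(vocab)) {
    vocab <- sort(unique(unlist(lapply(feats, names), use.names = FALSE)))
  }
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (r in seq_along(feats)) {
    j <- match(names(feats[[r]]), vocab)
    keep <- !is.na(j)
    ii <- c(ii, rep(r, sum(keep)))
    jj <- c(jj, j[keep])
    xx <- c(xx, unname(feats[[r]])[keep])
  }
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(feats), max(1L, length(vocab))))
  colnames(X) <- if (length(vocab)) vocab else "..empty.."
  list(X = X, vocab = vocab)
}

#' Train a hypothetical-sentence classifier
#'
#' The required algorithm, `maxent`, is maximum entropy realized as
#' L2-regularized (ridge) binomial logistic regression with regularization
#' strength `C` (penalty `lambda = 1/(C * n)`), fit with `glmnet`. The
#' remaining algorithms are optional alternatives behind the same contract:
#' `naive_bayes` and `svm` (e1071), `decision_tree` (rpart), `knn` (class).
#' Training is deterministic given `seed`.
#'
#' @param instances Label data.frame from [build_instances()]; both classes
#'   must be present.
#' @param sentences Sentences aligned with `instances`.
#' @param algorithm One of `"maxent"`, `"naive_bayes"`, `"knn"`,
#'   `"decision_tree"`, `"svm"`.
#' @param modes Feature families, subset of `c("base","spec","lex")`.
#' @param index Matcher index (needed for `spec`); stored in the model.
#' @param provider Linguistic provider (needed for `lex`); stored in the
#'   model.
#' @param seed Integer seed.
#' @param C Inverse regularization strength for `maxent`
#'   (`lambda = 1/(C*n)`; default 10). The default is deliberately weak:
#'   cue-indicator features that occur only a handful of times must still
#'   be able to drive a sentence past the decision threshold.
#' @param k Neighbour count for `knn` (default 5).
#' @return An `hf_model`.
#' @export
train_sentence_classifier <- function(instances, sentences,
                                      algorithm = "maxent",
                                      modes = c("base"),
                                      index = NULL, provider = NULL,
                                      seed = 1L, C = 10, k = 5L) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  if (nrow(instances) < 2L || length(unique(instances$label)) < 2L) {
    stopf("training requires at least two instances with both labels present")
  }
  stopifnot(nrow(instances) == length(sentences))
  fm <- feature_matrix(sentences, modes, index, provider)
  y <- factor(instances$label, levels = c("NEGATIVE", "POSITIVE"))
  n <- nrow(fm$X)
  fit <- with_rng_seed(seed, switch(
    algorithm,
    maxent = {
      X <- fm$X
      if (ncol(X) < 2L) X <- cbind(X, ..pad.. = 0)
      lam <- 1 / (C * n)
      # glmnet converges reliably only along a decreasing lambda path;
      # predictions are taken at the target penalty.
      glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                     lambda = lam * 10^seq(3, 0, length.out = 25),
                     standardize = FALSE)
    },
    naive_bayes = {
      require_suggested("e1071", "naive_bayes")
      e1071::naiveBayes(as.data.frame(as.matrix(fm$X)), y)
    },
    knn = {
      require_suggested("class", "knn")
      list(train = as.matrix(fm$X), y = y, k = k)
    },
    decision_tree = {
      require_suggested("rpart", "decision_tree")
      df <- as.data.frame(as.matrix(fm$X))
      names(df) <- paste0("f", seq_len(ncol(df)))
      df$..label.. <- y
      rpart::rpart(..label.. ~ ., data = df, method = "class")
    },
    svm = {
      require_suggested("e1071", "svm")
      e1071::svm(as.matrix(fm$X), y, kernel = "linear", scale = FALSE)
    }))
  majority <- names(which.max(table(y)))
  structure(list(algorithm = algorithm, modes = modes, vocab = fm$vocab,
                 fit = fit, index = index, provider = provider,
                 majority = majority, C = C, k = k, seed = seed,
                 n_train = n, class_counts = as.list(table(y))),
            class = "hf_model")
}

require_suggested <- function(pkg, algorithm) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stopf("algorithm '%s' needs the suggested package '%s'", algorithm, pkg)
  }
}

#' @export
print.hf_model <- function(x, ...) {
  cat(sprintf("<hf_model %s | features: %s | %d train instances, %d features>\n",
              x$algorithm, paste(x$modes, collapse = "+"), x$n_train,
              length(x$vocab)))
  invisible(x)
}

#' Predict sentence labels with a trained classifier
#'
#' Features are extracted under the namespaces the model was trained on
#' (using the index/provider stored in the model); unseen features are
#' dropped. A sentence with no known features receives the training
#' majority class.
#'
#' @param object An `hf_model`.
#' @param sentences List of `hf_sentence` objects.
#' @param ... Unused.
#' @return Label data.frame (`doc_id`, `sentence_index`, `label`).
#' @export
predict.hf_model <- function(object, sentences, ...) {
  fm <- feature_matrix(sentences, object$modes, object$index,
                       object$provider, vocab = object$vocab)
  X <- fm$X
  nonempty <- Matrix::rowSums(X != 0) > 0
  lab <- rep(object$majority, length(sentences))
  if (any(nonempty)) {
    pred <- switch(
      object$algorithm,
      maxent = {
        Xp <- X
        if (ncol(Xp) < 2L) Xp <- cbind(Xp, ..pad.. = 0)
        as.character(stats::predict(object$fit, newx = Xp, type = "class",
                                    s = 1 / (object$C * object$n_train)))
      },
      naive_bayes = as.character(stats::predict(object$fit,
                                                as.data.frame(as.matrix(X)))),
      knn = as.character(class::knn(object$fit$train, as.matrix(X),
                                    object$fit$y, k = object$fit$k)),
      decision_tree = {
        df <- as.data.frame(as.matrix(X))
        names(df) <- paste0("f", seq_len(ncol(df)))
        as.character(stats::predict(object$fit, df, type = "class"))
      },
      svm = as.character(stats::predict(object$fit, as.matrix(X))))
    lab[nonempty] <- pred[nonempty]
  }
  data.frame(doc_id = vapply(sentences, `[[`, character(1), "doc_id"),
             sentence_index = vapply(sentences, `[[`, integer(1), "index"),
             label = lab, stringsAsFactors = FALSE)
}
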