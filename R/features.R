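#' Preprocess a corpus for machine learning
#'
#' Tokenizes (lowercase, punctuation stripped), removes stop words, and
#' prunes terms whose total corpus occurrence count falls below
#' `min_term_freq`. The vocabulary is sorted lexicographically so it is
#' deterministic for a given corpus.
#'
#' @param texts character vector of document texts, or a document tibble.
#' @param stopwords character vector of stop words to drop.
#' @param min_term_freq minimum total corpus occurrences of a retained term.
#' @return list with `tokens` (stop-word-free token vectors) and
#'   `vocabulary` (sorted character vector).
#' @export
preprocess_for_ml <- function(texts, stopwords = english_stopwords(),
                              min_term_freq = 2L) {
  if (is.data.frame(texts)) texts <- texts$text
  tokens <- tokenize(texts)
  tokens <- lapply(tokens, function(tk) tk[!(tk %in% stopwords)])
  freq <- table(unlist(tokens))
  vocabulary <- sort(names(freq[freq >= min_term_freq]))
  if (length(vocabulary) == 0L) {
    stop("empty vocabulary after stop-word and frequency pruning",
         call. = FALSE)
  }
  list(tokens = tokens, vocabulary = vocabulary)
}

#' Fit a tf-idf featurizer
#'
#' Computes document frequencies on the supplied (training) tokens, applies
#' the `max_df` cap (terms present in more than `max_df` of documents are
#' dropped; `max_df = 1` keeps terms that appear in every document), and
#' stores smoothed idf weights `log((1 + N) / (1 + df)) + 1`.
#'
#' @param tokens list of token vectors (training documents).
#' @param vocabulary candidate term list.
#' @param use_idf scale term counts by idf (default TRUE).
#' @param max_df maximum document-frequency fraction for a retained term.
#' @return object of class `tfidf_featurizer`.
#' @export
fit_tfidf <- function(tokens, vocabulary, use_idf = TRUE, max_df = 1) {
  stopifnot(length(vocabulary) > 0)
  n_docs <- length(tokens)
  df <- integer(length(vocabulary))
  names(df) <- vocabulary
  for (tk in tokens) {
    present <- unique(tk)
    present <- present[present %in% vocabulary]
    df[present] <- df[present] + 1L
  }
  keep <- df <= max_df * n_docs
  vocabulary <- vocabulary[keep]
  df <- df[keep]
  if (length(vocabulary) == 0L) {
    stop("max_df pruning removed every term", call. = FALSE)
  }
  idf <- log((1 + n_docs) / (1 + df)) + 1
  structure(list(vocabulary = vocabulary, idf = unname(idf),
                 use_idf = use_idf, max_df = max_df, n_docs = n_docs),
            class = "tfidf_featurizer")
}

#' Transform documents into tf-idf feature rows
#'
#' Builds a sparse row-per-document matrix of term counts over the
#' featurizer's vocabulary (out-of-vocabulary terms ignored), scales by the
#' stored idf when `use_idf`, and L1-normalizes each row (rows with no
#' in-vocabulary terms stay all-zero). Weights are nonnegative and zero
#' exactly where a term is absent from a document.
#'
#' @param featurizer a [fit_tfidf()] object.
#' @param tokens list of token vectors.
#' @return sparse `dgCMatrix` with one row per document, columns named by
#'   the vocabulary.
#' @export
tfidf_transform <- function(featurizer, tokens) {
  stopifnot(inherits(featurizer, "tfidf_featurizer"))
  vocab <- featurizer$vocabulary
  triplets <- lapply(seq_along(tokens), function(d) {
    idx <- match(tokens[[d]], vocab)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) return(NULL)
    cnt <- table(idx)
    cbind(d, as.integer(names(cnt)), as.numeric(cnt))
  })
  trip <- do.call(rbind, triplets)
  if (is.null(trip)) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(tokens), length(vocab)),
                                dimnames = list(NULL, vocab)))
  }
  x <- trip[, 3]
  if (featurizer$use_idf) x <- x * featurizer$idf[trip[, 2]]
  m <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = x,
                            dims = c(length(tokens), length(vocab)),
                            dimnames = list(NULL, vocab))
  rs <- Matrix::rowSums(m)
  rs[rs == 0] <- 1
  Matrix::Diagonal(x = 1 / rs) %*% m
}

#' One-step tf-idf featurization
#'
#' Convenience wrapper fitting a featurizer and transforming the same
#' documents; the featurizer is attached as the `"featurizer"` attribute.
#'
#' @inheritParams fit_tfidf
#' @return sparse feature matrix with attribute `featurizer`.
#' @export
featurize_tfidf <- function(tokens, vocabulary, use_idf = TRUE, max_df = 1) {
  fz <- fit_tfidf(tokens, vocabulary, use_idf = use_idf, max_df = max_df)
  m <- tfidf_transform(fz, tokens)
  attr(m, "featurizer") <- fz
  m
}
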