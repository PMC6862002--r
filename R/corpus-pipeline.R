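#' Clean raw page text
#'
#' Removes characters outside an allowed set (letters in any script, digits,
#' basic punctuation), collapses runs of whitespace — spaces, tabs, newlines
#' — to single spaces, and strips leading/trailing whitespace. Emoticons and
#' other symbol characters fall outside the allowed set and are removed.
#' Idempotent: `clean_text(clean_text(x)) == clean_text(x)`.
#'
#' @param raw character vector.
#' @param allowed_pattern perl regex character class matched against
#'   *disallowed* characters; matches are replaced by a space.
#' @return cleaned character vector.
#' @export
clean_text <- function(raw,
                       allowed_pattern = "[^\\p{L}\\p{N}.,;:!?'\"()/-]+") {
  stopifnot(is.character(raw))
  x <- gsub(allowed_pattern, " ", raw, perl = TRUE)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Heuristic language detector
#'
#' Classifies a text as `english`, `non-english` or `undetermined`. A text
#' with no letters (or empty) is `undetermined`; one whose letters are mostly
#' outside the basic Latin range is `non-english`; otherwise the verdict is
#' `english` when the fraction of tokens that are common English function
#' words reaches `min_coverage`. Any callable with the same
#' string -> verdict contract can replace it in [filter_language()].
#'
#' @param text a single character string.
#' @param stopwords reference list of English function words.
#' @param min_coverage minimum stop-word token fraction to call English.
#' @param min_latin minimum fraction of letter characters in a-z/A-Z.
#' @return one of `"english"`, `"non-english"`, `"undetermined"`.
#' @export
detect_language <- function(text, stopwords = english_stopwords(),
                            min_coverage = 0.1, min_latin = 0.5) {
  if (length(text) != 1L || is.na(text)) return("undetermined")
  chars <- strsplit(text, "")[[1]]
  letters_all <- grepl("\\p{L}", chars, perl = TRUE)
  if (!any(letters_all)) return("undetermined")
  latin <- grepl("[a-zA-Z]", chars[letters_all])
  if (mean(latin) < min_latin) return("non-english")
  toks <- tokenize(text)[[1]]
  if (length(toks) == 0L) return("undetermined")
  if (mean(toks %in% stopwords) >= min_coverage) "english" else "non-english"
}

#' Keep English-language documents
#'
#' Applies a language detector to each document and keeps those with verdict
#' `english`. A detector failure marks the document `undetermined` and it is
#' excluded (with a message). The verdict is recorded in a `language_flag`
#' column on the returned documents.
#'
#' @param docs document tibble (id, url, text).
#' @param detector function string -> `english`/`non-english`/`undetermined`.
#' @return filtered tibble with a `language_flag` column.
#' @export
filter_language <- function(docs, detector = detect_language) {
  assert_documents(docs)
  flags <- vapply(docs$text, function(tx) {
    tryCatch(detector(tx), error = function(e) "undetermined")
  }, character(1), USE.NAMES = FALSE)
  n_und <- sum(flags == "undetermined")
  if (n_und > 0) {
    message(n_und, " document(s) with undetermined language excluded")
  }
  docs$language_flag <- flags
  docs[flags == "english", , drop = FALSE]
}

#' Keep documents with at least a minimum number of words
#'
#' A page with fewer than `min_words` whitespace-delimited words is removed;
#' a page with exactly `min_words` is kept. Adds/refreshes a `word_count`
#' column.
#'
#' @param docs document tibble.
#' @param min_words minimum word count (default 300).
#' @return filtered tibble with `word_count`.
#' @export
filter_length <- function(docs, min_words = 300L) {
  assert_documents(docs)
  docs$word_count <- count_words(docs$text)
  docs[docs$word_count >= min_words, , drop = FALSE]
}

#' Remove near-duplicate documents
#'
#' Computes word `shingle_k`-shingle sets per document and groups documents
#' whose pairwise Jaccard similarity reaches `similarity_threshold`
#' (transitively). Within each group only the document with the greatest
#' word count is retained; ties go to the lexicographically smallest id.
#' Output order follows input order; the operation is idempotent.
#'
#' @param docs document tibble.
#' @param similarity_threshold Jaccard similarity at or above which two
#'   pages count as duplicates (default 0.8).
#' @param shingle_k shingle width in words (default 5).
#' @return filtered tibble.
#' @export
deduplicate <- function(docs, similarity_threshold = 0.8, shingle_k = 5L) {
  assert_documents(docs)
  n <- nrow(docs)
  if (n <= 1L) return(docs)
  assert_probability(similarity_threshold, "similarity_threshold")
  toks <- tokenize(docs$text)
  sh <- lapply(toks, function(tk) unique(shingles(tk, shingle_k)))

  # candidate pairs: documents sharing at least one shingle
  doc_of <- rep(seq_len(n), lengths(sh))
  by_shingle <- split(doc_of, unlist(sh))
  pairs <- unique(do.call(rbind, lapply(by_shingle, function(ds) {
    if (length(ds) < 2L) return(NULL)
    t(utils::combn(sort(ds), 2L))
  })))
  word_count <- count_words(docs$text)
  if (is.null(pairs) || nrow(pairs) == 0L) return(transform_wc(docs, word_count))

  sim <- vapply(seq_len(nrow(pairs)), function(r)
    jaccard(sh[[pairs[r, 1]]], sh[[pairs[r, 2]]]), numeric(1))
  dup <- pairs[sim >= similarity_threshold, , drop = FALSE]
  if (nrow(dup) == 0L) return(transform_wc(docs, word_count))

  # union-find over duplicate pairs
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(dup))) {
    ra <- find(dup[r, 1]); rb <- find(dup[r, 2])
    if (ra != rb) parent[rb] <- ra
  }
  root <- vapply(seq_len(n), find, integer(1))
  keep <- logical(n)
  for (g in split(seq_len(n), root)) {
    best <- g[order(-word_count[g], docs$id[g])][1]
    keep[best] <- TRUE
  }
  transform_wc(docs[keep, , drop = FALSE], word_count[keep])
}

transform_wc <- function(docs, wc) {
  docs$word_count <- wc
  docs
}

#' Run the corpus ingest pipeline
#'
#' Applies, in order: text cleaning, language filtering, removal of empty
#' pages (pages whose fetched text is empty model unavailable/broken links),
#' the minimum-length filter, and near-duplicate removal. Returns the
#' analysis corpus and a per-stage attrition report.
#'
#' @param raw tibble of raw page records (id, url, text).
#' @param min_words minimum word count (default 300).
#' @param dedup_threshold shingle-Jaccard duplicate threshold (default 0.8).
#' @param shingle_k shingle width (default 5).
#' @param detector language detector, see [filter_language()].
#' @return list with `corpus` (filtered tibble with word_count) and `report`
#'   (tibble stage/count, monotonically non-increasing).
#' @export
run_ingest <- function(raw, min_words = 300L, dedup_threshold = 0.8,
                       shingle_k = 5L, detector = detect_language) {
  assert_documents(raw)
  docs <- raw[, c("id", "url", "text")]
  docs$text <- clean_text(docs$text)
  n_raw <- nrow(docs)
  docs <- filter_language(docs, detector)
  n_lang <- nrow(docs)
  docs <- docs[nzchar(docs$text), , drop = FALSE]
  n_avail <- nrow(docs)
  docs <- filter_length(docs, min_words)
  n_len <- nrow(docs)
  docs <- deduplicate(docs, dedup_threshold, shingle_k)
  n_dedup <- nrow(docs)
  report <- tibble::tibble(
    stage = c("raw", "after_language", "after_availability",
              "after_length", "after_dedup"),
    count = c(n_raw, n_lang, n_avail, n_len, n_dedup)
  )
  list(corpus = docs, report = report)
}
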