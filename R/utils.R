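# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tokenize cleaned text for analysis
#'
#' Lowercases, splits on whitespace, strips characters other than ASCII
#' letters, digits and apostrophes from each token, and drops empty tokens.
#' This is the single tokenizer used for word counts, feature construction
#' and term-presence tests, so the three stay consistent.
#'
#' @param text character vector of document texts.
#' @return list of character vectors, one per document.
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text))
  toks <- strsplit(tolower(text), "\\s+")
  lapply(toks, function(tk) {
    tk <- gsub("[^a-z0-9']+", "", tk)
    tk[nzchar(tk)]
  })
}

# word count on cleaned text: whitespace-delimited tokens
count_words <- function(text) {
  vapply(strsplit(trimws(text), "\\s+"),
         function(tk) sum(nzchar(tk)), integer(1))
}

# contiguous word k-shingles of a token vector, as strings
shingles <- function(tokens, k = 5L) {
  n <- length(tokens)
  if (n < k) {
    if (n == 0L) return(character(0))
    return(paste(tokens, collapse = " "))
  }
  vapply(seq_len(n - k + 1L), function(i)
    paste(tokens[i:(i + k - 1L)], collapse = " "), character(1))
}

jaccard <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

assert_probability <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# validate a tibble of documents with id/url/text columns
assert_documents <- function(docs) {
  if (!is.data.frame(docs) ||
      !all(c("id", "url", "text") %in% names(docs))) {
    stop("documents must be a data frame with columns id, url, text",
         call. = FALSE)
  }
  if (anyDuplicated(docs$id)) {
    stop("document ids must be unique", call. = FALSE)
  }
  invisible(docs)
}

new_tibble0 <- function(...) tibble::tibble(...)
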