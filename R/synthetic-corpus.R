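#' Specification for a synthetic labeled page corpus
#'
#' Describes a corpus of Web-page texts whose vocabulary usage depends on
#' latent credibility-criterion labels. Each page receives 7 independent
#' Bernoulli criterion labels with the given prevalences; its text is a bag
#' of words mixing (i) a function-word layer of common English words, (ii) a
#' Zipf-weighted background vocabulary shared by all pages, and (iii)
#' criterion-conditional signal terms: for each signal token a criterion is
#' picked at random and a term drawn from that criterion's "satisfied" set
#' with probability `signal_contrast` if the label is 1 (from the
#' "unsatisfied" set otherwise), mirrored when the label is 0. At
#' `signal_contrast = 0.5` the text carries no label information; near 1 the
#' criteria are recoverable from text alone.
#'
#' Default prevalences `(0.5, 0.35, 0.15, 0.55, 0.45, 0.6, 0.1)` reproduce a
#' labeled sample with substantial imbalance, including two rare criteria
#' (3 and 7).
#'
#' @param n_pages number of pages.
#' @param criterion_prevalences 7 probabilities, one per checklist criterion.
#' @param signal_vocab list of 7 elements, each `list(sat =, uns =)` character
#'   vectors; pairwise disjoint and disjoint from the background vocabulary.
#'   `NULL` builds a default with `terms_per_set` terms per set.
#' @param background_vocab_size size of the shared background vocabulary.
#' @param words_per_page integer range `c(min, max)` of page lengths.
#' @param signal_fraction fraction of tokens drawn from signal vocabularies.
#' @param function_word_fraction fraction of tokens drawn from common English
#'   function words (gives language heuristics realistic coverage).
#' @param signal_contrast probability in `[0.5, 1]` that a signal token comes
#'   from the label-consistent term set.
#' @param terms_per_set terms per satisfied/unsatisfied set in the default
#'   signal vocabulary.
#' @param seed integer seed; the generator is deterministic given the spec.
#' @return object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_pages = 2000,
                        criterion_prevalences = c(0.5, 0.35, 0.15, 0.55,
                                                  0.45, 0.6, 0.1),
                        signal_vocab = NULL,
                        background_vocab_size = 200,
                        words_per_page = c(300L, 600L),
                        signal_fraction = 0.3,
                        function_word_fraction = 0.35,
                        signal_contrast = 0.95,
                        terms_per_set = 5L,
                        seed = 1L) {
  n_pages <- assert_count(n_pages, "n_pages")
  if (length(criterion_prevalences) != 7L) {
    stop("`criterion_prevalences` must have length 7", call. = FALSE)
  }
  assert_probability(criterion_prevalences, "criterion_prevalences")
  background_vocab_size <- assert_count(background_vocab_size,
                                        "background_vocab_size", min = 1L)
  if (length(words_per_page) != 2L || any(words_per_page < 1) ||
      words_per_page[1] > words_per_page[2]) {
    stop("`words_per_page` must be c(min, max) with min >= 1", call. = FALSE)
  }
  assert_probability(signal_fraction, "signal_fraction")
  assert_probability(function_word_fraction, "function_word_fraction")
  if (signal_fraction + function_word_fraction > 1) {
    stop("signal_fraction + function_word_fraction must be <= 1",
         call. = FALSE)
  }
  if (signal_contrast < 0.5 || signal_contrast > 1) {
    stop("`signal_contrast` must lie in [0.5, 1]", call. = FALSE)
  }
  if (is.null(signal_vocab)) {
    signal_vocab <- lapply(1:7, function(i) list(
      sat = sprintf("sig%dsat%02d", i, seq_len(terms_per_set)),
      uns = sprintf("sig%duns%02d", i, seq_len(terms_per_set))
    ))
  }
  if (length(signal_vocab) != 7L ||
      !all(vapply(signal_vocab, function(s)
        is.list(s) && all(c("sat", "uns") %in% names(s)) &&
          length(s$sat) > 0 && length(s$uns) > 0, logical(1)))) {
    stop("`signal_vocab` must be 7 lists with non-empty $sat and $uns sets",
         call. = FALSE)
  }
  background <- sprintf("bg%04d", seq_len(background_vocab_size))
  all_signal <- unlist(lapply(signal_vocab, unlist), use.names = FALSE)
  if (anyDuplicated(all_signal) ||
      length(intersect(all_signal, background)) > 0) {
    stop("signal vocabularies must be pairwise disjoint and disjoint from ",
         "the background vocabulary", call. = FALSE)
  }
  structure(list(
    n_pages = n_pages,
    criterion_prevalences = criterion_prevalences,
    signal_vocab = signal_vocab,
    background_vocab = background,
    words_per_page = as.integer(words_per_page),
    signal_fraction = signal_fraction,
    function_word_fraction = function_word_fraction,
    signal_contrast = signal_contrast,
    seed = as.integer(seed)
  ), class = "corpus_spec")
}

#' @export
print.corpus_spec <- function(x, ...) {
  cat("<corpus_spec>", x$n_pages, "pages,",
      length(x$background_vocab), "background terms,",
      "signal contrast", x$signal_contrast, "\n")
  cat("  prevalences:", paste(x$criterion_prevalences, collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic labeled page corpus
#'
#' Draws criterion labels and page texts according to a [corpus_spec()].
#' Deterministic given the spec (including its seed).
#'
#' @param spec a [corpus_spec()].
#' @return list with `documents` (tibble: id, url, text) and `labels`
#'   (tibble: id, c1..c7).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$seed)
  n <- spec$n_pages
  ids <- sprintf("page%05d", seq_len(n))
  labels <- matrix(
    rbinom(n * 7L, 1L, rep(spec$criterion_prevalences, each = n)),
    nrow = n, ncol = 7L
  )
  colnames(labels) <- paste0("c", 1:7)

  fw <- function_word_layer()
  bg <- spec$background_vocab
  bg_weights <- 1 / seq_along(bg)   # Zipf-like document-frequency spread
  contrast <- spec$signal_contrast

  texts <- character(n)
  for (d in seq_len(n)) {
    len <- sample(spec$words_per_page[1]:spec$words_per_page[2], 1L)
    n_fw <- round(spec$function_word_fraction * len)
    n_sig <- round(spec$signal_fraction * len)
    n_bg <- len - n_fw - n_sig
    toks_fw <- sample(fw, n_fw, replace = TRUE)
    toks_bg <- sample(bg, n_bg, replace = TRUE, prob = bg_weights)
    crit <- sample.int(7L, n_sig, replace = TRUE)
    consistent <- runif(n_sig) < contrast
    toks_sig <- vapply(seq_len(n_sig), function(j) {
      i <- crit[j]
      sat <- labels[d, i] == 1L
      use_sat <- if (consistent[j]) sat else !sat
      set <- if (use_sat) spec$signal_vocab[[i]]$sat
             else spec$signal_vocab[[i]]$uns
      set[sample.int(length(set), 1L)]
    }, character(1))
    texts[d] <- paste(sample(c(toks_fw, toks_bg, toks_sig)), collapse = " ")
  }

  list(
    documents = tibble::tibble(
      id = ids,
      url = paste0("https://example.org/", ids),
      text = texts
    ),
    labels = tibble::as_tibble(cbind(
      tibble::tibble(id = ids), as.data.frame(labels)
    ))
  )
}

#' Inject filtering noise into a document set
#'
#' Appends near-duplicates (copies with a small fraction of word positions
#' resampled from the source page's own words), under-length pages, and
#' non-English-like pages to a corpus, so corpus-ingest filters can be
#' exercised with known bookkeeping. Original rows are returned unchanged, in
#' their original order, followed by the injected rows; the `noise` column
#' records each row's type (`original`, `duplicate`, `short`, `nonenglish`).
#'
#' The number injected of each type is `round(rate * nrow(documents))`.
#' Near-duplicate ids append `-dupNN` to the source id, so the source sorts
#' lexicographically first and is the page retained on word-count ties during
#' deduplication.
#'
#' @param documents tibble with id, url, text.
#' @param dup_rate,short_rate,nonenglish_rate injection rates in `[0, 1]`.
#' @param seed integer seed.
#' @param resample_frac fraction of word positions resampled in a duplicate;
#'   the default keeps expected 5-shingle Jaccard with the source near 0.9.
#' @param short_words range of lengths for injected short pages (below any
#'   standard 300-word cutoff).
#' @return tibble with id, url, text, noise.
#' @export
inject_filter_noise <- function(documents, dup_rate = 0, short_rate = 0,
                                nonenglish_rate = 0, seed = 1L,
                                resample_frac = 0.01,
                                short_words = c(40L, 250L)) {
  assert_documents(documents)
  assert_probability(dup_rate, "dup_rate")
  assert_probability(short_rate, "short_rate")
  assert_probability(nonenglish_rate, "nonenglish_rate")
  set.seed(seed)
  n <- nrow(documents)
  out <- tibble::tibble(id = documents$id, url = documents$url,
                        text = documents$text,
                        noise = rep("original", n))
  k_dup <- round(dup_rate * n)
  k_short <- round(short_rate * n)
  k_non <- round(nonenglish_rate * n)

  if (k_dup > 0) {
    src <- sample.int(n, k_dup, replace = k_dup > n)
    dups <- lapply(seq_len(k_dup), function(j) {
      toks <- strsplit(documents$text[src[j]], " ", fixed = TRUE)[[1]]
      m <- max(1L, round(resample_frac * length(toks)))
      pos <- sample.int(length(toks), m)
      toks[pos] <- sample(toks, m, replace = TRUE)
      tibble::tibble(
        id = sprintf("%s-dup%02d", documents$id[src[j]], j),
        url = sprintf("%s?dup=%d", documents$url[src[j]], j),
        text = paste(toks, collapse = " "),
        noise = "duplicate"
      )
    })
    out <- rbind(out, do.call(rbind, dups))
  }
  if (k_short > 0) {
    fw <- function_word_layer()
    shorts <- lapply(seq_len(k_short), function(j) {
      len <- sample(short_words[1]:short_words[2], 1L)
      tibble::tibble(
        id = sprintf("short%04d", j),
        url = sprintf("https://example.org/short%04d", j),
        text = paste(sample(fw, len, replace = TRUE), collapse = " "),
        noise = "short"
      )
    })
    out <- rbind(out, do.call(rbind, shorts))
  }
  if (k_non > 0) {
    cyr <- vapply(1:40, function(i)
      paste(sample(strsplit("абвгдежзиклмнопр", "")[[1]],
                   sample(3:8, 1L), replace = TRUE), collapse = ""),
      character(1))
    nons <- lapply(seq_len(k_non), function(j) {
      tibble::tibble(
        id = sprintf("nonen%04d", j),
        url = sprintf("https://example.org/nonen%04d", j),
        text = paste(sample(cyr, 400, replace = TRUE), collapse = " "),
        noise = "nonenglish"
      )
    })
    out <- rbind(out, do.call(rbind, nons))
  }
  out
}
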