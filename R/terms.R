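#' Term presence 2x2 contingency table
#'
#' Counts document-level presence (a term occurring several times in one
#' page still counts once): `a` low-band pages containing the term, `b`
#' low-band pages lacking it, `c` other pages containing it, `d` other
#' pages lacking it.
#'
#' @param term a single term.
#' @param low_tokens,other_tokens lists of token vectors for low-band and
#'   other pages; both non-empty.
#' @return named integer vector `c(a, b, c, d)`.
#' @export
term_presence_table <- function(term, low_tokens, other_tokens) {
  if (length(low_tokens) == 0L || length(other_tokens) == 0L) {
    stop("both page sets must be non-empty", call. = FALSE)
  }
  a <- sum(vapply(low_tokens, function(tk) term %in% tk, logical(1)))
  cc <- sum(vapply(other_tokens, function(tk) term %in% tk, logical(1)))
  c(a = a, b = length(low_tokens) - a,
    c = cc, d = length(other_tokens) - cc)
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Conditions on both margins and enumerates the hypergeometric distribution
#' of the `a` cell; the two-sided p-value is the total probability of all
#' admissible tables whose probability does not exceed that of the observed
#' table (probability-mass rule). Degenerate margins (an empty row or
#' column) give p = 1.
#'
#' @param a,b,c,d nonnegative cell counts (row 1 = low-band pages, column 1
#'   = term present); alternatively `a` may be a 2x2 matrix.
#' @return p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) ||
      any(cells != as.integer(cells))) {
    stop("cells must be nonnegative integers", call. = FALSE)
  }
  r1 <- a + b; m1 <- a + c; m2 <- b + d
  if (r1 == 0 || c + d == 0 || m1 == 0 || m2 == 0) return(1)
  support <- max(0, r1 - m2):min(r1, m1)
  probs <- stats::dhyper(support, m1, m2, r1)
  p_obs <- stats::dhyper(a, m1, m2, r1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Odds ratio of a 2x2 presence table
#'
#' `(a * d) / (b * c)`, with `Inf` when `b * c = 0` but `a * d > 0`. When
#' both cross products are zero the ratio is undefined; `NA` is returned
#' with a warning.
#'
#' @inheritParams fisher_exact_two_sided
#' @return extended nonnegative real (possibly `Inf`) or `NA`.
#' @export
odds_ratio <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  ad <- a * d; bc <- b * c
  if (ad == 0 && bc == 0) {
    warning("odds ratio undefined: both cross products are zero")
    return(NA_real_)
  }
  if (bc == 0) return(Inf)
  ad / bc
}

#' Rank terms by association with low-credibility pages
#'
#' For every vocabulary term, builds the presence table against the
#' low-band/other split, computes the two-sided Fisher exact p-value and
#' odds ratio, and ranks by p ascending, breaking ties by |log OR|
#' descending. Direction is `over` (over-represented in low-band pages)
#' when OR > 1, `under` when OR < 1, `none` otherwise. Benjamini-Hochberg
#' adjustment is available but off by default.
#'
#' @param tokens list of token vectors, one per page.
#' @param bands character vector of bands aligned to `tokens`; at least one
#'   `low` and one non-low page required.
#' @param vocabulary terms to test; `NULL` uses all distinct tokens.
#' @param alpha significance level for the `significant` flag.
#' @param correction `"none"` or `"BH"`.
#' @return tibble: term, a, b, c, d, odds_ratio, p, p_adjusted, direction,
#'   significant; one row per vocabulary term, ranked.
#' @export
rank_informative_terms <- function(tokens, bands, vocabulary = NULL,
                                   alpha = 0.05,
                                   correction = c("none", "BH")) {
  correction <- match.arg(correction)
  stopifnot(length(tokens) == length(bands))
  low <- bands == "low"
  if (!any(low) || all(low)) {
    stop("need at least one low-band and one other page", call. = FALSE)
  }
  vocabulary <- vocabulary %||% sort(unique(unlist(tokens)))
  if (length(vocabulary) == 0L) {
    stop("empty vocabulary", call. = FALSE)
  }
  present <- lapply(tokens, unique)
  n_low <- sum(low); n_other <- sum(!low)
  a_vec <- integer(length(vocabulary)); c_vec <- integer(length(vocabulary))
  tab_low <- table(factor(unlist(present[low]), levels = vocabulary))
  tab_oth <- table(factor(unlist(present[!low]), levels = vocabulary))
  a_vec <- as.integer(tab_low); c_vec <- as.integer(tab_oth)
  b_vec <- n_low - a_vec; d_vec <- n_other - c_vec

  p <- vapply(seq_along(vocabulary), function(i)
    fisher_exact_two_sided(a_vec[i], b_vec[i], c_vec[i], d_vec[i]),
    numeric(1))
  or <- vapply(seq_along(vocabulary), function(i) {
    suppressWarnings(odds_ratio(a_vec[i], b_vec[i], c_vec[i], d_vec[i]))
  }, numeric(1))
  direction <- ifelse(is.na(or) | or == 1, "none",
                      ifelse(or > 1, "over", "under"))
  p_adjusted <- if (correction == "BH") stats::p.adjust(p, "BH") else p
  log_or_mag <- abs(log(or))
  log_or_mag[is.na(log_or_mag)] <- 0

  out <- tibble::tibble(
    term = vocabulary, a = a_vec, b = b_vec, c = c_vec, d = d_vec,
    odds_ratio = or, p = p, p_adjusted = p_adjusted,
    direction = direction, significant = p_adjusted < alpha
  )
  out[order(out$p, -log_or_mag, out$term), ]
}
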