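#' Credibility band for a 0-7 score
#'
#' Scores 0-2 are `low`, 3-4 `medium`, 5-7 `high`. The three bands
#' partition 0..7 and the mapping is monotone in the score.
#'
#' @param score integer vector with values in 0..7.
#' @return character vector of `"low"`, `"medium"`, `"high"`.
#' @export
credibility_band <- function(score) {
  if (!is.numeric(score) || any(is.na(score)) || any(score < 0) ||
      any(score > 7) || any(score != as.integer(score))) {
    stop("`score` must be integers in 0..7", call. = FALSE)
  }
  c("low", "low", "low", "medium", "medium", "high", "high", "high")[
    as.integer(score) + 1L]
}

#' Credibility score of one criterion vector
#'
#' The score is the number of satisfied criteria (sum of the 7 binary
#' judgments); the band follows [credibility_band()]. The score depends only
#' on the count, not on which criteria are satisfied.
#'
#' @param v numeric/integer vector of 7 values in \{0, 1\}.
#' @return list with `score` (integer 0-7) and `band`.
#' @export
credibility_score <- function(v) {
  v <- unlist(v, use.names = FALSE)
  if (length(v) != 7L || any(is.na(v)) || !all(v %in% c(0, 1))) {
    stop("criterion vector must have exactly 7 entries in {0, 1}",
         call. = FALSE)
  }
  s <- as.integer(sum(v))
  list(score = s, band = credibility_band(s))
}

#' Score a table of criterion vectors
#'
#' Vectorized scoring: appends `score` and `band` columns to a tibble with
#' c1..c7 columns (manual labels or ensemble predictions).
#'
#' @param labels data frame with columns c1..c7 (and typically id).
#' @return input tibble with `score` and `band` appended.
#' @export
credibility_scores <- function(labels) {
  cols <- paste0("c", 1:7)
  if (!all(cols %in% names(labels))) {
    stop("`labels` must contain columns c1..c7", call. = FALSE)
  }
  m <- as.matrix(labels[, cols])
  if (any(is.na(m)) || !all(m %in% c(0, 1))) {
    stop("criterion columns must be binary with no missing values",
         call. = FALSE)
  }
  out <- tibble::as_tibble(labels)
  out$score <- as.integer(rowSums(m))
  out$band <- credibility_band(out$score)
  out
}

# Fleiss kappa from an item x category count matrix
fleiss_kappa_counts <- function(counts) {
  n_raters <- unique(rowSums(counts))
  stopifnot(length(n_raters) == 1L, n_raters >= 2)
  big_n <- nrow(counts)
  p_j <- colSums(counts) / (big_n * n_raters)
  p_e <- sum(p_j^2)
  p_i <- (rowSums(counts^2) - n_raters) / (n_raters * (n_raters - 1))
  p_bar <- mean(p_i)
  if (abs(1 - p_e) < .Machine$double.eps^0.5) return(NA_real_)
  (p_bar - p_e) / (1 - p_e)
}

#' Fleiss' kappa with a bootstrap confidence interval
#'
#' Chance-corrected agreement for `n >= 2` raters assigning categorical
#' ratings to items: mean observed pairwise item agreement compared with the
#' chance agreement implied by the category marginals. The confidence
#' interval is a percentile bootstrap over items (replicates in which a
#' single category exhausts the resample, making chance agreement 1, are
#' dropped).
#'
#' @param ratings items x raters matrix (or data frame) of categorical
#'   ratings; every cell filled.
#' @param ci_level confidence level (default 0.95).
#' @param n_boot bootstrap replicates over items (default 1000).
#' @param seed bootstrap seed.
#' @return list with `kappa`, `ci` (length 2), `ci_level`, `n_items`,
#'   `n_raters`, `n_boot`.
#' @export
fleiss_kappa <- function(ratings, ci_level = 0.95, n_boot = 1000L,
                         seed = 1L) {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 2L || ncol(ratings) < 2L || anyNA(ratings)) {
    stop("`ratings` needs >= 2 items, >= 2 raters and no missing cells",
         call. = FALSE)
  }
  categories <- sort(unique(as.vector(ratings)))
  counts <- t(apply(ratings, 1L, function(r)
    tabulate(match(r, categories), nbins = length(categories))))
  if (length(categories) == 1L) {
    stop("degenerate agreement: all ratings fall in a single category, ",
         "chance agreement is 1 and kappa is undefined", call. = FALSE)
  }
  kappa <- fleiss_kappa_counts(counts)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(nrow(counts), replace = TRUE)
    fleiss_kappa_counts(counts[idx, , drop = FALSE])
  }, numeric(1))
  alpha <- (1 - ci_level) / 2
  ci <- unname(quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
  list(kappa = kappa, ci = ci, ci_level = ci_level,
       n_items = nrow(counts), n_raters = ncol(ratings), n_boot = n_boot)
}

#' Per-user credibility profiles
#'
#' For every user in a tweet log, collects the credibility scores of the
#' pages the user shared. By default each distinct page contributes one
#' entry no matter how many times the user tweeted it; set
#' `distinct_pages = FALSE` to count one entry per tweet.
#'
#' @param tweets tibble with `user_id` and `url`.
#' @param page_scores tibble with `url`, `score` and `band` (e.g. from
#'   [credibility_scores()] joined to page urls). Tweets whose url is not
#'   scored are ignored.
#' @param distinct_pages count each page once per user (default TRUE).
#' @return tibble: user_id, n_pages, scores (list of integer vectors),
#'   bands (list of character vectors). Users with no scored pages are
#'   absent.
#' @export
user_credibility_profiles <- function(tweets, page_scores,
                                      distinct_pages = TRUE) {
  stopifnot(all(c("user_id", "url") %in% names(tweets)),
            all(c("url", "score", "band") %in% names(page_scores)))
  m <- match(tweets$url, page_scores$url)
  keep <- !is.na(m)
  df <- data.frame(user_id = tweets$user_id[keep],
                   url = tweets$url[keep],
                   score = page_scores$score[m[keep]],
                   band = page_scores$band[m[keep]],
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    return(tibble::tibble(user_id = character(0), n_pages = integer(0),
                          scores = list(), bands = list()))
  }
  parts <- lapply(split(df, df$user_id), function(d) {
    if (distinct_pages) d <- d[!duplicated(d$url), , drop = FALSE]
    tibble::tibble(user_id = d$user_id[1], n_pages = nrow(d),
                   scores = list(as.integer(d$score)),
                   bands = list(d$band))
  })
  out <- do.call(rbind, parts)
  out[order(out$user_id), ]
}
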