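#' Percentage share, paper-style
#'
#' `round(100 * part / total, 2)` — the rounding rule used for every
#' reported share.
#'
#' @param part,total numerators and denominator.
#' @return percentage rounded to 2 decimals.
#' @export
percentage_share <- function(part, total) {
  round(100 * part / total, 2)
}

#' Per-page share counts
#'
#' Counts, for each page url, the total number of tweets and retweets
#' linking it (retweets count equally with original tweets).
#'
#' @param tweets tibble with `url` and `is_retweet`.
#' @return tibble: url, shares, retweets.
#' @export
page_share_counts <- function(tweets) {
  stopifnot("url" %in% names(tweets))
  if (nrow(tweets) == 0L) {
    return(tibble::tibble(url = character(0), shares = integer(0),
                          retweets = integer(0)))
  }
  rt <- if ("is_retweet" %in% names(tweets)) as.logical(tweets$is_retweet)
        else rep(FALSE, nrow(tweets))
  shares <- table(tweets$url)
  retw <- table(factor(tweets$url[rt], levels = names(shares)))
  tibble::tibble(url = names(shares),
                 shares = as.integer(shares),
                 retweets = as.integer(retw))
}

#' Potential exposure per page
#'
#' Sums the posting user's follower count over every tweet and retweet
#' linking each page — the maximum possible audience; overlapping audiences
#' are deliberately not deduplicated. A page never tweeted has exposure 0
#' only if it is supplied via `pages`.
#'
#' @param tweets tibble with `url` and `follower_count` (the author's count
#'   recorded on each tweet, including retweets).
#' @param pages optional character vector of page urls to report (pages
#'   absent from the log get exposure 0).
#' @return tibble: url, exposure.
#' @export
potential_exposure <- function(tweets, pages = NULL) {
  stopifnot(all(c("url", "follower_count") %in% names(tweets)))
  if (any(tweets$follower_count < 0, na.rm = TRUE) ||
      anyNA(tweets$follower_count)) {
    stop("follower counts must be nonnegative and non-missing",
         call. = FALSE)
  }
  if (nrow(tweets) == 0L) {
    out <- tibble::tibble(url = character(0), exposure = numeric(0))
  } else {
    agg <- tapply(as.numeric(tweets$follower_count), tweets$url, sum)
    out <- tibble::tibble(url = names(agg), exposure = as.numeric(agg))
  }
  if (!is.null(pages)) {
    missing <- setdiff(pages, out$url)
    out <- rbind(out, tibble::tibble(url = missing,
                                     exposure = rep(0, length(missing))))
    out <- out[match(pages, out$url), , drop = FALSE]
  }
  out
}

#' Band-level exposure summary
#'
#' Aggregates pages, shares, retweets and potential exposures by
#' credibility band, with percentage shares of the grand totals rounded to
#' 2 decimals. Tweets whose url does not resolve against the scored pages
#' are excluded from the band summary and reported via the `unresolved`
#' element (and a message).
#'
#' @param page_scores tibble with `url` and `band` for every scored page.
#' @param tweets tweet log tibble (`url`, `is_retweet`, `follower_count`).
#' @return list with `per_band` (tibble: band, n_pages, shares, retweets,
#'   exposure and their pct_* shares), `per_page` (url, band, shares,
#'   retweets, exposure) and `unresolved` (count of excluded tweets).
#' @export
exposure_by_band <- function(page_scores, tweets) {
  stopifnot(all(c("url", "band") %in% names(page_scores)))
  resolved <- tweets$url %in% page_scores$url
  n_unres <- sum(!resolved)
  if (n_unres > 0) {
    message(n_unres, " tweet(s) with unresolved page urls excluded ",
            "from band summary")
  }
  tw <- tweets[resolved, , drop = FALSE]
  counts <- page_share_counts(tw)
  expo <- potential_exposure(
    if (nrow(tw)) tw else tibble::tibble(url = character(0),
                                         follower_count = numeric(0)),
    pages = page_scores$url)
  per_page <- tibble::tibble(
    url = page_scores$url,
    band = page_scores$band,
    shares = counts$shares[match(page_scores$url, counts$url)],
    retweets = counts$retweets[match(page_scores$url, counts$url)],
    exposure = expo$exposure
  )
  per_page$shares[is.na(per_page$shares)] <- 0L
  per_page$retweets[is.na(per_page$retweets)] <- 0L

  bands <- c("low", "medium", "high")
  per_band <- do.call(rbind, lapply(bands, function(b) {
    sel <- per_page$band == b
    tibble::tibble(band = b, n_pages = sum(sel),
                   shares = sum(per_page$shares[sel]),
                   retweets = sum(per_page$retweets[sel]),
                   exposure = sum(per_page$exposure[sel]))
  }))
  for (col in c("n_pages", "shares", "retweets", "exposure")) {
    per_band[[paste0("pct_", col)]] <-
      percentage_share(per_band[[col]], sum(per_band[[col]]))
  }
  list(per_band = per_band, per_page = per_page, unresolved = n_unres)
}

#' Per-band exposure survival curves
#'
#' For each band, sorts page exposures and attaches the empirical survival
#' fraction (share of the band's pages with exposure at least that large),
#' the form used for heavy-tail plots on log-log axes. Requested bands with
#' no pages are omitted with a warning.
#'
#' @param exposures numeric vector of per-page exposures.
#' @param bands band per page, aligned to `exposures`.
#' @param which_bands bands to include (default the three standard bands).
#' @return tibble: band, exposure, survival (non-increasing in exposure
#'   within band).
#' @export
exposure_distribution <- function(exposures, bands,
                                  which_bands = c("low", "medium", "high")) {
  stopifnot(length(exposures) == length(bands))
  parts <- list()
  for (b in which_bands) {
    v <- sort(exposures[bands == b])
    if (length(v) == 0L) {
      warning("band '", b, "' has no pages; omitted")
      next
    }
    n <- length(v)
    parts[[b]] <- tibble::tibble(band = b, exposure = v,
                                 survival = (n - seq_len(n) + 1) / n)
  }
  do.call(rbind, parts) %||%
    tibble::tibble(band = character(0), exposure = numeric(0),
                   survival = numeric(0))
}
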