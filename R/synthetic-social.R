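#' Specification for a synthetic sharing log and follower graph
#'
#' Describes a population of users split into communities, a heavy-tailed
#' follower-count distribution (discrete power law capped at `n_users`),
#' a stochastic-block follower graph (directed follower -> followed edges,
#' denser within than between communities), and a tweet log in which each
#' community preferentially shares pages from particular credibility bands.
#'
#' @param n_users number of users.
#' @param n_communities number of planted communities.
#' @param follower_exponent exponent of the discrete power law for follower
#'   counts (default 2.1), supported on `1..n_users`.
#' @param within_community_follow_prob,between_community_follow_prob directed
#'   edge probabilities; homophily requires within >= between.
#' @param community_band_bias matrix `n_communities x 3` (columns low,
#'   medium, high), each row a distribution over the band of pages the
#'   community's users share. `NULL` alternates a low-leaning and a
#'   high-leaning row.
#' @param tweets_per_user integer range `c(min, max)` of tweets per user.
#' @param retweet_prob probability a posting slot becomes a retweet of an
#'   earlier original tweet.
#' @param seed integer seed.
#' @return object of class `social_spec`.
#' @export
social_spec <- function(n_users = 400,
                        n_communities = 2,
                        follower_exponent = 2.1,
                        within_community_follow_prob = 0.05,
                        between_community_follow_prob = 0.005,
                        community_band_bias = NULL,
                        tweets_per_user = c(1L, 4L),
                        retweet_prob = 0.3,
                        seed = 1L) {
  n_users <- assert_count(n_users, "n_users", min = 1L)
  n_communities <- assert_count(n_communities, "n_communities", min = 1L)
  assert_probability(within_community_follow_prob,
                     "within_community_follow_prob")
  assert_probability(between_community_follow_prob,
                     "between_community_follow_prob")
  if (within_community_follow_prob < between_community_follow_prob) {
    stop("homophily requires within_community_follow_prob >= ",
         "between_community_follow_prob", call. = FALSE)
  }
  assert_probability(retweet_prob, "retweet_prob")
  if (length(tweets_per_user) != 2L || any(tweets_per_user < 0) ||
      tweets_per_user[1] > tweets_per_user[2]) {
    stop("`tweets_per_user` must be c(min, max) with min >= 0", call. = FALSE)
  }
  if (is.null(community_band_bias)) {
    low_row <- c(0.80, 0.15, 0.05)
    high_row <- c(0.05, 0.25, 0.70)
    community_band_bias <- t(vapply(seq_len(n_communities), function(i)
      if (i %% 2L == 1L) low_row else high_row, numeric(3)))
  }
  community_band_bias <- as.matrix(community_band_bias)
  if (nrow(community_band_bias) != n_communities ||
      ncol(community_band_bias) != 3L ||
      any(community_band_bias < 0) ||
      any(abs(rowSums(community_band_bias) - 1) > 1e-8)) {
    stop("`community_band_bias` must be n_communities x 3 with rows ",
         "summing to 1", call. = FALSE)
  }
  colnames(community_band_bias) <- c("low", "medium", "high")
  structure(list(
    n_users = n_users,
    n_communities = n_communities,
    follower_exponent = follower_exponent,
    within_community_follow_prob = within_community_follow_prob,
    between_community_follow_prob = between_community_follow_prob,
    community_band_bias = community_band_bias,
    tweets_per_user = as.integer(tweets_per_user),
    retweet_prob = retweet_prob,
    seed = as.integer(seed)
  ), class = "social_spec")
}

#' @export
print.social_spec <- function(x, ...) {
  cat("<social_spec>", x$n_users, "users in", x$n_communities,
      "communities; follow probs", x$within_community_follow_prob, "/",
      x$between_community_follow_prob, "\n")
  invisible(x)
}

# discrete power law on 1..cap
rpowerlaw <- function(n, exponent, cap) {
  support <- seq_len(cap)
  sample(support, n, replace = TRUE, prob = support^(-exponent))
}

# sample m distinct ordered pairs (follower in A, followed in B), no loops
sample_directed_pairs <- function(a_ids, b_ids, p, same = FALSE) {
  na <- length(a_ids); nb <- length(b_ids)
  total <- if (same) na * (nb - 1L) else na * nb
  if (total <= 0L || p <= 0) {
    return(tibble::tibble(follower_id = character(0),
                          followed_id = character(0)))
  }
  m <- rbinom(1L, total, p)
  if (m == 0L) {
    return(tibble::tibble(follower_id = character(0),
                          followed_id = character(0)))
  }
  idx <- sample.int(total, m)
  if (same) {
    row <- (idx - 1L) %/% (nb - 1L) + 1L
    colpos <- (idx - 1L) %% (nb - 1L) + 1L
    col <- colpos + (colpos >= row)
  } else {
    row <- (idx - 1L) %/% nb + 1L
    col <- (idx - 1L) %% nb + 1L
  }
  tibble::tibble(follower_id = a_ids[row], followed_id = b_ids[col])
}

#' Generate a synthetic tweet log and follower edge list
#'
#' Assigns users to communities, samples follower counts from a capped
#' discrete power law, samples the directed follower graph blockwise from
#' the within/between probabilities, and generates a tweet log: each posting
#' slot is, with probability `retweet_prob`, a retweet of a uniformly chosen
#' earlier original tweet (carrying the retweeter's own follower count) and
#' otherwise an original tweet of a page drawn via the author community's
#' band bias. Deterministic given the spec.
#'
#' @param spec a [social_spec()].
#' @param page_bands tibble with columns `url` and `band`
#'   (low/medium/high); every band given positive bias by some community must
#'   contain at least one page.
#' @return list with `tweets` (tibble: tweet_id, user_id, url, is_retweet,
#'   follower_count, timestamp), `edges` (tibble: follower_id, followed_id)
#'   and `users` (tibble: user_id, community, follower_count).
#' @export
generate_social <- function(spec, page_bands) {
  stopifnot(inherits(spec, "social_spec"))
  if (!is.data.frame(page_bands) ||
      !all(c("url", "band") %in% names(page_bands))) {
    stop("`page_bands` must have columns url and band", call. = FALSE)
  }
  bands <- c("low", "medium", "high")
  pages_by_band <- lapply(setNames(bands, bands),
                          function(b) page_bands$url[page_bands$band == b])
  needed <- bands[colSums(spec$community_band_bias > 0) > 0]
  empty <- needed[vapply(pages_by_band[needed], length, integer(1)) == 0L]
  if (length(empty) > 0) {
    stop("community_band_bias references empty band(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  set.seed(spec$seed)
  n <- spec$n_users
  user_ids <- sprintf("user%05d", seq_len(n))
  community <- rep_len(seq_len(spec$n_communities), n)
  community <- community[sample.int(n)]
  follower_count <- rpowerlaw(n, spec$follower_exponent, n)
  users <- tibble::tibble(user_id = user_ids, community = community,
                          follower_count = follower_count)

  edge_blocks <- list()
  for (i in seq_len(spec$n_communities)) {
    for (j in seq_len(spec$n_communities)) {
      p <- if (i == j) spec$within_community_follow_prob
           else spec$between_community_follow_prob
      edge_blocks[[length(edge_blocks) + 1L]] <- sample_directed_pairs(
        user_ids[community == i], user_ids[community == j], p, same = i == j)
    }
  }
  edges <- do.call(rbind, edge_blocks)

  n_tweets_user <- sample(spec$tweets_per_user[1]:spec$tweets_per_user[2],
                          n, replace = TRUE)
  authors <- rep(seq_len(n), n_tweets_user)
  authors <- authors[sample.int(length(authors))]
  n_tweets <- length(authors)
  url <- character(n_tweets)
  is_retweet <- logical(n_tweets)
  original_idx <- integer(0)
  for (t in seq_len(n_tweets)) {
    a <- authors[t]
    if (length(original_idx) > 0L && runif(1) < spec$retweet_prob) {
      src <- original_idx[sample.int(length(original_idx), 1L)]
      url[t] <- url[src]
      is_retweet[t] <- TRUE
    } else {
      band <- sample(bands, 1L, prob = spec$community_band_bias[community[a], ])
      candidates <- pages_by_band[[band]]
      url[t] <- candidates[sample.int(length(candidates), 1L)]
      original_idx <- c(original_idx, t)
    }
  }
  origin <- as.POSIXct("2017-01-17 00:00:00", tz = "UTC")
  tweets <- tibble::tibble(
    tweet_id = sprintf("t%07d", seq_len(n_tweets)),
    user_id = user_ids[authors],
    url = url,
    is_retweet = is_retweet,
    follower_count = follower_count[authors],
    timestamp = format(origin + 60 * (seq_len(n_tweets) - 1L),
                       "%Y-%m-%dT%H:%M:%SZ")
  )
  list(tweets = tweets, edges = edges, users = users)
}
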