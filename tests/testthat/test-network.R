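# build a profiles tibble from explicit band lists
profiles_of <- function(...) {
  bands <- list(...)
  tibble::tibble(
    user_id = names(bands),
    n_pages = lengths(bands),
    scores = lapply(bands, function(b) rep(0L, length(b))),
    bands = bands
  )
}

test_that("sharer categories follow the at-least-2 / none-opposite rule", {
  prof <- profiles_of(
    u1 = c("high", "high", "medium"),   # high-sharer
    u2 = c("low", "high"),              # mixed -> other
    u3 = "low",                         # below threshold -> other
    u4 = c("low", "low", "medium"),     # low-sharer
    u5 = c("medium", "medium")          # other
  )
  cats <- classify_users_by_sharing(prof)
  expect_equal(cats$category,
               c("high-sharer", "other", "other", "low-sharer", "other"))
  # exclusive and exhaustive
  expect_true(all(cats$category %in% c("low-sharer", "high-sharer",
                                       "other")))
})

test_that("network inclusion needs >= 2 shared pages and keeps the LCC", {
  prof <- profiles_of(
    a1 = c("low", "low"), a2 = c("high", "high"),
    b1 = c("low", "medium"), b2 = c("medium", "medium"),
    solo = "low"
  )
  edges <- tibble::tibble(
    follower_id = c("a1", "b1", "solo"),
    followed_id = c("a2", "b2", "a1")
  )
  g <- build_follower_network(edges, prof)
  # solo excluded (1 page); two dyads tie at size 2; the one holding the
  # lexicographically smallest id (a1) wins
  expect_setequal(igraph::V(g)$name, c("a1", "a2"))
  expect_equal(igraph::graph_attr(g, "min_shared_pages"), 2L)
  expect_setequal(igraph::V(g)$category, c("low-sharer", "high-sharer"))
  # every retained node is in one weak component
  expect_equal(igraph::components(g, mode = "weak")$no, 1)
})

test_that("an empty surviving graph warns and returns an empty network", {
  prof <- profiles_of(u1 = "low")
  edges <- tibble::tibble(follower_id = "u1", followed_id = "u1")
  expect_warning(g <- build_follower_network(edges, prof), "empty network")
  expect_equal(igraph::vcount(g), 0)
})

test_that("assortativity is 1 for purely within-category edges and ~0 for
           random mixing", {
  # constructed graph whose edges all join same-category users
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("l1", "h1"), to = c("l2", "h2")),
    directed = TRUE,
    vertices = data.frame(name = c("l1", "l2", "h1", "h2"),
                          category = rep(c("low-sharer", "high-sharer"),
                                         each = 2)))
  expect_equal(sharing_assortativity(g), 1)

  # labels independent of a large random graph: coefficient near 0
  set.seed(30)
  n <- 200
  ids <- sprintf("u%03d", 1:n)
  bands <- lapply(seq_len(n), function(i)
    rep(sample(c("low", "high"), 1), 2))
  names(bands) <- ids
  prof_big <- do.call(profiles_of, bands)
  edges_big <- tibble::tibble(
    follower_id = sample(ids, 1500, replace = TRUE),
    followed_id = sample(ids, 1500, replace = TRUE))
  edges_big <- edges_big[edges_big$follower_id != edges_big$followed_id, ]
  gb <- build_follower_network(edges_big, prof_big)
  expect_lt(abs(sharing_assortativity(gb)), 0.1)
})

test_that("assortativity under strong homophily beats a label-permutation null", {
  pages <- tibble::tibble(url = sprintf("p%02d", 1:20),
                          band = rep(c("low", "high"), each = 10))
  spec <- social_spec(n_users = 120, n_communities = 2,
                      within_community_follow_prob = 0.2,
                      between_community_follow_prob = 0.005,
                      community_band_bias = rbind(c(0.95, 0, 0.05),
                                                  c(0.05, 0, 0.95)),
                      tweets_per_user = c(4, 8), retweet_prob = 0, seed = 31)
  soc <- generate_social(spec, pages)
  scores <- tibble::tibble(url = pages$url,
                           score = ifelse(pages$band == "low", 1L, 6L),
                           band = pages$band)
  prof <- user_credibility_profiles(soc$tweets, scores)
  g <- build_follower_network(soc$edges, prof)
  obs <- sharing_assortativity(g)
  cats <- igraph::V(g)$category
  set.seed(32)
  null <- vapply(1:999, function(b) {
    gp <- igraph::set_vertex_attr(g, "category", value = sample(cats))
    sharing_assortativity(gp)
  }, numeric(1))
  expect_gt(obs, quantile(null, 0.99))
})

test_that("planted communities are recovered from the follower graph", {
  skip_if_not_installed("mclust")
  pages <- tibble::tibble(url = sprintf("p%02d", 1:20),
                          band = rep(c("low", "high"), each = 10))
  spec <- social_spec(n_users = 150, n_communities = 2,
                      within_community_follow_prob = 0.15,
                      between_community_follow_prob = 0.002,
                      community_band_bias = rbind(c(0.95, 0, 0.05),
                                                  c(0.05, 0, 0.95)),
                      tweets_per_user = c(3, 6), retweet_prob = 0, seed = 33)
  soc <- generate_social(spec, pages)
  scores <- tibble::tibble(url = pages$url,
                           score = ifelse(pages$band == "low", 1L, 6L),
                           band = pages$band)
  prof <- user_credibility_profiles(soc$tweets, scores)
  g <- build_follower_network(soc$edges, prof)
  set.seed(34)
  membership <- detect_communities(g)
  planted <- soc$users$community[match(names(membership),
                                       soc$users$user_id)]
  ari <- mclust::adjustedRandIndex(membership, planted)
  expect_gte(ari, 0.9)
})
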