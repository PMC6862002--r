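test_that("presence tables count documents, not occurrences", {
  low <- list(c("measles", "vaccine", "measles"), c("safety"))
  other <- list(c("trial", "phase"), c("vaccine"))
  tab <- term_presence_table("measles", low, other)
  expect_equal(unname(tab), c(1L, 1L, 0L, 2L))

  none <- term_presence_table("absent", low, other)
  expect_equal(unname(none[c("a", "c")]), c(0L, 0L))

  planted <- term_presence_table("vaccine", low, other)
  expect_equal(unname(planted), c(1L, 1L, 1L, 1L))

  expect_error(term_presence_table("x", list(), other), "non-empty")
})

test_that("Fisher exact two-sided p-values match hand enumeration", {
  expect_equal(fisher_exact_two_sided(1, 1, 1, 1), 1)
  # margins (2,2): three admissible tables, each extreme has p 1/6
  expect_equal(fisher_exact_two_sided(2, 0, 0, 2), 1 / 3)
  # C(10,5) = 252; the two extreme tables each carry 1/252
  expect_equal(fisher_exact_two_sided(5, 0, 0, 5), 2 / 252)
  # degenerate margins
  expect_equal(fisher_exact_two_sided(0, 0, 3, 4), 1)
  expect_equal(fisher_exact_two_sided(0, 3, 0, 4), 1)
  expect_error(fisher_exact_two_sided(-1, 1, 1, 1), "nonnegative")
})

test_that("the exact test agrees with enumeration and stats::fisher.test
           on random small tables", {
  set.seed(13)
  for (i in 1:200) {
    cells <- as.integer(rmultinom(1, sample(4:28, 1), rep(0.25, 4)))
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    p <- fisher_exact_two_sided(a, b, c, d)
    expect_equal(p, oracle_fisher_p(a, b, c, d), tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value
    expect_equal(p, ft, tolerance = 1e-7)
  }
})

test_that("p is invariant under simultaneous swap of rows and columns", {
  set.seed(14)
  for (i in 1:50) {
    cells <- as.integer(rmultinom(1, 20, rep(0.25, 4)))
    p1 <- fisher_exact_two_sided(cells[1], cells[2], cells[3], cells[4])
    p2 <- fisher_exact_two_sided(cells[4], cells[3], cells[2], cells[1])
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("odds ratios follow the cross-product rule with Inf and NA cases", {
  expect_equal(odds_ratio(1, 1, 1, 1), 1)
  expect_equal(odds_ratio(5, 0, 0, 5), Inf)
  expect_equal(odds_ratio(4, 1, 2, 3), 6)
  expect_equal(odds_ratio(0, 5, 3, 0), 0)
  expect_warning(und <- odds_ratio(0, 5, 0, 5), "undefined")
  expect_true(is.na(und))
})

test_that("term ranking surfaces a planted low-credibility marker first", {
  set.seed(15)
  vocab_bg <- sprintf("w%02d", 1:30)
  make_page <- function(marker) {
    words <- sample(vocab_bg, 40, replace = TRUE)
    if (marker) words <- c(words, "plantedterm")
    words
  }
  tokens <- c(lapply(1:50, function(i) make_page(TRUE)),
              lapply(1:50, function(i) make_page(FALSE)))
  bands <- rep(c("low", "high"), each = 50)
  ranked <- rank_informative_terms(tokens, bands)
  expect_equal(nrow(ranked), length(unique(unlist(tokens))))
  expect_equal(ranked$term[1], "plantedterm")
  expect_equal(ranked$direction[1], "over")
  expect_equal(ranked$a[1], 50)
  expect_equal(ranked$c[1], 0)
  # minimal achievable p at these margins: two extreme tables of C(100,50)
  expect_equal(ranked$p[1], 2 / choose(100, 50))
  # direction is consistent with the odds ratio throughout
  expect_true(all(ranked$direction[!is.na(ranked$odds_ratio) &
                                     ranked$odds_ratio > 1] == "over"))
  expect_true(all(ranked$direction[!is.na(ranked$odds_ratio) &
                                     ranked$odds_ratio < 1] == "under"))
})

test_that("a term with identical prevalence in both groups is unranked
           above any associated term", {
  tokens <- list(c("same", "assoc"), c("same", "assoc"), c("same"),
                 c("same"), c("same"), c("same"))
  bands <- c("low", "low", "low", "high", "high", "high")
  ranked <- rank_informative_terms(tokens, bands, c("same", "assoc"))
  expect_equal(ranked$p[ranked$term == "same"], 1)
  expect_lt(ranked$p[ranked$term == "assoc"], 1)
  expect_equal(ranked$term[1], "assoc")
})

test_that("Benjamini-Hochberg flags are computed on adjusted p-values", {
  set.seed(16)
  tokens <- lapply(1:40, function(i) sample(sprintf("w%02d", 1:20), 15,
                                            replace = TRUE))
  bands <- rep(c("low", "high"), 20)
  raw <- rank_informative_terms(tokens, bands)
  bh <- rank_informative_terms(tokens, bands, correction = "BH")
  expect_true(all(bh$p_adjusted >= bh$p))
  expect_lte(sum(bh$significant), sum(raw$significant))
  expect_error(rank_informative_terms(tokens, rep("low", 40)), "low-band")
})
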