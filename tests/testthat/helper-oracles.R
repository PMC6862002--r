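# Independent oracles used to check package computations. These are written
# from first principles (factorials, pair counting) and share no code with
# the implementation paths they verify.

# Two-sided Fisher exact p by explicit enumeration with binomial
# coefficients (probability-mass two-sided rule).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; m1 <- a + c; m2 <- b + d; n <- a + b + c + d
  support <- max(0, r1 - m2):min(r1, m1)
  prob <- vapply(support, function(x)
    choose(m1, x) * choose(m2, r1 - x) / choose(n, r1), numeric(1))
  p_obs <- choose(m1, a) * choose(m2, r1 - a) / choose(n, r1)
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# Fleiss kappa by pair counting: observed agreement is, per item, the
# fraction of rater pairs that agree; chance agreement from category
# marginal proportions.
oracle_fleiss <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- ncol(ratings)
  agree_frac <- apply(ratings, 1, function(r) {
    pairs <- combn(n, 2)
    mean(r[pairs[1, ]] == r[pairs[2, ]])
  })
  p_bar <- mean(agree_frac)
  marg <- table(as.vector(ratings)) / length(ratings)
  p_e <- sum(marg^2)
  if (abs(1 - p_e) < 1e-12) return(NA_real_)
  (p_bar - p_e) / (1 - p_e)
}

# word k-shingle Jaccard computed directly on two texts
oracle_shingle_jaccard <- function(text_a, text_b, k = 5) {
  sh <- function(tx) {
    w <- strsplit(tolower(tx), "\\s+")[[1]]
    if (length(w) < k) return(paste(w, collapse = " "))
    unique(vapply(seq_len(length(w) - k + 1), function(i)
      paste(w[i:(i + k - 1)], collapse = " "), character(1)))
  }
  A <- sh(text_a); B <- sh(text_b)
  length(intersect(A, B)) / length(union(A, B))
}

# small labeled corpus shared by classifier tests (cached per test run)
small_corpus <- local({
  cache <- NULL
  function(n_pages = 200, seed = 5) {
    key <- paste(n_pages, seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- generate_corpus(corpus_spec(n_pages = n_pages,
                                                   seed = seed))
    }
    cache[[key]]
  }
})

# tiny handmade documents tibble
make_docs <- function(texts, ids = sprintf("d%02d", seq_along(texts))) {
  tibble::tibble(id = ids, url = paste0("https://x.test/", ids),
                 text = texts)
}

# a repeated-word page of a given length
page_of <- function(words, n) paste(rep_len(words, n), collapse = " ")
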