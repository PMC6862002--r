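# linearly separable toy features: one informative column
toy_task <- function(n = 40, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(sig = y + rnorm(n, sd = 0.05),
             noise = rnorm(n))
  list(x = x, y = y)
}

test_that("a linear SVM separates a separable toy task perfectly", {
  task <- toy_task()
  m <- train_criterion_classifier(task$x, task$y, "svm")
  expect_equal(predict(m, task$x), task$y)
})

test_that("tree ensembles are reproducible under a fixed seed", {
  task <- toy_task(60, seed = 2)
  m1 <- train_criterion_classifier(task$x, task$y, "rf", seed = 11)
  m2 <- train_criterion_classifier(task$x, task$y, "rf", seed = 11)
  expect_identical(predict(m1, task$x), predict(m2, task$x))
})

test_that("single-class labels raise a degenerate-label error", {
  task <- toy_task()
  expect_error(train_criterion_classifier(task$x, rep(1L, 40), "svm"),
               "degenerate")
  expect_error(grid_search(task$x, rep(0L, 40)), "degenerate")
})

test_that("grid search returns the only candidate, ignores duplicates, and
           picks the setting with higher CV F1", {
  task <- toy_task(40, seed = 3)
  single <- grid_search(task$x, task$y, "svm",
                        grid = list(cost = 10, gamma = 1), k = 4, seed = 1)
  expect_equal(single$best$cost, 10)

  dup <- grid_search(task$x, task$y, "svm",
                     grid = list(cost = c(10, 10, 100), gamma = 1),
                     k = 4, seed = 1)
  dedup <- grid_search(task$x, task$y, "svm",
                       grid = list(cost = c(10, 100), gamma = 1),
                       k = 4, seed = 1)
  expect_equal(dup$best, dedup$best)

  # hard task where regularization matters; verify the winner by
  # re-scoring every setting from the returned results table
  gs <- grid_search(task$x, task$y, "rf",
                    grid = list(ntree = c(1L, 25L)), k = 4, seed = 2)
  expect_equal(gs$best$ntree, gs$results$ntree[which.max(gs$results$mean_f1)])
})

test_that("cross-validation is perfectly scored on a perfectly predictable label", {
  set.seed(4)
  marker_in <- rbinom(60, 1, 0.5)
  texts <- vapply(seq_len(60), function(i) {
    words <- sample(sprintf("w%02d", 1:20), 30, replace = TRUE)
    if (marker_in[i]) words <- c(words, rep("zzmarker", 3))
    paste(words, collapse = " ")
  }, character(1))
  labels <- tibble::as_tibble(
    setNames(as.data.frame(matrix(rep(marker_in, 7), ncol = 7)),
             paste0("c", 1:7)))
  rep1 <- cross_validate(texts, labels, "svm", k = 5, seed = 1,
                         min_term_freq = 1, criteria = 1)
  expect_equal(mean(rep1$f1), 1)
  expect_equal(mean(rep1$accuracy), 1)
})

test_that("report bookkeeping: k folds per criterion, summary matches folds", {
  cd <- small_corpus(100, seed = 5)
  rep1 <- cross_validate(cd$documents$text, cd$labels, "rf", k = 5,
                         seed = 2, criteria = c(1, 4))
  expect_equal(nrow(rep1), 2 * 5)
  expect_true(all(rep1$f1 >= 0 & rep1$f1 <= 1, na.rm = TRUE))
  expect_true(all(rep1$accuracy >= 0 & rep1$accuracy <= 1))
  s <- cv_summary(rep1)
  manual <- mean(rep1$f1[rep1$criterion == 1], na.rm = TRUE)
  expect_equal(s$mean_f1[s$criterion == 1], manual)
})

test_that("permuted labels drop accuracy to the majority-class baseline", {
  cd <- small_corpus(200, seed = 5)
  set.seed(9)
  lab <- cd$labels
  lab$c7 <- sample(lab$c7)   # rare criterion, prevalence 0.1
  rep1 <- cross_validate(cd$documents$text, lab, "rf", k = 5, seed = 2,
                         criteria = 7)
  majority <- max(mean(lab$c7), 1 - mean(lab$c7))
  total_pred <- 200
  bounds <- qbinom(c(0.005, 0.995), total_pred, majority) / total_pred
  expect_gte(mean(rep1$accuracy), bounds[1])
  expect_lte(mean(rep1$accuracy), bounds[2])
})

test_that("signal contrast monotonically controls class separability", {
  f1_at <- function(contrast) {
    cd <- generate_corpus(corpus_spec(n_pages = 150,
                                      words_per_page = c(80, 120),
                                      signal_contrast = contrast,
                                      seed = 21))
    rep1 <- cross_validate(cd$documents$text, cd$labels, "rf", k = 4,
                           seed = 3, criteria = c(1, 4))
    mean(rep1$f1, na.rm = TRUE)
  }
  f1s <- vapply(c(0.55, 0.75, 0.95), f1_at, numeric(1))
  expect_true(all(diff(f1s) > 0))
  expect_gt(f1s[3], 0.9)
})

test_that("ensemble assembly picks the best family per criterion", {
  # mean F1 pattern in which the margin-based family wins criteria 3 and 7
  svm_f1 <- c(0.903, 0.802, 0.761, 0.903, 0.787, 0.912, 0.801)
  rf_f1 <- c(0.950, 0.915, 0.745, 0.959, 0.921, 0.964, 0.764)
  summary <- tibble::tibble(
    criterion = rep(1:7, 2),
    family = rep(c("svm", "rf"), each = 7),
    mean_f1 = c(svm_f1, rf_f1)
  )
  task <- toy_task()
  dummy <- train_criterion_classifier(task$x, task$y, "svm")
  models <- list(svm = rep(list(dummy), 7), rf = rep(list(dummy), 7))
  ens <- assemble_ensemble(summary, models)
  expect_equal(ens$selection$family,
               c("rf", "rf", "svm", "rf", "rf", "rf", "svm"))

  # exact tie goes to the tree ensemble
  tied <- summary
  tied$mean_f1 <- 0.9
  expect_true(all(assemble_ensemble(tied, models)$selection$family == "rf"))

  # a single supplied family is chosen everywhere
  solo <- summary[summary$family == "svm", ]
  expect_true(all(assemble_ensemble(solo, models)$selection$family == "svm"))

  # ensemble selection is a pure function of the reports
  expect_identical(assemble_ensemble(summary, models)$selection,
                   ens$selection)

  # a missing criterion is an assembly error
  expect_error(assemble_ensemble(summary[summary$criterion != 5, ], models),
               "criterion 5")
})

test_that("fitted ensembles predict held-out criteria and handle degenerate docs", {
  cd <- small_corpus(200, seed = 5)
  train_idx <- 1:160
  ens <- fit_ensemble(cd$documents$text[train_idx],
                      cd$labels[train_idx, ], k = 5, seed = 1)
  expect_s3_class(ens, "vaxcred_ensemble")
  expect_equal(nrow(ens$selection), 7)

  held <- cd$documents[-train_idx, ]
  pred <- predict_criteria(ens, held)
  truth <- as.matrix(cd$labels[-train_idx, paste0("c", 1:7)])
  mean_correct <- mean(rowSums(as.matrix(pred[, paste0("c", 1:7)]) == truth))
  expect_gte(mean_correct, 6)

  # a document identical to a training document recovers its labels
  memo <- predict_criteria(ens, cd$documents[3, ])
  expect_equal(unlist(memo[, paste0("c", 1:7)]),
               unlist(cd$labels[3, paste0("c", 1:7)]),
               ignore_attr = TRUE)

  # out-of-vocabulary text equals the models' zero-vector response
  oov <- predict_criteria(ens, make_docs("qqqxyz qqqabc qqqdef"))
  zero <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(1L, length(ens$featurizer$vocabulary)),
                               dimnames = list(NULL,
                                               ens$featurizer$vocabulary))
  zero_resp <- vapply(ens$models, function(m) predict(m, zero), integer(1))
  expect_equal(unname(unlist(oov[, paste0("c", 1:7)])), unname(zero_resp))

  # empty-after-preprocessing documents warn and predict all-unsatisfied
  expect_warning(empty_pred <- predict_criteria(ens, make_docs("the and of")),
                 "empty")
  expect_true(all(empty_pred[, paste0("c", 1:7)] == 0))
})
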