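#' Default hyperparameters for the two classifier families
#'
#' The margin-based family is a linear-kernel support vector machine with
#' `C = 100`, `gamma = 1`; the tree-ensemble family is a random forest with
#' 10 trees and Gini impurity. These are the reference settings for the
#' per-criterion classifiers.
#'
#' @param family `"svm"` (margin-based) or `"rf"` (tree ensemble).
#' @return named list of parameters.
#' @export
default_params <- function(family = c("rf", "svm")) {
  family <- match.arg(family)
  if (family == "svm") list(cost = 100, gamma = 1, kernel = "linear")
  else list(ntree = 10L)
}

#' Default hyperparameter grid
#'
#' The reference setting for each parameter plus one neighboring candidate,
#' so grid search is exercised without a combinatorial blow-up.
#'
#' @param family `"svm"` or `"rf"`.
#' @return named list of candidate vectors.
#' @export
default_grid <- function(family = c("rf", "svm")) {
  family <- match.arg(family)
  if (family == "svm") list(cost = c(100, 10), gamma = c(1, 0.5))
  else list(ntree = c(10L, 50L))
}

#' Train one per-criterion classifier
#'
#' Fits a binary classifier for a single checklist criterion on tf-idf
#' features: either a linear-kernel SVM (margin-based family) or a seeded
#' random forest (tree-ensemble family).
#'
#' @param x feature matrix (rows = documents).
#' @param y binary labels (0/1), both classes present.
#' @param family `"rf"` or `"svm"`.
#' @param params parameter list; defaults from [default_params()].
#' @param seed seed for the tree ensemble's bootstrap/feature sampling.
#' @return object of class `criterion_model`.
#' @export
train_criterion_classifier <- function(x, y, family = c("rf", "svm"),
                                       params = NULL, seed = 42L) {
  family <- match.arg(family)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("degenerate labels: training data contain a single class",
         call. = FALSE)
  }
  params <- modifyList(default_params(family), params %||% list())
  x <- as.matrix(x)
  yf <- factor(y, levels = c(0L, 1L))
  fit <- if (family == "svm") {
    e1071::svm(x = x, y = yf, kernel = params$kernel, cost = params$cost,
               gamma = params$gamma, scale = FALSE)
  } else {
    set.seed(seed)
    randomForest::randomForest(x = x, y = yf, ntree = params$ntree)
  }
  structure(list(family = family, params = params, fit = fit,
                 n_features = ncol(x)),
            class = "criterion_model")
}

#' Predict criterion satisfaction for documents
#'
#' @param object a `criterion_model`.
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @return integer vector of 0/1 predictions.
#' @export
predict.criterion_model <- function(object, newdata, ...) {
  as.integer(as.character(predict(object$fit, as.matrix(newdata))))
}

#' @export
print.criterion_model <- function(x, ...) {
  cat("<criterion_model>", x$family, "with",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      "on", x$n_features, "features\n")
  invisible(x)
}

# F1 on the criterion-satisfied class; NA when no actual or predicted
# positives exist (excluded from fold averages)
f1_score <- function(truth, pred, positive = 1L) {
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  denom <- 2 * tp + fp + fn
  if (denom == 0) return(NA_real_)
  2 * tp / denom
}

# stratified fold assignment: within each class, shuffled then dealt
# round-robin so every fold sees both classes where counts allow
stratified_folds <- function(y, k, seed) {
  if (length(y) < k) {
    stop("fewer examples (", length(y), ") than folds (", k, ")",
         call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# mean CV F1 of one parameter setting (internal to grid_search)
cv_f1_setting <- function(x, y, family, params, k, seed) {
  fold <- stratified_folds(y, k, seed)
  f1s <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    model <- train_criterion_classifier(x[tr, , drop = FALSE], y[tr],
                                        family, params, seed = seed)
    f1_score(y[!tr], predict(model, x[!tr, , drop = FALSE]))
  }, numeric(1))
  mean(f1s, na.rm = TRUE)
}

#' Exhaustive grid search over hyperparameters
#'
#' Evaluates every combination in the grid's cartesian product by mean
#' cross-validated F1 and returns the best setting. Ties are broken by grid
#' order (the first of the tied settings wins), so duplicated candidate
#' values cannot change the result.
#'
#' @param x feature matrix.
#' @param y binary labels.
#' @param family `"rf"` or `"svm"`.
#' @param grid named list of candidate vectors; defaults from
#'   [default_grid()].
#' @param k folds for the inner cross-validation.
#' @param seed seed shared by fold assignment and tree ensembles.
#' @return list with `best` (parameter list) and `results` (tibble of all
#'   settings with mean CV F1, in grid order).
#' @export
grid_search <- function(x, y, family = c("rf", "svm"), grid = NULL,
                        k = 5L, seed = 42L) {
  family <- match.arg(family)
  if (length(unique(as.integer(y))) < 2L) {
    stop("degenerate labels: grid search needs both classes", call. = FALSE)
  }
  grid <- grid %||% default_grid(family)
  stopifnot(all(lengths(grid) > 0))
  settings <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
  x <- as.matrix(x)
  scores <- vapply(seq_len(nrow(settings)), function(r)
    cv_f1_setting(x, y, family, as.list(settings[r, , drop = FALSE]),
                  k, seed),
    numeric(1))
  best_row <- which.max(scores)
  results <- tibble::as_tibble(settings)
  results$mean_f1 <- scores
  list(best = as.list(settings[best_row, , drop = FALSE]), results = results)
}

#' Cross-validate per-criterion classifiers
#'
#' Runs stratified k-fold cross-validation for each of the 7 criteria with a
#' given classifier family. Featurization is refit on each training fold
#' only (stop-word/frequency pruning, vocabulary, idf), so no information
#' leaks from test folds. Reports per-fold F1 (criterion-satisfied class)
#' and accuracy.
#'
#' @param texts character vector of document texts (or document tibble).
#' @param labels data frame with columns c1..c7 (0/1), rows aligned to
#'   `texts`.
#' @param family `"rf"` or `"svm"`.
#' @param k number of folds (default 10).
#' @param seed fold/ensemble seed (default 42).
#' @param params parameter list; defaults from [default_params()].
#' @param stopwords,min_term_freq preprocessing controls, see
#'   [preprocess_for_ml()].
#' @param criteria integer subset of 1:7 to evaluate (default all).
#' @return tibble: criterion, family, fold, f1, accuracy.
#' @export
cross_validate <- function(texts, labels, family = c("rf", "svm"), k = 10L,
                           seed = 42L, params = NULL,
                           stopwords = english_stopwords(),
                           min_term_freq = 2L, criteria = 1:7) {
  family <- match.arg(family)
  if (is.data.frame(texts)) texts <- texts$text
  if (length(texts) < k) {
    stop("fewer documents (", length(texts), ") than folds (", k, ")",
         call. = FALSE)
  }
  lab <- as.matrix(labels[, paste0("c", 1:7)])
  tokens_all <- lapply(tokenize(texts),
                       function(tk) tk[!(tk %in% stopwords)])
  rows <- list()
  for (i in criteria) {
    y <- as.integer(lab[, i])
    fold <- stratified_folds(y, k, seed + i)
    for (f in seq_len(k)) {
      tr <- fold != f
      freq <- table(unlist(tokens_all[tr]))
      vocab <- sort(names(freq[freq >= min_term_freq]))
      fz <- fit_tfidf(tokens_all[tr], vocab)
      xtr <- tfidf_transform(fz, tokens_all[tr])
      xte <- tfidf_transform(fz, tokens_all[!tr])
      model <- train_criterion_classifier(xtr, y[tr], family, params,
                                          seed = seed)
      pred <- predict(model, xte)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        criterion = i, family = family, fold = f,
        f1 = f1_score(y[!tr], pred),
        accuracy = mean(pred == y[!tr])
      )
    }
  }
  do.call(rbind, rows)
}

#' Summarize a cross-validation report
#'
#' @param report per-fold tibble from [cross_validate()] (families may be
#'   mixed).
#' @return tibble: criterion, family, mean_f1, sd_f1, mean_accuracy,
#'   sd_accuracy.
#' @export
cv_summary <- function(report) {
  key <- interaction(report$criterion, report$family, drop = TRUE)
  parts <- lapply(split(report, key), function(d) tibble::tibble(
    criterion = d$criterion[1], family = d$family[1],
    mean_f1 = mean(d$f1, na.rm = TRUE), sd_f1 = sd(d$f1, na.rm = TRUE),
    mean_accuracy = mean(d$accuracy), sd_accuracy = sd(d$accuracy)
  ))
  out <- do.call(rbind, parts)
  out[order(out$criterion, out$family), ]
}

#' Assemble the best-per-criterion ensemble
#'
#' Pure selection: for each criterion, picks the family with the highest
#' mean cross-validated F1; exact ties go to the tree ensemble. The result
#' pairs each criterion with its fitted model.
#'
#' @param summary summary tibble from [cv_summary()] covering all 7 criteria.
#' @param models nested list `models[[family]][[criterion]]` of fitted
#'   `criterion_model`s.
#' @return object of class `vaxcred_ensemble` (without featurizer; see
#'   [fit_ensemble()] for the end-to-end constructor).
#' @export
assemble_ensemble <- function(summary, models) {
  selection <- lapply(1:7, function(i) {
    cand <- summary[summary$criterion == i, , drop = FALSE]
    if (nrow(cand) == 0L) {
      stop("no cross-validation report for criterion ", i, call. = FALSE)
    }
    best <- max(cand$mean_f1)
    fams <- cand$family[cand$mean_f1 == best]
    fam <- if ("rf" %in% fams) "rf" else fams[1]
    if (is.null(models[[fam]][[i]])) {
      stop("no fitted ", fam, " model for criterion ", i, call. = FALSE)
    }
    list(criterion = i, family = fam, mean_f1 = best,
         model = models[[fam]][[i]])
  })
  structure(list(
    selection = tibble::tibble(
      criterion = 1:7,
      family = vapply(selection, `[[`, character(1), "family"),
      mean_f1 = vapply(selection, `[[`, numeric(1), "mean_f1")
    ),
    models = lapply(selection, `[[`, "model"),
    featurizer = NULL,
    stopwords = NULL
  ), class = "vaxcred_ensemble")
}

#' @export
print.vaxcred_ensemble <- function(x, ...) {
  cat("<vaxcred_ensemble> best-per-criterion models:\n")
  print(as.data.frame(x$selection), row.names = FALSE)
  invisible(x)
}

#' Fit the full per-criterion ensemble from labeled documents
#'
#' Cross-validates both classifier families on the labeled corpus, selects
#' the best family per criterion by mean F1 ([assemble_ensemble()]), refits
#' the selected models on the full corpus, and stores the full-corpus
#' featurizer so the ensemble can score new documents.
#'
#' @inheritParams cross_validate
#' @param families character vector of families to compare.
#' @return `vaxcred_ensemble` with `selection`, fitted `models`,
#'   `featurizer`, `cv_report` (per-fold) and preprocessing settings.
#' @export
fit_ensemble <- function(texts, labels, families = c("rf", "svm"), k = 10L,
                         seed = 42L, stopwords = english_stopwords(),
                         min_term_freq = 2L) {
  if (is.data.frame(texts)) texts <- texts$text
  report <- do.call(rbind, lapply(families, function(fam)
    cross_validate(texts, labels, fam, k = k, seed = seed,
                   stopwords = stopwords, min_term_freq = min_term_freq)))
  summary <- cv_summary(report)

  prep <- preprocess_for_ml(texts, stopwords, min_term_freq)
  fz <- fit_tfidf(prep$tokens, prep$vocabulary)
  x <- tfidf_transform(fz, prep$tokens)
  lab <- as.matrix(labels[, paste0("c", 1:7)])
  models <- lapply(setNames(families, families), function(fam)
    lapply(1:7, function(i)
      train_criterion_classifier(x, lab[, i], fam, seed = seed)))

  ens <- assemble_ensemble(summary, models)
  ens$featurizer <- fz
  ens$stopwords <- stopwords
  ens$cv_report <- report
  ens
}

#' Predict the 7 criterion judgments for documents
#'
#' Tokenizes each document, removes the ensemble's stop words, transforms
#' with the stored featurizer (out-of-vocabulary terms ignored), and applies
#' the per-criterion models. Documents that are empty after preprocessing
#' get an all-criteria-unsatisfied prediction, with a warning.
#'
#' @param ensemble a fitted [fit_ensemble()] object (with featurizer).
#' @param docs document tibble (id, text) or character vector of texts.
#' @return tibble: id, c1..c7 (0/1).
#' @export
predict_criteria <- function(ensemble, docs) {
  stopifnot(inherits(ensemble, "vaxcred_ensemble"))
  if (is.null(ensemble$featurizer)) {
    stop("ensemble has no featurizer; fit it with fit_ensemble()",
         call. = FALSE)
  }
  if (is.character(docs)) {
    docs <- tibble::tibble(id = sprintf("doc%05d", seq_along(docs)),
                           text = docs)
  }
  tokens <- lapply(tokenize(docs$text),
                   function(tk) tk[!(tk %in% (ensemble$stopwords %||%
                                                character(0)))])
  empty <- lengths(tokens) == 0L
  if (any(empty)) {
    warning(sum(empty), " document(s) empty after preprocessing; ",
            "predicted all criteria unsatisfied")
  }
  x <- tfidf_transform(ensemble$featurizer, tokens)
  pred <- vapply(ensemble$models, function(m) predict(m, x),
                 integer(nrow(docs)))
  if (nrow(docs) == 1L) pred <- matrix(pred, nrow = 1)
  pred[empty, ] <- 0L
  colnames(pred) <- paste0("c", 1:7)
  tibble::as_tibble(cbind(tibble::tibble(id = docs$id),
                          as.data.frame(pred)))
}
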