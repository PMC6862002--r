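#' Default pipeline configuration
#'
#' Reads the checked-in default configuration (filter thresholds, classifier
#' settings, band cut points are implicit in the scoring module) shipped at
#' `inst/extdata/default-config.yaml`.
#'
#' @return named list.
#' @export
default_config <- function() {
  yaml::read_yaml(system.file("extdata", "default-config.yaml",
                              package = "vaxcred", mustWork = TRUE))
}

# validate and complete a run configuration
normalize_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config <- modifyList(default_config(), config)
  assert_probability(config$dedup_threshold, "dedup_threshold")
  assert_count(config$min_words, "min_words")
  assert_count(config$folds, "folds", min = 2L)
  if (is.null(config$seed)) {
    stop("configuration field `seed` is required for stochastic stages",
         call. = FALSE)
  }
  config
}

write_stage <- function(writer, obj, path, stage) {
  tryCatch(writer(obj, path), error = function(e) {
    if (file.exists(path)) file.rename(path, paste0(path, ".partial"))
    stop("stage '", stage, "' failed while writing ", basename(path), ": ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Run the full surveillance pipeline
#'
#' Sequences the stages end to end: simulate (optional) -> ingest -> train
#' -> score -> terms -> exposure -> network, writing every artifact and a
#' run manifest (config hash, seed, per-file checksums, package version)
#' under `out_dir`. Rerunning with an identical configuration and seed
#' reproduces byte-identical scores and exposure summaries.
#'
#' When `config$simulate` is `TRUE` the synthetic module generates corpus,
#' labels, tweets and edges; otherwise paths to existing files must be
#' given in `config$corpus_file`, `config$labels_file`,
#' `config$tweets_file`, `config$edges_file`.
#'
#' @param config list or path to a YAML file; missing fields are filled
#'   from [default_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly; artifacts are written under `out_dir`.
#' @export
run_full_pipeline <- function(config, out_dir) {
  config <- normalize_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  stages <- character(0)
  artifact <- function(name) file.path(out_dir, name)

  if (isTRUE(config$simulate)) {
    cspec <- corpus_spec(n_pages = config$sim_n_pages %||% 500,
                         seed = seed)
    corpus_data <- generate_corpus(cspec)
    raw_docs <- inject_filter_noise(
      corpus_data$documents,
      dup_rate = config$sim_dup_rate %||% 0.05,
      short_rate = config$sim_short_rate %||% 0.05,
      nonenglish_rate = config$sim_nonenglish_rate %||% 0.05,
      seed = seed + 1L)
    labels <- corpus_data$labels
    planted <- credibility_scores(labels)
    planted$url <- corpus_data$documents$url[match(planted$id,
                                                   corpus_data$documents$id)]
    sspec <- social_spec(n_users = config$sim_n_users %||% 200,
                         seed = seed + 2L)
    social <- generate_social(sspec, planted[, c("url", "band")])
    write_stage(write_jsonl, raw_docs[, c("id", "url", "text")],
                artifact("pages.jsonl"), "simulate")
    write_stage(write_labels_csv, labels, artifact("labels.csv"), "simulate")
    write_stage(write_jsonl, social$tweets, artifact("tweets.jsonl"),
                "simulate")
    write_stage(write_edges_tsv, social$edges, artifact("followers.tsv"),
                "simulate")
    config$corpus_file <- artifact("pages.jsonl")
    config$labels_file <- artifact("labels.csv")
    config$tweets_file <- artifact("tweets.jsonl")
    config$edges_file <- artifact("followers.tsv")
    stages <- c(stages, "simulate")
  }

  for (field in c("corpus_file", "labels_file", "tweets_file",
                  "edges_file")) {
    if (is.null(config[[field]])) {
      stop("configuration field `", field, "` is missing", call. = FALSE)
    }
  }

  # ingest
  raw <- read_jsonl(config$corpus_file)
  ingest <- run_ingest(raw, min_words = config$min_words,
                       dedup_threshold = config$dedup_threshold)
  write_stage(function(o, p) write_jsonl(o[, c("id", "url", "text")], p),
              ingest$corpus, artifact("corpus.jsonl"), "ingest")
  write_stage(function(o, p)
    jsonlite::write_json(setNames(as.list(o$count), o$stage), p,
                         auto_unbox = TRUE),
    ingest$report, artifact("attrition.json"), "ingest")
  stages <- c(stages, "ingest")

  # train
  labels <- read_labels_csv(config$labels_file)
  train_ids <- intersect(ingest$corpus$id, labels$id)
  if (length(train_ids) < config$folds) {
    stop("stage 'train': fewer labeled in-corpus pages (",
         length(train_ids), ") than folds", call. = FALSE)
  }
  train_docs <- ingest$corpus[match(train_ids, ingest$corpus$id), ]
  train_lab <- labels[match(train_ids, labels$id), ]
  ensemble <- fit_ensemble(train_docs$text, train_lab,
                           k = config$folds, seed = seed)
  write_stage(function(o, p) write.csv(o, p, row.names = FALSE),
              cv_summary(ensemble$cv_report), artifact("cv_report.csv"),
              "train")
  stages <- c(stages, "train")

  # score
  pred <- predict_criteria(ensemble, ingest$corpus)
  scores <- credibility_scores(pred)
  scores$url <- ingest$corpus$url[match(scores$id, ingest$corpus$id)]
  write_stage(function(o, p) write.csv(o, p, row.names = FALSE, quote = FALSE),
              scores[, c("id", paste0("c", 1:7), "score", "band")],
              artifact("scores.csv"), "score")
  stages <- c(stages, "score")

  # terms
  prep <- preprocess_for_ml(ingest$corpus$text)
  terms <- rank_informative_terms(prep$tokens, scores$band,
                                  prep$vocabulary,
                                  alpha = config$alpha %||% 0.05)
  write_stage(function(o, p)
    write.table(o, p, sep = "\t", row.names = FALSE, quote = FALSE),
    terms, artifact("terms.tsv"), "terms")
  stages <- c(stages, "terms")

  # exposure
  tweets <- read_jsonl(config$tweets_file)
  expo <- exposure_by_band(scores[, c("url", "band")], tweets)
  write_stage(function(o, p)
    jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA),
    list(per_band = expo$per_band, unresolved = expo$unresolved),
    artifact("exposure.json"), "exposure")
  stages <- c(stages, "exposure")

  # network
  edges <- read_edges_tsv(config$edges_file)
  profiles <- user_credibility_profiles(tweets,
                                        scores[, c("url", "score", "band")])
  network <- build_follower_network(edges, profiles,
                                    min_shared_pages =
                                      config$min_shared_pages %||% 2L)
  write_stage(write_network_graphml, network, artifact("network.graphml"),
              "network")
  stages <- c(stages, "network")

  config_path <- artifact("config.json")
  jsonlite::write_json(config, config_path, auto_unbox = TRUE, digits = NA)
  files <- c("corpus.jsonl", "attrition.json", "cv_report.csv",
             "scores.csv", "terms.tsv", "exposure.json", "network.graphml")
  manifest <- list(
    seed = seed,
    config_hash = unname(tools::md5sum(config_path)),
    stages = stages,
    checksums = setNames(
      as.list(unname(tools::md5sum(file.path(out_dir, files)))), files),
    package_version = as.character(utils::packageVersion("vaxcred")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(manifest, artifact("manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
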