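# Experiment orchestration: simulate -> extract -> featurize -> train ->
# rank -> evaluate, with every artifact written to disk and every source of
# randomness seeded from the config, so re-running an identical config
# reproduces the report bit for bit.

#' Extract and label the candidates of a whole corpus
#'
#' Runs [extract_candidates()] and [label_candidates()] over every note and
#' pools the results.
#'
#' @param notes named list of `note` objects.
#' @param gold named list of gold term vectors.
#' @param lexicon a `lexicon`.
#' @return list with `candidates` (pooled labeled data frame), `missed`
#'   (named integer vector of per-note extraction misses) and
#'   `extraction_recall` (overall fraction of gold terms found).
#' @export
label_corpus <- function(notes, gold, lexicon) {
  lab <- lapply(names(notes), function(id) {
    label_candidates(extract_candidates(notes[[id]], lexicon),
                     gold[[id]] %||% character(0))
  })
  names(lab) <- names(notes)
  candidates <- do.call(rbind, lapply(lab, `[[`, "candidates"))
  rownames(candidates) <- NULL
  missed <- vapply(lab, function(x) length(x$missed_gold), integer(1))
  n_gold <- vapply(names(notes),
                   function(id) length(unique(gold[[id]] %||% character(0))),
                   integer(1))
  list(candidates = candidates, missed = missed,
       extraction_recall = 1 - sum(missed) / max(sum(n_gold), 1L))
}

#' Default experiment configuration
#'
#' @param ... named overrides.
#' @return configuration list.
#' @export
default_experiment_config <- function(...) {
  cfg <- list(
    simulate = TRUE,
    profile = "table1",
    profile_overrides = list(),
    paths = NULL,                # list(notes=, gold=, lexicon=, embeddings=)
    seed = 42L,
    ranker = "ranksvm",
    folds = 10L,
    C = 100,
    C_grid = NULL,               # non-NULL: select C by inner CV
    B_grid = c(100L, 300L),
    blocks = c("baseline", "embedding", "semantic_type", "chv", "topic"),
    min_count = 3L,
    topic_combine = "product",
    lda_K = c(5L, 10L, 20L),
    lda_iter = 150L,
    embedding_d = 50L,
    embedding_signal = 1,
    out_dir = "termrank_run",
    write_features = FALSE)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Run a full ranking experiment
#'
#' Executes the whole pipeline from a single config: simulate a corpus (or
#' load one from `paths`), extract and label candidates, build feature
#' resources, cross-validate the requested ranker and write all artifacts
#' (corpus files, candidate dump, optional feature matrix, final model,
#' ranked lists, evaluation report as JSON and TSV, fold assignment and a
#' log of seeds and package versions) under `config$out_dir`.
#'
#' @param config a [default_experiment_config()] list, a YAML file path, or
#'   named overrides via a partial list.
#' @return the `eval_report`, invisibly extended with `out_dir`.
#' @export
run_experiment <- function(config = default_experiment_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- do.call(default_experiment_config, config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "log.txt")
  log_line <- function(...) {
    msg <- paste0(...)
    message("[termrank] ", msg)
    cat(msg, "\n", file = logf, append = TRUE)
  }
  cat("", file = logf)
  log_line("termrank ", as.character(utils::packageVersion("termrank")),
           " | R ", as.character(getRversion()), " | seed ", config$seed)

  seed <- as.integer(config$seed)
  if (isTRUE(config$simulate)) {
    log_line("stage simulate: profile ", config$profile)
    profile <- do.call(generator_profile,
                       c(list(name = config$profile), config$profile_overrides))
    lexicon <- generate_lexicon(profile, seed = seed)
    corpus <- generate_corpus(profile, lexicon, seed = seed + 1L)
    notes <- corpus$notes
    gold <- corpus$gold
    background <- generate_background(profile, lexicon, seed = seed + 2L)
    embeddings <- generate_embeddings(lexicon, d = config$embedding_d,
                                      signal_strength = config$embedding_signal,
                                      seed = seed + 3L)
    write_notes(notes, file.path(out, "notes"))
    write_gold(gold, file.path(out, "gold.tsv"))
    write_lexicon(lexicon, file.path(out, "lexicon.tsv"))
    write_embeddings(embeddings, file.path(out, "embeddings.txt"))
  } else {
    p <- config$paths
    if (is.null(p)) stop("run_experiment: simulate = FALSE needs paths")
    log_line("stage load: ", p$notes)
    notes <- read_notes(p$notes)
    gold <- read_gold(p$gold)
    lexicon <- load_lexicon(p$lexicon)
    background_notes <- if (!is.null(p$background)) read_notes(p$background)
                        else notes
    background <- background_corpus(background_notes, lexicon)
    embeddings <- if (!is.null(p$embeddings)) load_embeddings(p$embeddings)
                  else NULL
  }

  log_line("stage extract: ", length(notes), " notes")
  lab <- label_corpus(notes, gold, lexicon)
  write_candidates(lab$candidates, file.path(out, "candidates.tsv"))
  log_line("extraction recall ", round(lab$extraction_recall, 3))

  fc <- feature_config(blocks = config$blocks, min_count = config$min_count,
                       topic_combine = config$topic_combine)
  resources <- list(background = background, embeddings = embeddings)
  if ("topic" %in% fc$blocks) {
    log_line("stage topics: K = ", paste(config$lda_K, collapse = ","))
    resources$topic_models <- lapply(seq_along(config$lda_K), function(i) {
      train_topic_model(background, K = config$lda_K[i],
                        seed = seed + 10L + i, n_iter = config$lda_iter)
    })
    resources$note_topics <- compute_note_topics(notes,
                                                 resources$topic_models,
                                                 seed = seed + 100L)
  }

  log_line("stage evaluate: ", config$ranker, ", ", config$folds, " folds")
  report <- cross_validate(notes, gold, lexicon, resources, fc,
                           ranker = config$ranker, folds = config$folds,
                           seed = seed,
                           C = if (is.null(config$C_grid)) config$C else NULL,
                           C_grid = config$C_grid %||% c(0.01, 0.1, 1, 10, 100),
                           B_grid = config$B_grid,
                           candidates = lab$candidates, missed = lab$missed)

  # final model on the full corpus, for deployment-style artifacts
  schema <- feature_schema(lab$candidates, fc, lexicon$semantic_types)
  X <- assemble_features(lab$candidates, notes, resources, fc, schema)
  X <- apply_scaling(X, feature_scaling(X))
  if (isTRUE(config$write_features)) {
    utils::write.table(cbind(lab$candidates[, c("note_id", "term", "label")],
                             as.data.frame(as.matrix(X))),
                       file.path(out, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (config$ranker == "ranksvm") {
    pairs <- build_pairs(lab$candidates$label, lab$candidates$note_id)
    model <- train_ranksvm(X, pairs, C = config$C)
    utils::write.table(data.frame(feature = names(model$w), weight = model$w),
                       file.path(out, "model.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    model <- train_rf(X, lab$candidates$label, B_grid = config$B_grid,
                      seed = seed)
    yaml::write_yaml(list(ranker = "rf", B = model$B,
                          oob = as.list(model$oob), seed = seed),
                     file.path(out, "model.yaml"))
  }

  utils::write.table(report$ranked, file.path(out, "ranked.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(note_id = names(report$folds),
                                fold = unname(report$folds)),
                     file.path(out, "folds.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$per_note, file.path(out, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(ranker = report$ranker, seed = seed,
         extraction_recall = lab$extraction_recall,
         macro = as.list(report$macro),
         per_note = report$per_note,
         config = config[c("profile", "ranker", "folds", "C", "blocks",
                           "lda_K", "embedding_d", "min_count", "seed")]),
    file.path(out, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  log_line("done: macro AUC-ROC_ranking ",
           round(report$macro[["auc_ranking"]], 3))
  report$out_dir <- out
  invisible(report)
}

#' Compare two evaluation reports metric by metric
#'
#' Paired t tests on the per-note metric values of two systems evaluated on
#' the same note set, laid out as the usual eight-metric grid (P/R/F at 5
#' and 10, the two AUC variants).
#'
#' @param report_a,report_b `eval_report` objects over identical note sets.
#' @return data frame with one row per metric: means of both systems, mean
#'   paired difference and the two-sided p-value.
#' @export
compare_systems <- function(report_a, report_b) {
  a <- report_a$per_note
  b <- report_b$per_note
  if (!identical(sort(a$note_id), sort(b$note_id))) {
    stop("compare_systems: note sets differ")
  }
  b <- b[match(a$note_id, b$note_id), ]
  metrics <- c("p5", "r5", "f5", "p10", "r10", "f10",
               "auc_ranking", "auc_ke")
  rows <- lapply(metrics, function(m) {
    tt <- paired_t_test(a[[m]], b[[m]])
    data.frame(metric = m, mean_a = mean(a[[m]], na.rm = TRUE),
               mean_b = mean(b[[m]], na.rm = TRUE),
               mean_diff = tt$mean_diff, p_value = tt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
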