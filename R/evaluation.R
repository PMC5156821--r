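# Evaluation protocol: relaxed string match, precision/recall/F at rank n,
# per-note AUC-ROC over extracted candidates (ranking quality) and over all
# gold terms including extraction misses (joint extraction + ranking quality),
# cross-validation, and paired t tests.

# gold must occur as a contiguous subsequence of system (or be equal)
.relaxed_match_tokens <- function(sys_toks, gold_toks) {
  ns <- length(sys_toks); ng <- length(gold_toks)
  if (ns == 0L || ng == 0L || ng > ns) return(FALSE)
  for (k in 0:(ns - ng)) {
    if (all(sys_toks[(k + 1L):(k + ng)] == gold_toks)) return(TRUE)
  }
  FALSE
}

#' Relaxed string match between a system term and a gold term
#'
#' True when the two terms are equal after normalization (lowercasing,
#' possessive stripping, Porter stemming), or when the gold term occurs as a
#' contiguous token subsequence of the system term (the system term
#' *subsumes* the gold term, e.g. "non-Hodgkin lymphoma" subsumes
#' "lymphoma"). The reverse, part-of containment, does not count: a fragment
#' of an important term (e.g. "iron" within "iron deficiency") is typically
#' too general to be important.
#'
#' @param system_term term produced by a system.
#' @param gold_term gold-standard term.
#' @return logical scalar; empty strings never match.
#' @export
relaxed_match <- function(system_term, gold_term) {
  if (!nzchar(system_term) || !nzchar(gold_term)) return(FALSE)
  .relaxed_match_tokens(.norm_tokens(system_term), .norm_tokens(gold_term))
}

#' Precision, recall and F-score over the top k ranked terms
#'
#' Each of the top `min(k, length(ranked_terms))` terms counts as a true
#' positive if it relaxed-matches a gold term not already credited to an
#' earlier term (one gold term is credited at most once, so duplicated system
#' output cannot double-count). Precision divides by `k`, recall by the gold
#' set size. In the final-evaluation protocol the gold set passed here is the
#' full annotation, including terms the extractor missed.
#'
#' @param ranked_terms character vector of system terms in rank order.
#' @param gold character vector of gold terms.
#' @param k rank cutoff (>= 1).
#' @return named numeric vector `c(p, r, f)`; all `NA` when the gold set is
#'   empty (such notes are skipped and reported by callers).
#' @export
prf_at_k <- function(ranked_terms, gold, k) {
  stopifnot(k >= 1)
  gold <- unique(gold[nzchar(gold)])
  if (!length(gold)) return(c(p = NA_real_, r = NA_real_, f = NA_real_))
  top <- utils::head(ranked_terms, k)
  gtoks <- lapply(gold, .norm_tokens)
  claimed <- logical(length(gold))
  tp <- 0L
  for (term in top) {
    ttoks <- .norm_tokens(term)
    for (j in seq_along(gold)) {
      if (!claimed[j] && .relaxed_match_tokens(ttoks, gtoks[[j]])) {
        claimed[j] <- TRUE
        tp <- tp + 1L
        break
      }
    }
  }
  p <- tp / k
  r <- tp / length(gold)
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(p = p, r = r, f = f)
}

#' Per-note AUC-ROC over extracted candidates
#'
#' Fraction of (positive, negative) candidate pairs ranked concordantly by
#' score, counting exact score ties as 1/2 — the trapezoidal ROC area,
#' computed by the rank-sum identity. Notes with a single class cannot be
#' scored and should be skipped (this function returns `NA` for them).
#'
#' @param scores numeric scores, higher = ranked more important.
#' @param labels binary labels in `{0, 1}`.
#' @return AUC in `[0, 1]`, or `NA` if one class is absent.
#' @export
auc_ranking <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-note AUC-ROC over all gold terms (keyphrase-level)
#'
#' Counts every gold term as a positive, including the `n_missed_gold` terms
#' the extractor never produced: these enter as phantom positives ranked
#' strictly below every scored candidate, so each contributes zero concordant
#' pairs. With no score ties at the bottom this equals
#' `auc_ranking * found / (found + missed)`.
#'
#' @param scores numeric scores of the extracted candidates.
#' @param labels binary labels of the extracted candidates.
#' @param n_missed_gold number of gold terms absent from the candidates.
#' @return AUC in `[0, 1]`, or `NA` when no scored positive or no negative
#'   exists (degenerate note, skipped by callers).
#' @export
auc_ke <- function(scores, labels, n_missed_gold = 0L) {
  stopifnot(n_missed_gold >= 0L)
  if (n_missed_gold == 0L) return(auc_ranking(scores, labels))
  labels <- as.integer(labels)
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L) return(NA_real_)
  floor_score <- min(scores) - 1
  auc_ranking(c(scores, rep(floor_score, n_missed_gold)),
              c(labels, rep(1L, n_missed_gold)))
}

#' Paired t test between two per-note metric vectors
#'
#' Two-sided paired t test on the per-note differences. Degenerate inputs are
#' handled explicitly: identical vectors give p = 1; a constant nonzero
#' difference has infinite t, reported as p = 0 with `degenerate = TRUE`.
#'
#' @param metric_a,metric_b numeric vectors of equal length >= 2, paired by
#'   note.
#' @return list with `p.value`, `statistic`, `mean_diff` and `degenerate`.
#' @export
paired_t_test <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) == length(metric_b), length(metric_a) >= 2L)
  keep <- !is.na(metric_a) & !is.na(metric_b)
  d <- metric_a[keep] - metric_b[keep]
  if (length(d) < 2L) stop("paired_t_test: fewer than 2 complete pairs")
  if (stats::sd(d) < 1e-12 * max(1, abs(mean(d)))) {
    if (abs(mean(d)) < 1e-12) {
      return(list(p.value = 1, statistic = 0, mean_diff = 0, degenerate = TRUE))
    }
    return(list(p.value = 0, statistic = sign(mean(d)) * Inf,
                mean_diff = mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(metric_a[keep], metric_b[keep], paired = TRUE)
  list(p.value = ht$p.value, statistic = unname(ht$statistic),
       mean_diff = mean(d), degenerate = FALSE)
}

# deterministic fold assignment of note ids
.make_folds <- function(note_ids, folds, seed) {
  if (folds > length(note_ids)) stop("cross_validate: folds > number of notes")
  if (folds < 2L) stop("cross_validate: need folds >= 2")
  set.seed(seed)
  shuffled <- sample(note_ids)
  fold <- rep(seq_len(folds), length.out = length(shuffled))
  stats::setNames(fold[order(match(note_ids, shuffled))], note_ids)
}

#' Cross-validated evaluation of a ranker on an annotated corpus
#'
#' Partitions notes into folds, and per fold rebuilds every training-derived
#' resource (lexical vocabulary, one-hot category sets, optionally the
#' regularization constant), trains the requested ranker on the training
#' folds, ranks the held-out notes and scores them: P/R/F at ranks 5 and 10
#' against the full gold sets (including extraction misses), per-note AUC-ROC
#' over candidates, and keyphrase-level AUC-ROC with misses as phantom
#' positives. Metrics are macro-averaged over all evaluable notes.
#'
#' @param notes named list of `note` objects.
#' @param gold named list mapping note id to gold term vectors.
#' @param lexicon a `lexicon`.
#' @param resources resource list as for [assemble_features()].
#' @param config a [feature_config()].
#' @param ranker `"ranksvm"` or `"rf"`.
#' @param folds number of folds (default 10).
#' @param seed integer seed controlling fold assignment and training.
#' @param C rankSVM regularization constant, or `NULL` to select it by inner
#'   cross-validation over `C_grid`.
#' @param C_grid grid for [select_C()] when `C` is `NULL`.
#' @param B_grid forest sizes for [train_rf()].
#' @param candidates optional precomputed labeled candidate data frame (as
#'   produced by [label_corpus()]); supply to avoid re-extracting.
#' @param missed optional named integer vector of per-note extraction-miss
#'   counts matching `candidates`; recomputed if omitted.
#' @return an `eval_report`: `per_note` data frame, `macro` named means,
#'   `folds` assignment, `skipped` note ids (no gold, or single-class for
#'   AUC), `ranker`, `seed`, and the pooled `ranked` lists from the held-out
#'   folds.
#' @export
cross_validate <- function(notes, gold, lexicon, resources, config,
                           ranker = c("ranksvm", "rf"), folds = 10L,
                           seed = 1L, C = 1, C_grid = c(0.01, 0.1, 1, 10, 100),
                           B_grid = c(100L, 300L), candidates = NULL,
                           missed = NULL) {
  ranker <- match.arg(ranker)
  ids <- names(notes)
  fold_of <- .make_folds(ids, folds, seed)

  if (is.null(candidates)) {
    lab <- label_corpus(notes, gold, lexicon)
    candidates <- lab$candidates
    missed <- lab$missed
  } else {
    stopifnot(all(c("note_id", "label") %in% names(candidates)))
    if (is.null(missed)) {
      missed <- vapply(ids, function(id) {
        g <- unique(gold[[id]] %||% character(0))
        cand <- candidates$term[candidates$note_id == id]
        sum(!vapply(g, function(gt) any(vapply(cand, relaxed_match,
                                               logical(1), gold_term = gt)),
                    logical(1)))
      }, integer(1))
    }
  }

  per_note <- list()
  ranked_all <- list()
  for (f in seq_len(folds)) {
    test_ids <- ids[fold_of == f]
    train_ids <- setdiff(ids, test_ids)
    tr <- candidates[candidates$note_id %in% train_ids, , drop = FALSE]
    te <- candidates[candidates$note_id %in% test_ids, , drop = FALSE]
    schema <- feature_schema(tr, config, lexicon$semantic_types)
    Xtr <- assemble_features(tr, notes, resources, config, schema)
    Xte <- assemble_features(te, notes, resources, config, schema)
    # per-column max-abs rescaling fitted on the training folds: puts every
    # feature on a comparable [0, 1]-ish scale for the margin penalty
    # without destroying sparsity
    sc <- feature_scaling(Xtr)
    Xtr <- apply_scaling(Xtr, sc)
    Xte <- apply_scaling(Xte, sc)

    if (ranker == "ranksvm") {
      pairs <- build_pairs(tr$label, tr$note_id)
      Cuse <- C
      if (is.null(Cuse)) {
        Cuse <- select_C(tr, Xtr, grid = C_grid, folds = 3L,
                         seed = seed + 1000L + f)
      }
      model <- train_ranksvm(Xtr, pairs, C = Cuse)
    } else {
      model <- train_rf(Xtr, tr$label, B_grid = B_grid, seed = seed + f)
    }
    ranked <- score_and_rank(model, te, Xte)
    ranked_all[[f]] <- ranked

    for (id in test_ids) {
      g <- unique(gold[[id]] %||% character(0))
      rk <- ranked[ranked$note_id == id, , drop = FALSE]
      lab_note <- te$label[te$note_id == id][match(rk$term, te$term[te$note_id == id])]
      p5 <- prf_at_k(rk$term, g, 5L)
      p10 <- prf_at_k(rk$term, g, 10L)
      per_note[[id]] <- data.frame(
        note_id = id, fold = f, n_candidates = nrow(rk),
        n_pos = sum(lab_note == 1L), n_missed = unname(missed[id]),
        p5 = p5["p"], r5 = p5["r"], f5 = p5["f"],
        p10 = p10["p"], r10 = p10["r"], f10 = p10["f"],
        auc_ranking = auc_ranking(rk$score, lab_note),
        auc_ke = auc_ke(rk$score, lab_note, unname(missed[id])),
        stringsAsFactors = FALSE)
    }
  }
  per_note <- do.call(rbind, per_note[ids])
  rownames(per_note) <- NULL
  metr <- c("p5", "r5", "f5", "p10", "r10", "f10", "auc_ranking", "auc_ke")
  macro <- vapply(metr, function(m) mean(per_note[[m]], na.rm = TRUE),
                  numeric(1))
  skipped <- per_note$note_id[apply(is.na(per_note[, metr]), 1L, any)]
  structure(list(per_note = per_note, macro = macro, folds = fold_of,
                 skipped = skipped, ranker = ranker, seed = seed,
                 ranked = do.call(rbind, ranked_all)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", x$ranker, "-", nrow(x$per_note), "notes,",
      max(x$folds), "folds\n")
  print(round(x$macro, 3))
  if (length(x$skipped)) {
    cat("skipped (degenerate):", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
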