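# Rankers: a pairwise ranking SVM trained on within-note
# (important, nonimportant) candidate pairs, and a probability random
# forest baseline that scores candidates by the averaged per-tree leaf
# positive fraction. Both consume identical feature matrices.

#' Build the within-note training pair set
#'
#' All pairs (i, j) with `label[i] = 1`, `label[j] = 0` and both candidates
#' in the same note. Notes lacking either class contribute no pairs.
#'
#' @param labels integer labels in `{0, 1}` (one per candidate row).
#' @param note_ids note id per candidate row.
#' @return object of class `pair_set` with integer vectors `i`, `j` (row
#'   indices into the candidate/feature matrix) and the pair count `m`.
#' @export
build_pairs <- function(labels, note_ids) {
  stopifnot(length(labels) == length(note_ids),
            all(labels %in% c(0L, 1L)))
  ii <- integer(0); jj <- integer(0)
  for (ids in split(seq_along(labels), note_ids)) {
    pos <- ids[labels[ids] == 1L]
    neg <- ids[labels[ids] == 0L]
    if (length(pos) && length(neg)) {
      g <- expand.grid(i = pos, j = neg, KEEP.OUT.ATTRS = FALSE)
      ii <- c(ii, g$i); jj <- c(jj, g$j)
    }
  }
  structure(list(i = ii, j = jj, m = length(ii)), class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat("<pair_set>", x$m, "pairs\n")
  invisible(x)
}

#' Exact pairwise hinge objective of a ranking SVM
#'
#' `0.5 * ||w||^2 + (C/m) * sum over pairs of max(0, 1 - w.(x_i - x_j))` —
#' the soft-margin objective whose slack term counts (softly) the training
#' pairs ranked in the wrong order.
#'
#' @param w weight vector.
#' @param X feature matrix.
#' @param pairs a [build_pairs()] result.
#' @param C regularization trade-off (> 0).
#' @return objective value.
#' @export
ranksvm_objective <- function(w, X, pairs, C) {
  s <- as.numeric(X %*% w)
  margins <- 1 - (s[pairs$i] - s[pairs$j])
  0.5 * sum(w^2) + (C / pairs$m) * sum(pmax(margins, 0))
}

# smoothed (Huberized) hinge and its derivative wrt the margin violation t
.huber_hinge <- function(t, delta) {
  ifelse(t <= 0, 0, ifelse(t <= delta, t^2 / (2 * delta), t - delta / 2))
}
.huber_hinge_d <- function(t, delta) {
  pmin(pmax(t / delta, 0), 1)
}

#' Train a pairwise ranking SVM
#'
#' Minimizes the soft-margin pairwise objective on difference vectors with a
#' smoothed-hinge continuation (L-BFGS on a Huberized hinge with decreasing
#' smoothing), which converges to the exact hinge optimum; the model stores
#' the exact hinge objective at the solution. On small problems the attained
#' objective matches exhaustive grid search to well under 1%.
#'
#' @param X numeric feature matrix (rows = candidates).
#' @param pairs a [build_pairs()] result with `m >= 1`.
#' @param C regularization trade-off (> 0).
#' @param maxit L-BFGS iteration cap per continuation stage.
#' @param deltas decreasing smoothing constants for the continuation.
#' @return object of class `ranksvm_model`: weight vector `w` (named by
#'   feature columns), `C`, exact `objective`, and a `convergence` record.
#' @export
train_ranksvm <- function(X, pairs, C = 1, maxit = 200L,
                          deltas = c(0.1, 0.005, 5e-4, 5e-5)) {
  stopifnot(inherits(pairs, "pair_set"))
  if (pairs$m < 1L) stop("train_ranksvm: no training pairs")
  if (C <= 0) stop("train_ranksvm: C must be > 0")
  if (!inherits(X, "Matrix")) X <- as.matrix(X)
  m <- pairs$m
  pi <- pairs$i; pj <- pairs$j
  n <- nrow(X)

  cache <- new.env(parent = emptyenv())
  fngr <- function(w, delta) {
    last_w <- get0("w", envir = cache, inherits = FALSE)
    last_d <- get0("delta", envir = cache, inherits = FALSE)
    if (!is.null(last_w) && identical(last_w, w) && identical(last_d, delta)) {
      return(list(f = get("f", envir = cache), g = get("g", envir = cache)))
    }
    s <- as.numeric(X %*% w)
    t <- 1 - (s[pi] - s[pj])
    f <- 0.5 * sum(w^2) + (C / m) * sum(.huber_hinge(t, delta))
    dh <- .huber_hinge_d(t, delta)
    # accumulate -dh at i and +dh at j, then one crossprod with X
    acc <- rowsum(c(-dh, dh), c(pi, pj))
    a <- numeric(n)
    a[as.integer(rownames(acc))] <- acc[, 1L]
    g <- w + (C / m) * as.numeric(Matrix::crossprod(X, a))
    assign("w", w, envir = cache)
    assign("delta", delta, envir = cache)
    assign("f", f, envir = cache)
    assign("g", g, envir = cache)
    list(f = f, g = g)
  }

  w <- numeric(ncol(X))
  conv <- list()
  for (delta in deltas) {
    res <- stats::optim(w,
                        fn = function(w) fngr(w, delta)$f,
                        gr = function(w) fngr(w, delta)$g,
                        method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 1e7))
    w <- res$par
    conv[[as.character(delta)]] <- res$convergence
  }
  names(w) <- colnames(X)
  structure(list(w = w, C = C,
                 objective = ranksvm_objective(w, X, pairs, C),
                 convergence = conv, feature_names = colnames(X)),
            class = "ranksvm_model")
}

#' @export
print.ranksvm_model <- function(x, ...) {
  cat("<ranksvm_model>", length(x$w), "features, C =", x$C,
      "- objective", format(x$objective, digits = 6), "\n")
  invisible(x)
}

#' Train the random-forest baseline
#'
#' A probability forest (per-tree predictions are the positive-class
#' fractions of the assigned leaves; the forest score is their average over
#' the B trees). B is chosen from `B_grid` by minimum out-of-bag error,
#' ties going to the smaller B; other hyperparameters stay at the library
#' defaults.
#'
#' @param X numeric feature matrix.
#' @param labels integer labels in `{0, 1}`; both classes must be present.
#' @param B_grid candidate numbers of trees.
#' @param seed integer seed (forest growth is deterministic given it).
#' @return object of class `rf_model` with the fitted forest, the chosen
#'   `B` and the per-B out-of-bag errors.
#' @export
train_rf <- function(X, labels, B_grid = c(100L, 300L, 500L), seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("train_rf: labels must contain both classes")
  }
  X <- as.matrix(X)
  colnames(X) <- make.names(colnames(X), unique = TRUE)
  y <- factor(labels, levels = c(0L, 1L))
  oob <- vapply(B_grid, function(B) {
    fit <- ranger::ranger(x = X, y = y, num.trees = B, probability = TRUE,
                          seed = seed, num.threads = 1L)
    fit$prediction.error
  }, numeric(1))
  B <- B_grid[which.min(oob)]
  fit <- ranger::ranger(x = X, y = y, num.trees = B, probability = TRUE,
                        seed = seed, num.threads = 1L)
  structure(list(fit = fit, B = B, oob = stats::setNames(oob, B_grid),
                 seed = seed, feature_names = colnames(X)),
            class = "rf_model")
}

#' @export
print.rf_model <- function(x, ...) {
  cat("<rf_model> B =", x$B, "trees (OOB",
      format(min(x$oob), digits = 4), ")\n")
  invisible(x)
}

#' Score candidates with a trained ranker
#'
#' @param model a `ranksvm_model` or `rf_model`.
#' @param X feature matrix with the training column schema.
#' @return numeric score vector (linear score `w.x` for the SVM, averaged
#'   positive-class probability for the forest).
#' @export
score_candidates <- function(model, X) {
  if (inherits(model, "ranksvm_model")) {
    if (!identical(colnames(X), model$feature_names)) {
      stop("score_candidates: feature schema mismatch")
    }
    return(as.numeric(X %*% model$w))
  }
  if (inherits(model, "rf_model")) {
    X <- as.matrix(X)
    colnames(X) <- make.names(colnames(X), unique = TRUE)
    if (!identical(colnames(X), model$feature_names)) {
      stop("score_candidates: feature schema mismatch")
    }
    pr <- stats::predict(model$fit, data = as.data.frame(X),
                         num.threads = 1L)$predictions
    return(pr[, "1"])
  }
  stop("score_candidates: unknown model class")
}

#' Rank the candidates of each note by score
#'
#' Scores with [score_candidates()] and sorts within each note by
#' descending score; exact ties are broken by earlier first occurrence,
#' then lexicographic term order, so the output is deterministic and
#' invariant to the input row order.
#'
#' @param model a trained ranker.
#' @param candidates candidate data frame (needs `note_id`, `term`,
#'   `first_token_index`).
#' @param X feature matrix aligned with `candidates`.
#' @return data frame `note_id`, `rank`, `term`, `score`.
#' @export
score_and_rank <- function(model, candidates, X) {
  s <- score_candidates(model, X)
  out <- lapply(split(seq_len(nrow(candidates)), candidates$note_id),
                function(rows) {
    o <- rows[order(-s[rows], candidates$first_token_index[rows],
                    candidates$term[rows])]
    data.frame(note_id = candidates$note_id[o], rank = seq_along(o),
               term = candidates$term[o], score = s[o],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Select the rankSVM regularization constant by inner cross-validation
#'
#' Splits the training notes into inner folds, trains on each inner
#' training part for every grid value and keeps the C with the highest mean
#' per-note candidate AUC-ROC on the inner validation notes; ties go to the
#' smallest C.
#'
#' @param candidates labeled training candidates.
#' @param X training feature matrix aligned with `candidates`.
#' @param grid candidate C values (nonempty).
#' @param folds inner fold count (>= 2).
#' @param seed integer seed for the inner split.
#' @return the selected C.
#' @export
select_C <- function(candidates, X, grid = c(0.01, 0.1, 1, 10, 100),
                     folds = 3L, seed = 1L) {
  stopifnot(length(grid) >= 1L)
  if (folds < 2L) stop("select_C: need folds >= 2")
  grid <- sort(grid)
  if (length(grid) == 1L) return(grid)
  ids <- unique(candidates$note_id)
  fold_of <- .make_folds(ids, min(folds, length(ids)), seed)
  perf <- sapply(grid, function(C) {
    aucs <- c()
    for (f in unique(fold_of)) {
      val_ids <- ids[fold_of == f]
      tr <- candidates$note_id %in% setdiff(ids, val_ids)
      pairs <- build_pairs(candidates$label[tr], candidates$note_id[tr])
      if (pairs$m == 0L) next
      model <- train_ranksvm(X[tr, , drop = FALSE], pairs, C = C)
      s <- as.numeric(X[!tr, , drop = FALSE] %*% model$w)
      lab <- candidates$label[!tr]
      nid <- candidates$note_id[!tr]
      for (id in val_ids) {
        a <- auc_ranking(s[nid == id], lab[nid == id])
        if (!is.na(a)) aucs <- c(aucs, a)
      }
    }
    if (!length(aucs)) return(NA_real_)
    mean(aucs)
  })
  if (all(is.na(perf))) return(grid[1L])
  grid[which.max(perf)]  # which.max takes the first (smallest C) on ties
}
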