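# Topic-coherence features. A small collapsed-Gibbs LDA sampler (in C++)
# provides the word-topic distributions; the package's own computation is
# the coherence of a candidate term with its note:
#   P(w|e) = sum_k P(w|topic_k) * P(topic_k|e)
#   P(t|e) = prod over words w of t of P(w|e)
# with out-of-vocabulary words floored at 1e-9 so the feature stays strictly
# inside (0, 1).

#' Train an LDA topic model on a background corpus
#'
#' Collapsed Gibbs sampling with symmetric priors (alpha = 50/K, beta =
#' 0.01, the usual defaults). Deterministic under `seed`. The reference
#' profile for this feature trains three models with K = 50, 100 and 200;
#' smaller K are appropriate for small corpora.
#'
#' @param background a `background_corpus`.
#' @param K number of topics (>= 1; must not exceed the vocabulary size).
#' @param seed integer seed.
#' @param n_iter Gibbs sweeps (default 200).
#' @param alpha,beta Dirichlet hyperparameters; `alpha = NULL` uses 50/K.
#' @return object of class `topic_model`: `K`, `vocabulary`, `word_topic`
#'   (K x V matrix, rows sum to 1), `theta` (training-document mixtures),
#'   `alpha`, `beta`, `seed`.
#' @export
train_topic_model <- function(background, K, seed = 1L, n_iter = 200L,
                              alpha = NULL, beta = 0.01) {
  stopifnot(inherits(background, "background_corpus"), K >= 1L)
  vocab <- sort(unique(unlist(background$documents, use.names = FALSE)))
  if (K > length(vocab)) stop("train_topic_model: K exceeds vocabulary size")
  if (is.null(alpha)) alpha <- 50 / K
  ids <- lapply(background$documents, function(d) match(d, vocab) - 1L)
  set.seed(seed)
  fit <- lda_gibbs_fit(ids, length(vocab), as.integer(K), alpha, beta,
                       as.integer(n_iter))
  phi <- fit$phi
  colnames(phi) <- vocab
  structure(list(K = as.integer(K), vocabulary = vocab, word_topic = phi,
                 theta = fit$theta, alpha = alpha, beta = beta,
                 seed = as.integer(seed), n_iter = as.integer(n_iter)),
            class = "topic_model")
}

#' @export
print.topic_model <- function(x, ...) {
  cat("<topic_model> K =", x$K, "-", length(x$vocabulary), "word vocabulary\n")
  invisible(x)
}

#' Infer the topic mixture of a new document
#'
#' Fold-in Gibbs sampling with the word-topic matrix held fixed; words
#' outside the model vocabulary are dropped. Deterministic under `seed`.
#'
#' @param model a `topic_model`.
#' @param stems stemmed token vector of the document.
#' @param n_iter sweeps (default 100).
#' @param seed optional integer seed set before sampling.
#' @return numeric topic mixture of length `K`, summing to 1.
#' @export
infer_topics <- function(model, stems, n_iter = 100L, seed = NULL) {
  ids <- match(stems, model$vocabulary) - 1L
  ids <- ids[!is.na(ids)]
  if (!is.null(seed)) set.seed(seed)
  as.numeric(lda_gibbs_infer(as.integer(ids), model$word_topic, model$alpha,
                             as.integer(n_iter)))
}

#' Probability of a word given a note's topic mixture
#'
#' `P(w|e) = sum_k P(w|topic_k) * theta_k`. Words outside the vocabulary get
#' the floor value 1e-9.
#'
#' @param model a `topic_model`.
#' @param word a single (stemmed) word.
#' @param theta topic mixture of the note, length `K`, summing to 1.
#' @return probability in `[0, 1]`.
#' @export
word_prob_given_doc <- function(model, word, theta) {
  if (length(theta) != model$K) {
    stop("word_prob_given_doc: theta length must equal K")
  }
  j <- match(word, model$vocabulary)
  if (is.na(j)) return(1e-9)
  sum(model$word_topic[, j] * theta)
}

#' Topic-coherence feature of a candidate term
#'
#' `P(t|e)`: the product over the term's words of `P(w|e)` (word
#' independence), or their geometric mean with `combine = "geometric"`,
#' which removes the penalty on longer terms. Strictly inside (0, 1) thanks
#' to the out-of-vocabulary floor.
#'
#' @param model a `topic_model`.
#' @param words stemmed words of the term (nonempty).
#' @param theta topic mixture of the note.
#' @param combine `"product"` (default) or `"geometric"`.
#' @return numeric scalar in (0, 1).
#' @export
topic_feature <- function(model, words, theta,
                          combine = c("product", "geometric")) {
  combine <- match.arg(combine)
  if (!length(words)) stop("topic_feature: empty term")
  p <- vapply(words, word_prob_given_doc, numeric(1), model = model,
              theta = theta)
  p <- pmax(p, 1e-9)
  if (combine == "product") prod(p) else exp(mean(log(p)))
}

#' Compute per-note topic mixtures for a list of topic models
#'
#' Convenience wrapper used by feature assembly: for every model, a matrix
#' of inferred mixtures with one row per note.
#'
#' @param notes named list of `note` objects.
#' @param models list of `topic_model`s.
#' @param seed integer seed (one deterministic stream per model/note).
#' @param n_iter fold-in sweeps per note.
#' @return list of matrices, one per model, rownames = note ids.
#' @export
compute_note_topics <- function(notes, models, seed = 1L, n_iter = 100L) {
  lapply(seq_along(models), function(mi) {
    model <- models[[mi]]
    th <- t(vapply(seq_along(notes), function(i) {
      infer_topics(model, notes[[i]]$tokens$stem, n_iter = n_iter,
                   seed = seed + mi * 10000L + i)
    }, numeric(model$K)))
    rownames(th) <- names(notes)
    th
  })
}

#' Save a topic model as plain text
#'
#' Writes the dense word-topic matrix as TSV, the vocabulary as one word per
#' line, and a YAML sidecar with K, priors and seed.
#'
#' @param model a `topic_model`.
#' @param prefix path prefix; files `<prefix>.word_topic.tsv`,
#'   `<prefix>.vocab.txt` and `<prefix>.meta.yaml` are produced.
#' @return `prefix`, invisibly.
#' @export
save_topic_model <- function(model, prefix) {
  utils::write.table(model$word_topic, paste0(prefix, ".word_topic.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(model$vocabulary, paste0(prefix, ".vocab.txt"))
  yaml::write_yaml(list(K = model$K, alpha = model$alpha, beta = model$beta,
                        seed = model$seed, n_iter = model$n_iter),
                   paste0(prefix, ".meta.yaml"))
  invisible(prefix)
}

#' Load a topic model saved by [save_topic_model()]
#'
#' @param prefix path prefix used when saving.
#' @return a `topic_model` (without training-document mixtures).
#' @export
load_topic_model <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".meta.yaml"))
  vocab <- readLines(paste0(prefix, ".vocab.txt"))
  phi <- as.matrix(utils::read.delim(paste0(prefix, ".word_topic.tsv"),
                                     check.names = FALSE))
  colnames(phi) <- vocab
  structure(list(K = meta$K, vocabulary = vocab, word_topic = phi,
                 theta = NULL, alpha = meta$alpha, beta = meta$beta,
                 seed = meta$seed, n_iter = meta$n_iter),
            class = "topic_model")
}
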