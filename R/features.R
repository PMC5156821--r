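# Feature engineering for candidate ranking.
#
# Baseline block (9 features): term frequency, inverse document frequency,
# TF-IDF; term length in words (TL), longest word length in characters
# (maxWL), their combination TL x maxWL; normalized first-occurrence
# position; a lexical identity feature (one-hot, rare terms pooled); the
# part-of-speech tag of the head word (one-hot). Additional blocks: averaged
# word embedding (min-max normalized per dimension), semantic-type one-hot,
# 7 binary consumer-health-vocabulary features, and topic-coherence features
# (one per topic model).

#' Build a background corpus for document-frequency statistics
#'
#' Runs candidate extraction over a collection of background documents and
#' tabulates, for every canonical term, the number of documents containing
#' it. The stemmed token streams are kept for topic-model training.
#'
#' @param notes list of `note` objects (the background collection).
#' @param lexicon a `lexicon`.
#' @return object of class `background_corpus` with fields `N` (document
#'   count), `document_frequency` (named integer vector over canonical
#'   terms) and `documents` (list of stemmed token vectors).
#' @export
background_corpus <- function(notes, lexicon) {
  stopifnot(length(notes) >= 1L)
  per_doc <- lapply(notes, function(nt) unique(extract_candidates(nt, lexicon)$term))
  df <- table(unlist(per_doc, use.names = FALSE))
  docs <- lapply(notes, function(nt) nt$tokens$stem)
  structure(list(N = length(notes),
                 document_frequency = stats::setNames(as.integer(df), names(df)),
                 documents = docs),
            class = "background_corpus")
}

#' @export
print.background_corpus <- function(x, ...) {
  cat("<background_corpus>", x$N, "documents,",
      length(x$document_frequency), "terms with df > 0\n")
  invisible(x)
}

#' Smoothed inverse document frequency
#'
#' `idf = ln((N + 1) / (df + 1))`; the add-one smoothing keeps terms absent
#' from the background finite.
#'
#' @param background a `background_corpus`.
#' @param term character vector of canonical terms.
#' @return numeric vector of idf values.
#' @export
idf <- function(background, term) {
  df <- background$document_frequency[term]
  df[is.na(df)] <- 0L
  unname(log((background$N + 1) / (df + 1)))
}

#' Frequency-based features
#'
#' Term frequency is the candidate's occurrence count in its note; idf comes
#' from the background corpus; tfidf is their product.
#'
#' @param candidates candidate data frame (needs `term`, `n_occurrences`).
#' @param background a `background_corpus`.
#' @return data frame with columns `tf`, `idf`, `tfidf`.
#' @export
frequency_features <- function(candidates, background) {
  tf <- candidates$n_occurrences
  iv <- idf(background, candidates$term)
  data.frame(tf = tf, idf = iv, tfidf = tf * iv)
}

#' Term-structure features
#'
#' TL = number of words; maxWL = character length of the longest word;
#' `combined = TL * maxWL`, monotone in both, reflecting that longer terms
#' and longer words are less likely to be familiar.
#'
#' @param terms character vector of candidate terms.
#' @return data frame with columns `tl`, `maxwl`, `combined`.
#' @export
length_features <- function(terms) {
  toks <- lapply(terms, .term_words)
  tl <- lengths(toks)
  if (any(tl == 0L)) stop("length_features: empty term")
  maxwl <- vapply(toks, function(w) max(nchar(w)), integer(1))
  data.frame(tl = tl, maxwl = maxwl, combined = tl * maxwl)
}

#' Position feature
#'
#' Number of words preceding the first occurrence of the candidate, divided
#' by the note's word count; 0 for a term starting the note, approaching 1 at
#' the end.
#'
#' @param first_token_index 0-based index of the first token of the first
#'   occurrence.
#' @param word_count note word count (> 0).
#' @return numeric vector in `[0, 1)`.
#' @export
position_feature <- function(first_token_index, word_count) {
  if (any(word_count == 0)) stop("position_feature: empty note")
  first_token_index / word_count
}

#' Lexical vocabulary from training data
#'
#' The lexical feature keeps a stemmed term identity only if it occurs at
#' least `min_count` times in the training data (candidate rows in the
#' training folds); rarer terms are pooled into a `"RARE"` sentinel. This
#' guards against misspellings in noisy clinical text and against train/test
#' leakage, since the vocabulary depends on the training folds only.
#'
#' @param train_keys stemmed term keys of the training candidates.
#' @param min_count minimum training count (default 3).
#' @return character vector of retained keys.
#' @export
build_lexical_vocab <- function(train_keys, min_count = 3L) {
  tab <- table(train_keys)
  names(tab)[tab >= min_count]
}

#' Lexical identity feature
#'
#' @param keys stemmed term keys of candidates.
#' @param vocab vocabulary from [build_lexical_vocab()].
#' @return character vector: the key itself when in vocabulary, else
#'   `"RARE"`.
#' @export
lexical_feature <- function(keys, vocab) {
  ifelse(keys %in% vocab, keys, "RARE")
}

#' Heuristic part-of-speech tag for a single word
#'
#' A deterministic suffix-based tagger covering the coarse distinctions the
#' head-word feature needs: `CD` for numerals, `VBG`/`VBD` for -ing/-ed
#' forms, `RB` for -ly adverbs, `JJ` for common adjectival suffixes, `NN`
#' otherwise; anything untaggable (empty or non-alphanumeric) gets `"UNK"`.
#'
#' @param word character vector of words.
#' @return character vector of tags.
#' @export
pos_tag <- function(word) {
  vapply(word, function(w) {
    w <- tolower(w)
    if (is.na(w) || !nzchar(w) || !grepl("^[a-z0-9]+$", w)) return("UNK")
    if (grepl("^[0-9]+$", w)) return("CD")
    if (nchar(w) > 4L && endsWith(w, "ing")) return("VBG")
    if (nchar(w) > 3L && endsWith(w, "ed")) return("VBD")
    if (nchar(w) > 3L && endsWith(w, "ly")) return("RB")
    if (nchar(w) > 4L &&
        (endsWith(w, "ous") || endsWith(w, "ful") || endsWith(w, "ive") ||
         endsWith(w, "ic") || endsWith(w, "al"))) return("JJ")
    "NN"
  }, character(1), USE.NAMES = FALSE)
}

#' Part-of-speech feature of a candidate's head word
#'
#' English noun phrases are right-headed, so the head is taken to be the
#' final word of the term.
#'
#' @param terms character vector of candidate terms.
#' @return character vector of POS tags (`"UNK"` on tagging failure).
#' @export
pos_feature <- function(terms) {
  vapply(terms, function(t) {
    w <- .term_words(t)
    if (!length(w)) return("UNK")
    pos_tag(w[length(w)])
  }, character(1), USE.NAMES = FALSE)
}

#' Load a word-embedding table in word2vec text format
#'
#' First line `V d`, then one word and `d` floats per line. Per-dimension
#' minima and maxima over the whole vocabulary are computed at load time and
#' reused for min-max normalization of every phrase vector.
#'
#' @param path file path.
#' @return object of class `embedding_table` with fields `vectors`
#'   (V x d matrix with word rownames), `d`, `mins`, `maxs`.
#' @export
load_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  hd <- scan(text = lines[1L], what = integer(), quiet = TRUE)
  if (length(hd) != 2L) stop("load_embeddings: bad header")
  V <- hd[1L]; d <- hd[2L]
  parts <- strsplit(lines[-1L][seq_len(V)], " ", fixed = TRUE)
  words <- vapply(parts, `[[`, character(1), 1L)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(d)))
  rownames(mat) <- words
  new_embedding_table(mat)
}

#' Construct an embedding table from a matrix
#'
#' @param mat numeric matrix, one row per word, with word rownames.
#' @return an `embedding_table`.
#' @export
new_embedding_table <- function(mat) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  structure(list(vectors = mat, d = ncol(mat),
                 mins = apply(mat, 2L, min), maxs = apply(mat, 2L, max)),
            class = "embedding_table")
}

#' Write an embedding table in word2vec text format
#'
#' @param table an `embedding_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(table$vectors), table$d), con)
  writeLines(paste(rownames(table$vectors),
                   apply(table$vectors, 1L, function(v)
                     paste(format(v, digits = 8, trim = TRUE), collapse = " "))),
             con)
  invisible(path)
}

#' Word-embedding feature of a multi-word term
#'
#' The mean of the member words' vectors (words missing from the table are
#' skipped), then rescaled per dimension to `[0, 1]` with the min-max bounds
#' computed over the table's whole vocabulary. A term with no in-vocabulary
#' word maps to the neutral all-0.5 vector.
#'
#' @param words lowercased words of the term.
#' @param table an `embedding_table`.
#' @param d expected dimension (error on mismatch); default is the table's.
#' @return numeric vector of length `d` with values in `[0, 1]`.
#' @export
embedding_feature <- function(words, table, d = table$d) {
  if (d != table$d) stop("embedding_feature: dimension mismatch")
  hit <- words[words %in% rownames(table$vectors)]
  if (!length(hit)) return(rep(0.5, d))
  v <- colMeans(table$vectors[hit, , drop = FALSE])
  rng <- table$maxs - table$mins
  out <- ifelse(rng > 0, (v - table$mins) / rng, 0.5)
  pmin(pmax(out, 0), 1)
}

#' Semantic-type one-hot feature
#'
#' @param type semantic type of a candidate.
#' @param types the declared closed type set.
#' @return 0/1 vector over `types`, summing to exactly 1.
#' @export
semantic_type_feature <- function(type, types = default_semantic_types()) {
  if (!type %in% types) stop("semantic_type_feature: unknown type '", type, "'")
  as.numeric(types == type)
}

#' The 7 consumer-health-vocabulary features
#'
#' `[in_chv, bin1..bin5, has_score]`: CHV membership; five equal-range
#' familiarity bins over `[0, 0.2), [0.2, 0.4), [0.4, 0.6), [0.6, 0.8),
#' [0.8, 1.0]` (half-open below, the top bin closed); and whether a
#' familiarity score exists at all. At most one bin is active; a missing
#' familiarity zeroes all bins and `has_score`.
#'
#' @param in_chv logical CHV membership.
#' @param familiarity numeric in `[0, 1]` or `NA`.
#' @return named numeric vector of length 7 with values in `{0, 1}`.
#' @export
chv_features <- function(in_chv, familiarity) {
  bins <- numeric(5)
  has <- 0
  if (!is.na(familiarity)) {
    b <- min(floor(familiarity / 0.2) + 1, 5)
    bins[b] <- 1
    has <- 1
  }
  c(in_chv = as.numeric(in_chv),
    stats::setNames(bins, paste0("fam_bin", 1:5)),
    has_score = has)
}

#' Column scaling fitted on training data
#'
#' Computes per-column maximum absolute values. Dividing by them puts all
#' feature blocks on a comparable scale for margin-based training without
#' shifting zeros (sparsity is preserved). Constant-zero columns get scale 1.
#'
#' @param X training feature matrix.
#' @return named numeric vector of column scales.
#' @export
feature_scaling <- function(X) {
  if (inherits(X, "dgCMatrix")) {
    nc <- ncol(X)
    m <- numeric(nc)
    xp <- X@p
    ax <- abs(X@x)
    for (j in seq_len(nc)) {
      if (xp[j + 1L] > xp[j]) m[j] <- max(ax[(xp[j] + 1L):xp[j + 1L]])
    }
    names(m) <- colnames(X)
  } else {
    m <- apply(abs(X), 2L, max)
  }
  m[m == 0] <- 1
  m
}

#' Apply a fitted column scaling
#'
#' @param X feature matrix with the same columns as the training matrix.
#' @param scales result of [feature_scaling()].
#' @return rescaled matrix.
#' @export
apply_scaling <- function(X, scales) {
  stopifnot(identical(colnames(X), names(scales)))
  out <- X %*% Matrix::Diagonal(x = 1 / scales)
  colnames(out) <- colnames(X)
  out
}

#' Feature configuration
#'
#' Selects the feature blocks to assemble and their tuning constants.
#'
#' @param blocks subset of `c("baseline", "embedding", "semantic_type",
#'   "chv", "topic")`.
#' @param min_count lexical-feature minimum training count (default 3).
#' @param topic_combine how the topic feature combines word probabilities:
#'   `"product"` (default) or `"geometric"` mean, which removes the
#'   term-length bias of the raw product.
#' @return object of class `feature_config`.
#' @export
feature_config <- function(blocks = c("baseline", "embedding",
                                      "semantic_type", "chv", "topic"),
                           min_count = 3L,
                           topic_combine = c("product", "geometric")) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  stopifnot(min_count >= 1L)
  structure(list(blocks = blocks, min_count = as.integer(min_count),
                 topic_combine = match.arg(topic_combine)),
            class = "feature_config")
}

#' Training-fold feature schema
#'
#' Fixes every category set that a one-hot encoding needs — the lexical
#' vocabulary and the observed POS tag set — on training data only, so
#' assembling test rows can never leak test statistics.
#'
#' @param train_candidates labeled candidates of the training folds.
#' @param config a [feature_config()].
#' @param semantic_types the closed semantic type set.
#' @return list with `lexical_levels`, `pos_levels`, `semantic_types`.
#' @export
feature_schema <- function(train_candidates, config,
                           semantic_types = default_semantic_types()) {
  keys <- vapply(train_candidates$term,
                 function(t) paste(.norm_tokens(t), collapse = " "),
                 character(1), USE.NAMES = FALSE)
  vocab <- build_lexical_vocab(keys, config$min_count)
  tags <- sort(unique(c(pos_feature(unique(train_candidates$term)), "UNK")))
  list(lexical_levels = c(sort(vocab), "RARE"), pos_levels = tags,
       semantic_types = semantic_types)
}

.one_hot <- function(values, levels) {
  m <- matrix(0, length(values), length(levels),
              dimnames = list(NULL, levels))
  j <- match(values, levels)
  ok <- !is.na(j)
  m[cbind(which(ok), j[ok])] <- 1
  m
}

# sparse one-hot; wide categorical blocks (lexical identity) dominate the
# feature width, so the assembled matrix is kept sparse end to end
.one_hot_sparse <- function(values, levels, prefix = "") {
  j <- match(values, levels)
  ok <- which(!is.na(j))
  Matrix::sparseMatrix(i = ok, j = j[ok], x = 1,
                       dims = c(length(values), length(levels)),
                       dimnames = list(NULL, paste0(prefix, levels)))
}

#' Assemble the feature matrix for a set of candidates
#'
#' Produces one row per candidate with a stable column order: the baseline
#' block (tf, idf, tfidf, tl, maxwl, tl_maxwl, position, lexical one-hot,
#' POS one-hot), then — when enabled — the embedding block, the
#' semantic-type one-hot, the 7 CHV features and one topic-coherence feature
#' per topic model. Categorical encodings use the training-fold `schema`;
#' unseen lexical identities fall into `RARE` and unseen tags into `UNK`.
#'
#' @param candidates labeled candidate data frame (possibly several notes).
#' @param notes named list of `note` objects covering `candidates$note_id`.
#' @param resources list with elements `background` (a `background_corpus`),
#'   `embeddings` (an `embedding_table`), `topic_models` (list of
#'   `topic_model`s) and `note_topics` (list, one matrix of per-note topic
#'   mixtures per model, rownames = note ids), as required by the enabled
#'   blocks.
#' @param config a [feature_config()].
#' @param schema a [feature_schema()].
#' @return a sparse numeric matrix (`dgCMatrix`) with named columns, rows
#'   aligned to `candidates`. Term-level features are computed once per
#'   unique term and broadcast, so repeated assembly across folds stays
#'   cheap.
#' @export
assemble_features <- function(candidates, notes, resources, config, schema) {
  n <- nrow(candidates)
  uterm <- unique(candidates$term)
  row_of <- match(candidates$term, uterm)
  blocks <- list()
  need <- function(what) {
    if (is.null(resources[[what]])) {
      stop("assemble_features: resource '", what, "' required by config")
    }
    resources[[what]]
  }
  dense <- function(m) Matrix::Matrix(m, sparse = TRUE)

  if ("baseline" %in% config$blocks) {
    bg <- need("background")
    fr <- frequency_features(candidates, bg)
    ln_u <- length_features(uterm)
    wc <- vapply(candidates$note_id,
                 function(id) notes[[id]]$word_count, numeric(1))
    pos <- position_feature(candidates$first_token_index, wc)
    keys_u <- vapply(uterm, function(t) paste(.norm_tokens(t), collapse = " "),
                     character(1), USE.NAMES = FALSE)
    lex <- .one_hot_sparse(lexical_feature(keys_u, schema$lexical_levels)[row_of],
                           schema$lexical_levels, "lex_")
    tag_u <- pos_feature(uterm)
    tag_u[!tag_u %in% schema$pos_levels] <- "UNK"
    pm <- .one_hot_sparse(tag_u[row_of], schema$pos_levels, "pos_")
    base <- cbind(tf = fr$tf, idf = fr$idf, tfidf = fr$tfidf,
                  tl = ln_u$tl[row_of], maxwl = ln_u$maxwl[row_of],
                  tl_maxwl = ln_u$combined[row_of], position = pos)
    blocks$baseline <- cbind(dense(base), lex, pm)
  }

  if ("embedding" %in% config$blocks) {
    tab <- need("embeddings")
    emb_u <- t(vapply(uterm, function(t) {
      embedding_feature(.term_words(t), tab)
    }, numeric(tab$d)))
    emb <- emb_u[row_of, , drop = FALSE]
    dimnames(emb) <- list(NULL, paste0("emb_", seq_len(tab$d)))
    blocks$embedding <- dense(emb)
  }

  if ("semantic_type" %in% config$blocks) {
    st <- .one_hot_sparse(candidates$semantic_type, schema$semantic_types,
                          "st_")
    if (any(Matrix::rowSums(st) != 1)) {
      stop("assemble_features: candidate with unknown semantic type")
    }
    colnames(st) <- gsub("[^A-Za-z_]+", "_", colnames(st))
    blocks$semantic_type <- st
  }

  if ("chv" %in% config$blocks) {
    chv <- t(mapply(chv_features, candidates$in_chv, candidates$familiarity))
    rownames(chv) <- NULL
    blocks$chv <- dense(chv)
  }

  if ("topic" %in% config$blocks) {
    models <- need("topic_models")
    thetas <- need("note_topics")
    stems_u <- lapply(uterm, .norm_tokens)
    tms <- lapply(seq_along(models), function(mi) {
      model <- models[[mi]]
      th <- thetas[[mi]]
      out <- numeric(n)
      for (id in unique(candidates$note_id)) {
        rows <- which(candidates$note_id == id)
        pwe <- as.vector(th[id, ] %*% model$word_topic)
        names(pwe) <- model$vocabulary
        vals <- vapply(stems_u[row_of[rows]], function(ws) {
          p <- pwe[ws]
          p[is.na(p)] <- 1e-9
          p <- pmax(p, 1e-9)
          if (config$topic_combine == "product") prod(p)
          else exp(mean(log(p)))
        }, numeric(1))
        out[rows] <- vals
      }
      out
    })
    tm <- do.call(cbind, tms)
    colnames(tm) <- paste0("topic_K", vapply(models, `[[`, numeric(1), "K"))
    blocks$topic <- dense(tm)
  }

  X <- do.call(cbind, blocks)
  rownames(X) <- NULL
  X
}
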