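make_bg <- function(N, df_counts) {
  structure(list(N = N, document_frequency = df_counts, documents = list()),
            class = "background_corpus")
}

test_that("idf is smoothed and monotone decreasing in df", {
  bg <- make_bg(99L, c(common = 24L))
  expect_equal(idf(bg, "common"), log(100 / 25))
  expect_equal(idf(bg, "unseen"), log(100))
  dfs <- c(a = 1L, b = 5L, c = 50L)
  bg2 <- make_bg(99L, dfs)
  vals <- idf(bg2, names(dfs))
  expect_true(all(diff(vals) < 0))
})

test_that("tfidf is exactly tf * idf", {
  bg <- make_bg(99L, c(`crohn disease` = 24L))
  cand <- data.frame(term = c("crohn disease", "novel"),
                     n_occurrences = c(4L, 2L))
  fr <- frequency_features(cand, bg)
  expect_equal(fr$tfidf, fr$tf * fr$idf)
  expect_equal(fr$tf, c(4L, 2L))
})

test_that("term-structure features count words and characters", {
  lf <- length_features(c("diabetes mellitus", "pain",
                          "autologous stem cell transplant"))
  expect_equal(lf$tl, c(2L, 1L, 4L))
  expect_equal(lf$maxwl, c(8L, 4L, 10L))
  expect_equal(lf$combined, lf$tl * lf$maxwl)
  expect_equal(lf$combined[1L], 16)
})

test_that("position feature is the normalized first-occurrence offset", {
  expect_equal(position_feature(0L, 100L), 0)
  expect_equal(position_feature(50L, 100L), 0.5)
  expect_equal(position_feature(199L, 200L), 0.995)
  expect_error(position_feature(0L, 0L), "empty")
})

test_that("lexical feature pools rare terms below the training threshold", {
  vocab <- build_lexical_vocab(c(rep("metformin", 5), rep("rare term", 2),
                                 rep("warfarin", 3)))
  expect_setequal(vocab, c("metformin", "warfarin"))
  expect_identical(lexical_feature(c("metformin", "rare term", "unseen"), vocab),
                   c("metformin", "RARE", "RARE"))
})

test_that("POS feature tags the head (final) word", {
  expect_identical(pos_feature("thyroid ultrasound"), "NN")
  expect_identical(pos_feature("dialysis"), "NN")
  expect_identical(pos_tag("quickly"), "RB")
  expect_identical(pos_tag(""), "UNK")
})

test_that("embedding feature averages then min-max rescales", {
  mat <- rbind(alpha = c(0.2, 0.4), beta = c(0.6, 0.8),
               lo = c(0, 0), hi = c(1, 1))
  tab <- new_embedding_table(mat)
  # mean of (0.2,0.4) and (0.6,0.8) is (0.4,0.6); bounds are [0,1] per dim
  expect_equal(embedding_feature(c("alpha", "beta"), tab), c(0.4, 0.6))
  # the vocabulary minimum maps to all zeros
  expect_equal(embedding_feature("lo", tab), c(0, 0))
  # all words out of vocabulary -> neutral 0.5 vector
  expect_equal(embedding_feature(c("none", "here"), tab), c(0.5, 0.5))
  expect_error(embedding_feature("alpha", tab, d = 5L), "mismatch")
})

test_that("embedding table round-trips through word2vec text format", {
  w <- small_world()
  f <- withr::local_tempfile(fileext = ".txt")
  write_embeddings(w$embeddings, f)
  tab2 <- load_embeddings(f)
  expect_equal(dim(tab2$vectors), dim(w$embeddings$vectors))
  expect_equal(tab2$vectors, w$embeddings$vectors, tolerance = 1e-6)
})

test_that("semantic-type one-hot has exactly one active slot", {
  v <- semantic_type_feature("Organic chemical")
  expect_equal(sum(v), 1)
  expect_equal(which(v == 1),
               which(default_semantic_types() == "Organic chemical"))
  expect_equal(sum(semantic_type_feature("Therapeutic or preventive procedure")), 1)
  expect_error(semantic_type_feature("Martian"), "unknown")
})

test_that("CHV features follow the half-open bin convention", {
  v <- chv_features(TRUE, 0.95)
  expect_equal(unname(v), c(1, 0, 0, 0, 0, 1, 1))
  v2 <- chv_features(TRUE, 0.2)  # boundary falls into the second bin
  expect_equal(unname(v2), c(1, 0, 1, 0, 0, 0, 1))
  v3 <- chv_features(TRUE, NA)
  expect_equal(unname(v3), c(1, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(chv_features(FALSE, NA)), rep(0, 7))
  # at most one bin active, always
  for (f in c(0, 0.1, 0.39, 0.6, 0.8, 1)) {
    expect_lte(sum(chv_features(TRUE, f)[2:6]), 1)
  }
})

test_that("assembled matrix has the documented block structure", {
  w <- small_world()
  lab <- label_corpus(w$corpus$notes, w$corpus$gold, w$lexicon)
  cand <- lab$candidates
  tm <- train_topic_model(w$background, K = 3L, seed = 1L, n_iter = 50L)
  nth <- compute_note_topics(w$corpus$notes, list(tm), seed = 2L,
                             n_iter = 30L)
  res <- list(background = w$background, embeddings = w$embeddings,
              topic_models = list(tm), note_topics = nth)

  cfg_base <- feature_config(blocks = "baseline")
  sch <- feature_schema(cand, cfg_base, w$lexicon$semantic_types)
  Xb <- assemble_features(cand, w$corpus$notes, res, cfg_base, sch)
  expect_equal(ncol(Xb), 7L + length(sch$lexical_levels) +
                 length(sch$pos_levels))

  cfg_full <- feature_config()
  schf <- feature_schema(cand, cfg_full, w$lexicon$semantic_types)
  Xf <- assemble_features(cand, w$corpus$notes, res, cfg_full, schf)
  expect_equal(ncol(Xf), ncol(Xb) + w$embeddings$d +
                 length(default_semantic_types()) + 7L + 1L)

  Xfd <- as.matrix(Xf)
  emb_cols <- grepl("^emb_", colnames(Xfd))
  expect_true(all(Xfd[, emb_cols] >= 0 & Xfd[, emb_cols] <= 1))
  st_cols <- grepl("^st_", colnames(Xfd))
  expect_true(all(rowSums(Xfd[, st_cols]) == 1))
  expect_true(all(rowSums(Xfd[, grepl("^fam_bin", colnames(Xfd))]) <= 1))
  expect_false(any(is.na(Xfd)))

  # missing resource for an enabled block is an error
  expect_error(assemble_features(cand, w$corpus$notes,
                                 list(background = w$background),
                                 cfg_full, schf), "resource")
})

test_that("one-hot schemas depend on the training folds only", {
  w <- small_world()
  lab <- label_corpus(w$corpus$notes, w$corpus$gold, w$lexicon)
  cand <- lab$candidates
  ids <- unique(cand$note_id)
  train <- cand[cand$note_id %in% ids[1:10], ]
  cfg <- feature_config(blocks = "baseline")
  s1 <- feature_schema(train, cfg, w$lexicon$semantic_types)
  s2 <- feature_schema(cand, cfg, w$lexicon$semantic_types)
  # the schema from a training subset ignores the held-out notes entirely
  s1b <- feature_schema(cand[cand$note_id %in% ids[1:10], ], cfg,
                        w$lexicon$semantic_types)
  expect_identical(s1, s1b)
  expect_false(identical(s1$lexical_levels, s2$lexical_levels))
})

test_that("identical candidates in two notes differ only in note-dependent columns", {
  lex <- tiny_lexicon()
  n1 <- make_note("n1", "metformin was continued for care")
  n2 <- make_note("n2", "the plan was to continue metformin")
  bg <- background_corpus(list(n1 = n1, n2 = n2), lex)
  cand <- rbind(extract_candidates(n1, lex), extract_candidates(n2, lex))
  cand$label <- 0L
  cfg <- feature_config(blocks = "baseline")
  sch <- feature_schema(cand, cfg, lex$semantic_types)
  X <- as.matrix(assemble_features(cand, list(n1 = n1, n2 = n2),
                                   list(background = bg), cfg, sch))
  same <- X[1L, ] == X[2L, ]
  expect_false(same[["position"]])
  expect_true(all(same[setdiff(names(same), "position")]))
})
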