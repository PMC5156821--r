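test_that("lexicon generation is deterministic and respects the profile", {
  p <- generator_profile(n_lexicon_terms = 300L)
  l1 <- generate_lexicon(p, seed = 8L)
  l2 <- generate_lexicon(p, seed = 8L)
  expect_identical(l1$entries, l2$entries)
  expect_equal(nrow(l1$entries), 300L)
  fam <- l1$entries$familiarity
  expect_true(all(is.na(fam) | (fam >= 0 & fam <= 1)))
  # familiarity only ever attaches to CHV members
  expect_true(all(l1$entries$in_chv[!is.na(fam)]))
  # type counts are consistent with the profile mixture
  counts <- table(factor(l1$entries$semantic_type,
                         levels = names(p$type_mixture)))
  expect_gt(chisq.test(counts, p = p$type_mixture)$p.value, 0.001)
})

test_that("background corpus supports document-frequency queries", {
  w <- small_world()
  bg <- w$background
  expect_equal(bg$N, 30L)
  expect_true(all(bg$document_frequency >= 1L))
  expect_true(all(bg$document_frequency <= bg$N))
  # df agrees with direct re-extraction on one document
  lexicon <- w$lexicon
  some_term <- names(bg$document_frequency)[1L]
  expect_true(is.finite(idf(bg, some_term)))
})

test_that("fitted topic structure beats a single-topic model on held-out text", {
  w <- small_world()
  kT <- w$profile$n_topics_true
  tm_k <- train_topic_model(w$background, K = kT, seed = 31L, n_iter = 150L)
  tm_1 <- train_topic_model(w$background, K = 1L, seed = 31L, n_iter = 20L)
  # mean held-out log P(w|e) under each model, on 5 fresh notes
  ll <- function(tm, note) {
    th <- infer_topics(tm, note$tokens$stem, seed = 77L)
    pwe <- as.vector(th %*% tm$word_topic)
    names(pwe) <- tm$vocabulary
    p <- pwe[note$tokens$stem]
    mean(log(pmax(p, 1e-12)), na.rm = TRUE)
  }
  gain <- vapply(w$corpus$notes[1:5], function(nt) {
    ll(tm_k, nt) - ll(tm_1, nt)
  }, numeric(1))
  expect_gt(mean(gain), 0)
})

test_that("every gold annotation is present in its note's text", {
  w <- small_world()
  for (id in names(w$corpus$gold)) {
    stems <- w$corpus$notes[[id]]$tokens$stem
    hay <- paste(stems, collapse = " ")
    for (g in w$corpus$gold[[id]]) {
      needle <- paste(.norm <- stem_word(tokenize(g)$word), collapse = " ")
      expect_true(grepl(needle, hay, fixed = TRUE),
                  info = paste(id, g))
    }
  }
})

test_that("gold counts respect the profile floor and corpus determinism", {
  w <- small_world()
  expect_true(all(lengths(w$corpus$gold) >= 1L))
  c2 <- generate_corpus(w$profile, w$lexicon, seed = 12L)
  expect_identical(vapply(c2$notes, `[[`, character(1), "text"),
                   vapply(w$corpus$notes, `[[`, character(1), "text"))
  expect_identical(c2$gold, w$corpus$gold)
})

test_that("a perfect extraction-recall profile yields no missed gold", {
  p <- generator_profile(n_notes = 6L, words_mean = 200, words_sd = 20,
                         words_min = 80L, cands_mean = 40, cands_sd = 5,
                         cands_min = 20L, gold_mean = 5, gold_sd = 1,
                         extraction_recall = 1.0, n_lexicon_terms = 200L)
  lex <- generate_lexicon(p, seed = 3L)
  corp <- generate_corpus(p, lex, seed = 4L)
  lab <- label_corpus(corp$notes, corp$gold, lex)
  expect_equal(sum(lab$missed), 0L)
  expect_equal(lab$extraction_recall, 1.0)
})

test_that("null importance coefficients give uniform-looking gold draws", {
  p <- generator_profile(n_notes = 20L, words_mean = 300, words_sd = 30,
                         words_min = 100L, cands_mean = 80, cands_sd = 5,
                         cands_min = 40L, gold_mean = 8, gold_sd = 1,
                         extraction_recall = 1.0, n_lexicon_terms = 300L,
                         beta_position = 0, beta_topic = 0, boost = 0,
                         type_effects = c(
                           "Disease or syndrome" = 0, "Organic chemical" = 0,
                           "Finding" = 0, "Neoplastic process" = 0,
                           "Therapeutic or preventive procedure" = 0,
                           "Amino acid, peptide, or protein" = 0,
                           "Pathologic function" = 0,
                           "Diagnostic procedure" = 0, "other" = 0),
                         fam_bin_effects = rep(0, 5))
  lex <- generate_lexicon(p, seed = 6L)
  corp <- generate_corpus(p, lex, seed = 7L)
  # under a flat eta, gold position should be uniform: mean ~ 0.5
  tr <- corp$truth
  mean_pos_gold <- mean(tr$position[tr$gold])
  expect_gt(mean_pos_gold, 0.4)
  expect_lt(mean_pos_gold, 0.6)
})

test_that("embeddings are reproducible and carry type signal when asked", {
  w <- small_world()
  e1 <- generate_embeddings(w$lexicon, d = 8L, seed = 14L)
  expect_identical(e1$vectors, w$embeddings$vectors)
  expect_equal(e1$d, 8L)
  # with signal, same-type words are closer than cross-type words
  lex <- w$lexicon
  e_sig <- generate_embeddings(lex, d = 16L, signal_strength = 3, seed = 2L)
  ent <- lex$entries
  one_word <- ent[!grepl(" ", ent$term), ]
  types <- names(sort(table(one_word$semantic_type), decreasing = TRUE))[1:2]
  w1 <- one_word$term[one_word$semantic_type == types[1L]][1:8]
  w2 <- one_word$term[one_word$semantic_type == types[2L]][1:8]
  v1 <- e_sig$vectors[w1, ]; v2 <- e_sig$vectors[w2, ]
  within <- mean(dist(v1)) + mean(dist(v2))
  between <- mean(as.matrix(dist(rbind(colMeans(v1) * 0 + v1, v2)))[1:8, 9:16])
  expect_lt(within / 2, between)
})
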