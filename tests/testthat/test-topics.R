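toy_background <- function(seed = 3L) {
  set.seed(seed)
  vocab <- c("alpha", "beta", "gamma", "delta", "epsilon")
  notes <- lapply(1:15, function(i) {
    make_note(paste0("d", i),
              paste(sample(vocab, 60, replace = TRUE,
                           prob = c(.35, .25, .2, .15, .05)),
                    collapse = " "))
  })
  names(notes) <- vapply(notes, `[[`, character(1), "note_id")
  lex <- as_lexicon(data.frame(term = "alpha", semantic_type = "other",
                               in_chv = TRUE, familiarity = NA))
  background_corpus(notes, lex)
}

test_that("K = 1 degenerates to the smoothed corpus unigram distribution", {
  bg <- toy_background()
  tm <- train_topic_model(bg, K = 1L, seed = 7L, n_iter = 20L)
  uni <- table(factor(unlist(bg$documents), levels = tm$vocabulary))
  expected <- (as.numeric(uni) + tm$beta) /
    (sum(uni) + length(tm$vocabulary) * tm$beta)
  expect_equal(as.numeric(tm$word_topic[1L, ]), expected, tolerance = 1e-12)
})

test_that("training is deterministic under a fixed seed and rows normalize", {
  bg <- toy_background()
  a <- train_topic_model(bg, K = 3L, seed = 9L, n_iter = 40L)
  b <- train_topic_model(bg, K = 3L, seed = 9L, n_iter = 40L)
  expect_identical(a$word_topic, b$word_topic)
  expect_equal(rowSums(a$word_topic), rep(1, 3L), tolerance = 1e-9)
  expect_error(train_topic_model(bg, K = 99L), "vocabulary")
})

test_that("word probability given a document mixes topic rows", {
  bg <- toy_background()
  tm <- train_topic_model(bg, K = 2L, seed = 1L, n_iter = 30L)
  # handcrafted two-topic model over the same vocabulary
  tm$word_topic[1L, ] <- c(0.2, 0.2, 0.2, 0.2, 0.2)
  tm$word_topic[2L, ] <- c(0.4, 0.3, 0.1, 0.1, 0.1)
  expect_equal(word_prob_given_doc(tm, "alpha", c(0.5, 0.5)), 0.3)
  expect_equal(word_prob_given_doc(tm, "alpha", c(1, 0)), 0.2)
  expect_equal(word_prob_given_doc(tm, "martian", c(0.5, 0.5)), 1e-9)
  expect_error(word_prob_given_doc(tm, "alpha", c(1, 0, 0)), "length")
  # P(.|e) is a distribution over the vocabulary
  theta <- c(0.3, 0.7)
  tot <- sum(vapply(tm$vocabulary, word_prob_given_doc, numeric(1),
                    model = tm, theta = theta))
  expect_equal(tot, 1, tolerance = 1e-6)
})

test_that("topic feature multiplies word probabilities", {
  bg <- toy_background()
  tm <- train_topic_model(bg, K = 2L, seed = 1L, n_iter = 30L)
  theta <- c(0.5, 0.5)
  p_alpha <- word_prob_given_doc(tm, "alpha", theta)
  p_beta <- word_prob_given_doc(tm, "beta", theta)
  expect_equal(topic_feature(tm, "alpha", theta), p_alpha)
  expect_equal(topic_feature(tm, c("alpha", "beta"), theta),
               p_alpha * p_beta)
  # order invariance and length monotonicity (all probabilities < 1)
  expect_equal(topic_feature(tm, c("beta", "alpha"), theta),
               topic_feature(tm, c("alpha", "beta"), theta))
  expect_lt(topic_feature(tm, c("alpha", "beta", "gamma"), theta),
            topic_feature(tm, c("alpha", "beta"), theta))
  # geometric variant removes the length penalty direction
  g2 <- topic_feature(tm, c("alpha", "alpha"), theta, combine = "geometric")
  expect_equal(g2, p_alpha)
  expect_error(topic_feature(tm, character(0), theta), "empty")
  v <- topic_feature(tm, c("martian", "alpha"), theta)
  expect_gt(v, 0); expect_lt(v, 1)
})

test_that("inference is deterministic and sums to one", {
  bg <- toy_background()
  tm <- train_topic_model(bg, K = 3L, seed = 2L, n_iter = 30L)
  th1 <- infer_topics(tm, c("alpha", "beta", "alpha"), seed = 5L)
  th2 <- infer_topics(tm, c("alpha", "beta", "alpha"), seed = 5L)
  expect_identical(th1, th2)
  expect_equal(sum(th1), 1, tolerance = 1e-9)
})

test_that("topic model files round-trip", {
  bg <- toy_background()
  tm <- train_topic_model(bg, K = 2L, seed = 4L, n_iter = 20L)
  prefix <- file.path(withr::local_tempdir(), "tm")
  save_topic_model(tm, prefix)
  tm2 <- load_topic_model(prefix)
  expect_equal(tm2$K, tm$K)
  expect_identical(tm2$vocabulary, tm$vocabulary)
  expect_equal(tm2$word_topic, tm$word_topic, tolerance = 1e-6)
})
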