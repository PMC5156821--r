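test_that("pair set enumerates within-note positive-negative pairs", {
  p <- build_pairs(c(1L, 1L, 0L, 0L, 0L), rep("a", 5))
  expect_equal(p$m, 6L)
  expect_true(all(c(1L, 2L) %in% p$i))
  # no positives -> no pairs; cross-note pairs never form
  p2 <- build_pairs(c(0L, 0L, 1L, 0L), c("a", "a", "b", "b"))
  expect_equal(p2$m, 1L)
  expect_equal(p2$i, 3L)
  expect_equal(p2$j, 4L)
  p3 <- build_pairs(c(0L, 0L), c("a", "a"))
  expect_equal(p3$m, 0L)
  # m equals the sum of per-note products
  lab <- c(1L, 0L, 0L, 1L, 1L, 0L)
  nid <- c("a", "a", "a", "b", "b", "b")
  expect_equal(build_pairs(lab, nid)$m, 1L * 2L + 2L * 1L)
})

test_that("separable 1-D problem attains the closed-form optimum", {
  # positives at x = 2, negatives at x = 0: minimize w^2/2 s.t. 2w >= 1,
  # optimum w = 0.5 with objective 0.125
  X <- matrix(c(2, 2, 0, 0, 0), ncol = 1, dimnames = list(NULL, "f"))
  pairs <- build_pairs(c(1L, 1L, 0L, 0L, 0L), rep("n", 5))
  m <- train_ranksvm(X, pairs, C = 1)
  expect_equal(m$objective, 0.125, tolerance = 0.01)
  expect_equal(unname(m$w), 0.5, tolerance = 0.02)
})

test_that("separable 2-D data is ranked without swapped pairs", {
  X <- rbind(matrix(rep(c(1, 0), 4), 4, byrow = TRUE),
             matrix(rep(c(0, 1), 4), 4, byrow = TRUE))
  colnames(X) <- c("a", "b")
  lab <- c(rep(1L, 4), rep(0L, 4))
  pairs <- build_pairs(lab, rep("n", 8))
  m <- train_ranksvm(X, pairs, C = 10)
  s <- drop(X %*% m$w)
  expect_equal(auc_ranking(s, lab), 1.0)
})

test_that("regularization dominates as C tends to zero", {
  set.seed(1)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  pairs <- build_pairs(rep(c(1L, 0L), 5), rep("n", 10))
  w_small <- train_ranksvm(X, pairs, C = 1e-6)$w
  expect_lt(sqrt(sum(w_small^2)), 1e-3)
  expect_error(train_ranksvm(X, build_pairs(rep(0L, 10), rep("n", 10)), C = 1),
               "no training pairs")
  expect_error(train_ranksvm(X, pairs, C = -1), "C must be")
})

test_that("ranking is invariant to positive rescaling of the weights", {
  set.seed(2)
  X <- matrix(rnorm(16), 8, 2, dimnames = list(NULL, c("a", "b")))
  cand <- data.frame(note_id = "n", term = letters[1:8],
                     first_token_index = 1:8, stringsAsFactors = FALSE)
  m <- list(w = c(a = 1.3, b = -0.4), C = 1, feature_names = c("a", "b"))
  class(m) <- "ranksvm_model"
  r1 <- score_and_rank(m, cand, X)
  m2 <- m; m2$w <- m$w * 7
  r2 <- score_and_rank(m2, cand, X)
  expect_identical(r1$term, r2$term)
})

test_that("ties break by position then term, independent of input order", {
  X <- matrix(0, 3, 1, dimnames = list(NULL, "f"))
  m <- structure(list(w = c(f = 1), feature_names = "f"),
                 class = "ranksvm_model")
  cand <- data.frame(note_id = "n", term = c("zeta", "beta", "alpha"),
                     first_token_index = c(3L, 40L, 3L),
                     stringsAsFactors = FALSE)
  r <- score_and_rank(m, cand, X)
  expect_identical(r$term, c("alpha", "zeta", "beta"))
  perm <- c(2L, 3L, 1L)
  r2 <- score_and_rank(m, cand[perm, ], X[perm, , drop = FALSE])
  expect_identical(r2$term, r$term)
  expect_error(score_candidates(m, matrix(0, 1, 1,
                                          dimnames = list(NULL, "g"))),
               "schema")
})

test_that("C selection honors the grid, ties and separable recovery", {
  set.seed(4)
  n_notes <- 6L
  cand <- do.call(rbind, lapply(seq_len(n_notes), function(i) {
    data.frame(note_id = paste0("n", i), term = paste0("t", 1:8),
               label = rep(c(1L, 0L), c(2, 6)),
               first_token_index = 1:8, stringsAsFactors = FALSE)
  }))
  X <- matrix(rnorm(nrow(cand)), ncol = 1, dimnames = list(NULL, "sig"))
  X[cand$label == 1L, 1] <- X[cand$label == 1L, 1] + 10  # separable
  expect_equal(select_C(cand, X, grid = 0.5), 0.5)
  expect_equal(select_C(cand, X, grid = c(1, 0.1, 10), folds = 2L, seed = 1L),
               0.1)  # all C perfect on separable data -> smallest wins
  expect_error(select_C(cand, X, grid = c(1, 2), folds = 1L), "folds")
})

test_that("random forest selects B by OOB error and averages tree scores", {
  set.seed(5)
  X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  lab <- as.integer(X[, 1] + 0.3 * rnorm(100) > 0)
  m <- train_rf(X, lab, B_grid = c(50L, 150L), seed = 9L)
  expect_true(m$B %in% c(50L, 150L))
  expect_equal(unname(m$oob[as.character(m$B)]), min(m$oob))
  s1 <- score_candidates(m, X)
  expect_true(all(s1 >= 0 & s1 <= 1))
  # forest score equals the mean of per-tree probability predictions
  pr_all <- predict(m$fit, data = as.data.frame(X), predict.all = TRUE,
                    num.threads = 1L)$predictions
  expect_equal(unname(s1), rowMeans(pr_all[, 2L, ]), tolerance = 1e-12)
  # determinism under the seed
  m2 <- train_rf(X, lab, B_grid = c(50L, 150L), seed = 9L)
  expect_equal(score_candidates(m2, X), s1)
  expect_error(train_rf(X, rep(1L, 100)), "both classes")
})

test_that("trained objective matches exhaustive grid search on random toys", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    X <- matrix(round(rnorm(2 * n), 2), n, 2,
                dimnames = list(NULL, c("a", "b")))
    lab <- integer(n); lab[sample(n, 2)] <- 1L
    pairs <- build_pairs(lab, rep("n", n))
    C <- sample(c(0.5, 1, 5), 1)
    fit <- train_ranksvm(X, pairs, C = C)
    grid <- seq(-3, 3, by = 0.01)
    g <- as.matrix(expand.grid(w1 = grid, w2 = grid))
    S <- X %*% t(g)
    viol <- pmax(1 - (S[pairs$i, , drop = FALSE] -
                        S[pairs$j, , drop = FALSE]), 0)
    obj <- 0.5 * (g[, 1]^2 + g[, 2]^2) + (C / pairs$m) * colSums(viol)
    expect_lt(fit$objective, min(obj) * 1.01)
    expect_gt(fit$objective, min(obj) * 0.9)
  }
})
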