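# Shared fixtures, built in code.

tiny_lexicon <- function() {
  load_lexicon(system.file("extdata", "example_lexicon.tsv",
                           package = "termrank"))
}

example_note <- function() {
  make_note("example_note",
            paste(readLines(system.file("extdata", "example_note.txt",
                                        package = "termrank")),
                  collapse = " "))
}

# small annotated synthetic world for pipeline tests (cached per session)
.small_world_cache <- new.env(parent = emptyenv())
small_world <- function() {
  w <- get0("w", envir = .small_world_cache, inherits = FALSE)
  if (!is.null(w)) return(w)
  profile <- generator_profile(n_notes = 16L, words_mean = 220,
                               words_sd = 40, words_min = 80L,
                               cands_mean = 60, cands_sd = 10,
                               cands_min = 20L, gold_mean = 6, gold_sd = 2,
                               n_lexicon_terms = 300L,
                               n_background_docs = 30L,
                               background_len_mean = 120,
                               background_len_sd = 20)
  lexicon <- generate_lexicon(profile, seed = 11L)
  corpus <- generate_corpus(profile, lexicon, seed = 12L)
  background <- generate_background(profile, lexicon, seed = 13L)
  embeddings <- generate_embeddings(lexicon, d = 8L, seed = 14L)
  w <- list(profile = profile, lexicon = lexicon, corpus = corpus,
            background = background, embeddings = embeddings)
  assign("w", w, envir = .small_world_cache)
  w
}

# the default study-scale corpus used by the acceptance tests (cached)
.default_world_cache <- new.env(parent = emptyenv())
default_world <- function() {
  w <- get0("w", envir = .default_world_cache, inherits = FALSE)
  if (!is.null(w)) return(w)
  profile <- generator_profile()
  lexicon <- generate_lexicon(profile, seed = 42L)
  corpus <- generate_corpus(profile, lexicon, seed = 43L)
  labeled <- label_corpus(corpus$notes, corpus$gold, lexicon)
  w <- list(profile = profile, lexicon = lexicon, corpus = corpus,
            labeled = labeled)
  assign("w", w, envir = .default_world_cache)
  w
}

# brute-force oracles -------------------------------------------------------

bf_auc <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

bf_prf <- function(ranked_terms, gold, k) {
  gold <- unique(gold[nzchar(gold)])
  top <- head(ranked_terms, k)
  claimed <- rep(FALSE, length(gold))
  tp <- 0
  for (term in top) {
    for (j in seq_along(gold)) {
      if (!claimed[j] && relaxed_match(term, gold[j])) {
        claimed[j] <- TRUE
        tp <- tp + 1
        break
      }
    }
  }
  p <- tp / k
  r <- tp / length(gold)
  c(p = p, r = r, f = if (p + r > 0) 2 * p * r / (p + r) else 0)
}
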