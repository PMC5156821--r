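# Candidate term extraction: a left-to-right greedy longest dictionary match
# over stemmed tokens, standing in for a full concept-detection tool. Matches
# never overlap; after a match the scan resumes at the first token past it.
# Occurrences of the same canonical term within a note are merged into one
# candidate.

#' Extract candidate terms from a note
#'
#' Scans the note's stemmed token sequence left to right; at each position the
#' longest window (up to `lexicon$max_term_words`) whose stemmed tokens form a
#' lexicon key is taken as a match and the scan resumes after it
#' (maximal-munch). Occurrences of the same canonical term are merged into one
#' candidate that inherits the entry's semantic type, CHV membership and
#' familiarity.
#'
#' @param note a `note` object.
#' @param lexicon a `lexicon` object.
#' @return data frame with one row per distinct candidate term: `note_id`,
#'   `term`, `semantic_type`, `in_chv`, `familiarity`, `first_token_index`
#'   (0-based index of the first token of the first occurrence),
#'   `n_occurrences`, plus a list column `occurrences` of integer matrices
#'   with 1-based token `start` and exclusive `end` per occurrence.
#' @export
extract_candidates <- function(note, lexicon) {
  stopifnot(inherits(note, "note"), inherits(lexicon, "lexicon"))
  st <- note$tokens$stem
  n <- length(st)
  maxw <- lexicon$max_term_words
  hit_entry <- integer(0)
  hit_start <- integer(0)
  hit_end <- integer(0)
  i <- 1L
  while (i <= n) {
    found <- FALSE
    for (L in seq.int(min(maxw, n - i + 1L), 1L)) {
      key <- paste(st[i:(i + L - 1L)], collapse = " ")
      row <- get0(key, envir = lexicon$index, inherits = FALSE)
      if (!is.null(row)) {
        hit_entry <- c(hit_entry, row)
        hit_start <- c(hit_start, i)
        hit_end <- c(hit_end, i + L)
        i <- i + L
        found <- TRUE
        break
      }
    }
    if (!found) i <- i + 1L
  }
  if (!length(hit_entry)) {
    out <- data.frame(note_id = character(0), term = character(0),
                      semantic_type = character(0), in_chv = logical(0),
                      familiarity = numeric(0), first_token_index = integer(0),
                      n_occurrences = integer(0), stringsAsFactors = FALSE)
    out$occurrences <- list()
    return(out)
  }
  ord <- order(hit_start)
  hit_entry <- hit_entry[ord]; hit_start <- hit_start[ord]; hit_end <- hit_end[ord]
  groups <- split(seq_along(hit_entry), hit_entry)
  rows <- lapply(groups, function(ii) {
    e <- lexicon$entries[hit_entry[ii[1L]], ]
    occ <- cbind(start = hit_start[ii], end = hit_end[ii])
    out <- data.frame(note_id = note$note_id, term = e$term,
                      semantic_type = e$semantic_type, in_chv = e$in_chv,
                      familiarity = e$familiarity,
                      first_token_index = hit_start[ii[1L]] - 1L,
                      n_occurrences = length(ii), stringsAsFactors = FALSE)
    out$occurrences <- list(occ)
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$first_token_index), ]
  rownames(out) <- NULL
  out
}

#' Label candidates against gold-standard terms
#'
#' A candidate is positive when it relaxed-matches any gold term (exact match
#' after normalization, or the candidate subsumes the gold term; see
#' [relaxed_match()]). Also reports the gold terms that no candidate matched
#' (extraction misses), which the keyphrase-level AUC needs as phantom
#' positives.
#'
#' @param candidates candidate data frame from [extract_candidates()].
#' @param gold character vector of gold-standard terms for the same note.
#' @return list with `candidates` (input plus an integer `label` column in
#'   `{0, 1}`) and `missed_gold` (character vector of unmatched gold terms).
#' @export
label_candidates <- function(candidates, gold) {
  gold <- unique(gold[nzchar(gold)])
  if (!length(gold) || !nrow(candidates)) {
    candidates$label <- if (nrow(candidates)) 0L else integer(0)
    return(list(candidates = candidates, missed_gold = gold))
  }
  gtoks <- lapply(gold, .norm_tokens)
  ctoks <- lapply(candidates$term, .norm_tokens)
  hit <- matrix(FALSE, nrow(candidates), length(gold))
  for (i in seq_len(nrow(candidates))) {
    for (j in seq_along(gold)) {
      hit[i, j] <- .relaxed_match_tokens(ctoks[[i]], gtoks[[j]])
    }
  }
  candidates$label <- as.integer(rowSums(hit) > 0)
  list(candidates = candidates,
       missed_gold = gold[colSums(hit) == 0])
}

#' Write a candidate dump as TSV
#'
#' @param candidates labeled candidate data frame (multiple notes allowed).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  cols <- c("note_id", "term", "label", "first_token_index", "n_occurrences",
            "semantic_type")
  if (!"label" %in% names(candidates)) candidates$label <- NA_integer_
  utils::write.table(candidates[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
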