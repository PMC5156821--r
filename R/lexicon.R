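# The controlled vocabulary: canonical terms with a coarse semantic type,
# consumer-health-vocabulary (CHV) membership, and an optional familiarity
# score in [0, 1]. The lexicon is indexed by the stemmed lowercase token
# sequence of each term, so matching in text is case- and
# inflection-insensitive.

#' Default closed set of semantic types
#'
#' The eight major topics that carried gold-standard important terms in the
#' reference corpus, plus a catch-all `"other"`.
#'
#' @return character vector of semantic type labels.
#' @export
default_semantic_types <- function() {
  c("Disease or syndrome", "Organic chemical", "Finding",
    "Neoplastic process", "Therapeutic or preventive procedure",
    "Amino acid, peptide, or protein", "Pathologic function",
    "Diagnostic procedure", "other")
}

#' Build a lexicon from a data frame of entries
#'
#' @param entries data frame with columns `term`, `semantic_type`, `in_chv`
#'   (logical or 0/1) and `familiarity` (numeric in `[0, 1]`, `NA` allowed).
#' @param semantic_types closed set of allowed semantic types.
#' @return an object of class `lexicon`: the entry table, a hash index from
#'   stemmed token-sequence keys to entry rows, and `max_term_words`, the
#'   longest key length in words.
#' @export
as_lexicon <- function(entries, semantic_types = default_semantic_types()) {
  need <- c("term", "semantic_type", "in_chv", "familiarity")
  if (!all(need %in% names(entries))) {
    stop("as_lexicon: entries must have columns ", paste(need, collapse = ", "))
  }
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  entries$term <- as.character(entries$term)
  entries$in_chv <- as.logical(entries$in_chv)
  entries$familiarity <- as.numeric(entries$familiarity)
  if (any(is.na(entries$term)) || any(!nzchar(trimws(entries$term)))) {
    stop("as_lexicon: empty term")
  }
  bad <- !(entries$semantic_type %in% semantic_types)
  if (any(bad)) {
    stop("as_lexicon: unknown semantic type: ",
         paste(unique(entries$semantic_type[bad]), collapse = ", "))
  }
  fam <- entries$familiarity
  if (any(!is.na(fam) & (fam < 0 | fam > 1))) {
    stop("as_lexicon: familiarity outside [0, 1]")
  }
  if (anyDuplicated(entries$term)) {
    stop("as_lexicon: duplicate term: ",
         entries$term[duplicated(entries$term)][1L])
  }
  keys <- vapply(entries$term, function(t) paste(.norm_tokens(t), collapse = " "),
                 character(1), USE.NAMES = FALSE)
  if (any(!nzchar(keys))) stop("as_lexicon: term empty after normalization")
  if (anyDuplicated(keys)) {
    stop("as_lexicon: terms collide after stemming: ",
         entries$term[duplicated(keys)][1L])
  }
  idx <- new.env(parent = emptyenv(), size = max(29L, nrow(entries)))
  for (i in seq_len(nrow(entries))) assign(keys[i], i, envir = idx)
  entries$key <- keys
  structure(list(entries = entries, index = idx,
                 max_term_words = max(lengths(strsplit(keys, " ", fixed = TRUE))),
                 semantic_types = semantic_types),
            class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon>", nrow(x$entries), "terms, up to", x$max_term_words,
      "words;", sum(x$entries$in_chv), "in CHV\n")
  invisible(x)
}

#' Load a lexicon from a TSV file
#'
#' Expects a UTF-8 tab-separated file with a header row `term`,
#' `semantic_type`, `in_chv`, `familiarity`; `"NA"` marks a missing
#' familiarity score. Malformed rows, familiarity outside `[0, 1]` and unknown
#' semantic types raise an error naming the offending line (line 1 is the
#' header).
#'
#' @param path TSV path.
#' @param semantic_types closed set of allowed semantic types.
#' @return a `lexicon` object.
#' @export
load_lexicon <- function(path, semantic_types = default_semantic_types()) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!length(lines)) stop("load_lexicon: empty file ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  need <- c("term", "semantic_type", "in_chv", "familiarity")
  if (!identical(header, need)) {
    stop("load_lexicon: line 1: header must be ", paste(need, collapse = "\t"))
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  rows <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    line <- i + 1L
    if (length(p) != 4L) stop("load_lexicon: line ", line, ": expected 4 fields")
    chv <- p[3L]
    if (!chv %in% c("0", "1", "TRUE", "FALSE")) {
      stop("load_lexicon: line ", line, ": in_chv must be 0/1")
    }
    fam <- if (identical(p[4L], "NA")) NA_real_ else suppressWarnings(as.numeric(p[4L]))
    if (!identical(p[4L], "NA") && (is.na(fam) || fam < 0 || fam > 1)) {
      stop("load_lexicon: line ", line, ": familiarity must be in [0, 1] or NA")
    }
    if (!p[2L] %in% semantic_types) {
      stop("load_lexicon: line ", line, ": unknown semantic type '", p[2L], "'")
    }
    rows[[i]] <- data.frame(term = p[1L], semantic_type = p[2L],
                            in_chv = chv %in% c("1", "TRUE"),
                            familiarity = fam, stringsAsFactors = FALSE)
  }
  entries <- do.call(rbind, rows)
  if (anyDuplicated(entries$term)) {
    dup <- entries$term[duplicated(entries$term)][1L]
    stop("load_lexicon: line ", which(entries$term == dup)[2L] + 1L,
         ": duplicate term '", dup, "'")
  }
  as_lexicon(entries, semantic_types)
}

#' Write a lexicon to a TSV file
#'
#' Inverse of [load_lexicon()]; round-trips the entry table up to row order.
#'
#' @param lexicon a `lexicon` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "lexicon"))
  e <- lexicon$entries
  d <- data.frame(term = e$term, semantic_type = e$semantic_type,
                  in_chv = as.integer(e$in_chv),
                  familiarity = ifelse(is.na(e$familiarity), "NA",
                                       format(e$familiarity, digits = 10)),
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up a stemmed token sequence in the lexicon
#'
#' Exact key match only; no partial or prefix matching.
#'
#' @param lexicon a `lexicon` object.
#' @param tokens character vector of lowercased, stemmed tokens.
#' @return the matching entry as a one-row data frame, or `NULL`.
#' @export
lookup_term <- function(lexicon, tokens) {
  stopifnot(inherits(lexicon, "lexicon"))
  if (!length(tokens)) return(NULL)
  i <- get0(paste(tokens, collapse = " "), envir = lexicon$index,
            inherits = FALSE)
  if (is.null(i)) NULL else lexicon$entries[i, , drop = FALSE]
}
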