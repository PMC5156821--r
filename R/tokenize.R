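# Tokenization of clinical note text.
#
# Word tokens are maximal runs of letters, digits and apostrophes; hyphens and
# other punctuation split tokens and are dropped. Possessives ("Crohn's" ->
# "crohn") and stray apostrophes are stripped before stemming. Character
# offsets into the raw text are preserved.

#' Tokenize raw note text
#'
#' Splits text into word tokens on whitespace and punctuation (hyphens split;
#' numerals are kept as tokens), drops punctuation, and attaches a lowercased
#' normalized form and a Porter stem to every token. Deterministic; an empty
#' string yields a zero-row result.
#'
#' @param text a single character string (may be empty).
#' @return data frame with columns `token` (raw surface form), `word`
#'   (lowercase, possessive/apostrophe stripped), `stem` (Porter stem of
#'   `word`), `start`, `end` (1-based inclusive character offsets).
#' @examples
#' tokenize("He has black stool.")
#' tokenize("non-Hodgkin lymphoma")$word
#' @export
tokenize <- function(text) {
  empty <- data.frame(token = character(0), word = character(0),
                      stem = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (length(text) != 1L || is.na(text)) stop("tokenize: need one non-NA string")
  if (!nzchar(text)) return(empty)
  m <- gregexpr("[A-Za-z0-9']+", text)[[1L]]
  if (m[1L] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  raw <- regmatches(text, list(m))[[1L]]
  word <- tolower(raw)
  word <- sub("'s$", "", word)
  word <- gsub("'", "", word, fixed = TRUE)
  keep <- nzchar(word)
  raw <- raw[keep]
  word <- word[keep]
  starts <- starts[keep]
  lens <- lens[keep]
  data.frame(token = raw, word = word, stem = stem_word(word),
             start = starts, end = starts + lens - 1L,
             stringsAsFactors = FALSE)
}

#' Construct a note object
#'
#' A note bundles an identifier, the raw text, its token table and the word
#' count; it is the document unit that candidates are extracted from and
#' ranked within.
#'
#' @param note_id note identifier (a string).
#' @param text raw note text.
#' @return an object of class `note` with fields `note_id`, `text`, `tokens`
#'   and `word_count`.
#' @export
make_note <- function(note_id, text) {
  stopifnot(is.character(note_id), length(note_id) == 1L, nzchar(note_id))
  toks <- tokenize(text)
  structure(list(note_id = note_id, text = text, tokens = toks,
                 word_count = nrow(toks)),
            class = "note")
}

#' @export
print.note <- function(x, ...) {
  cat("<note>", x$note_id, "-", x$word_count, "words\n")
  invisible(x)
}

#' Read notes from a directory of plain-text files
#'
#' One UTF-8 `.txt` file per note; the note id is the file name without
#' extension.
#'
#' @param dir directory containing `.txt` files.
#' @return named list of [make_note()] objects.
#' @export
read_notes <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (!length(files)) stop("read_notes: no .txt files in ", dir)
  notes <- lapply(files, function(f) {
    id <- sub("\\.txt$", "", basename(f))
    make_note(id, paste(readLines(f, warn = FALSE, encoding = "UTF-8"),
                        collapse = "\n"))
  })
  names(notes) <- vapply(notes, `[[`, character(1), "note_id")
  notes
}

#' Write notes to a directory as plain text
#'
#' @param notes list of notes.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_notes <- function(notes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (n in notes) {
    writeLines(n$text, file.path(dir, paste0(n$note_id, ".txt")), useBytes = TRUE)
  }
  invisible(dir)
}

#' Read gold-standard annotations
#'
#' Tab-separated file with columns `note_id` and `term`, one row per gold
#' term.
#'
#' @param path TSV path.
#' @return named list mapping note id to a character vector of gold terms.
#' @export
read_gold <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("note_id", "term") %in% names(d))) {
    stop("read_gold: need columns note_id and term")
  }
  split(d$term, d$note_id)
}

#' Write gold-standard annotations
#'
#' @param gold named list mapping note id to gold terms.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_gold <- function(gold, path) {
  d <- data.frame(
    note_id = rep(names(gold), lengths(gold)),
    term = unlist(gold, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# normalized stemmed token sequence of a term string (used for lexicon keys,
# candidate labeling and relaxed match); memoized, term strings recur heavily
.norm_cache <- new.env(parent = emptyenv())
.norm_tokens <- function(term) {
  hit <- get0(term, envir = .norm_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  v <- tokenize(term)$stem
  assign(term, v, envir = .norm_cache)
  v
}

# lowercased (unstemmed) words of a term string; memoized
.word_cache <- new.env(parent = emptyenv())
.term_words <- function(term) {
  hit <- get0(term, envir = .word_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  v <- tokenize(term)$word
  assign(term, v, envir = .word_cache)
  v
}
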