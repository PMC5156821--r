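# Porter (1980) suffix-stripping stemmer, original variant.
# Written against the published algorithm description; no stemming package is
# declared as a dependency, so the implementation lives here. Words shorter
# than three letters and words containing non-letters are returned unchanged.

.vowels <- c("a", "e", "i", "o", "u")

# consonant flags for a word split into single letters; "y" is a consonant at
# the start of the word or after a vowel
.cons_flags <- function(ch) {
  n <- length(ch)
  out <- logical(n)
  for (i in seq_len(n)) {
    c <- ch[i]
    out[i] <- if (c %in% .vowels) {
      FALSE
    } else if (c == "y") {
      if (i == 1L) TRUE else !out[i - 1L]
    } else {
      TRUE
    }
  }
  out
}

# the measure m in the pattern [C](VC)^m[V]
.m <- function(w) {
  if (!nzchar(w)) return(0L)
  f <- .cons_flags(strsplit(w, "", fixed = TRUE)[[1L]])
  r <- rle(f)$values
  if (length(r) && r[1L]) r <- r[-1L]
  length(r) %/% 2L
}

.hasv <- function(w) {
  if (!nzchar(w)) return(FALSE)
  any(!.cons_flags(strsplit(w, "", fixed = TRUE)[[1L]]))
}

# ends with a double consonant
.dbl <- function(w) {
  n <- nchar(w)
  if (n < 2L) return(FALSE)
  ch <- strsplit(w, "", fixed = TRUE)[[1L]]
  ch[n] == ch[n - 1L] && .cons_flags(ch)[n]
}

# ends consonant-vowel-consonant, final consonant not w, x or y
.cvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  ch <- strsplit(w, "", fixed = TRUE)[[1L]]
  f <- .cons_flags(ch)
  f[n - 2L] && !f[n - 1L] && f[n] && !(ch[n] %in% c("w", "x", "y"))
}

# apply the longest matching rule of a step; the rule fires only if the
# residual stem has measure > minm, and no other rule of the step is tried
.rule_step <- function(w, rules, minm) {
  lens <- vapply(rules, function(r) nchar(r[1L]), integer(1))
  for (k in order(lens, decreasing = TRUE)) {
    suf <- rules[[k]][1L]
    if (endsWith(w, suf) && nchar(w) > nchar(suf)) {
      stem <- substr(w, 1L, nchar(w) - nchar(suf))
      if (.m(stem) > minm) w <- paste0(stem, rules[[k]][2L])
      return(w)
    }
  }
  w
}

.porter1 <- function(w) {
  if (nchar(w) < 3L || !grepl("^[a-z]+$", w)) return(w)

  # step 1a: plurals
  if (endsWith(w, "sses")) {
    w <- sub("sses$", "ss", w)
  } else if (endsWith(w, "ies")) {
    w <- sub("ies$", "i", w)
  } else if (!endsWith(w, "ss") && endsWith(w, "s")) {
    w <- sub("s$", "", w)
  }

  # step 1b: -eed / -ed / -ing
  flag <- FALSE
  if (endsWith(w, "eed")) {
    stem <- sub("eed$", "", w)
    if (.m(stem) > 0L) w <- paste0(stem, "ee")
  } else if (endsWith(w, "ed")) {
    stem <- sub("ed$", "", w)
    if (.hasv(stem)) {
      w <- stem
      flag <- TRUE
    }
  } else if (endsWith(w, "ing")) {
    stem <- sub("ing$", "", w)
    if (.hasv(stem)) {
      w <- stem
      flag <- TRUE
    }
  }
  if (flag) {
    if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.dbl(w) && !endsWith(w, "l") && !endsWith(w, "s") &&
               !endsWith(w, "z")) {
      w <- substr(w, 1L, nchar(w) - 1L)
    } else if (.m(w) == 1L && .cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # step 1c: y -> i when the stem contains a vowel
  if (endsWith(w, "y")) {
    stem <- substr(w, 1L, nchar(w) - 1L)
    if (.hasv(stem)) w <- paste0(stem, "i")
  }

  # step 2 (m > 0)
  w <- .rule_step(w, list(
    c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
    c("anci", "ance"), c("izer", "ize"), c("abli", "able"), c("alli", "al"),
    c("entli", "ent"), c("eli", "e"), c("ousli", "ous"), c("ization", "ize"),
    c("ation", "ate"), c("ator", "ate"), c("alism", "al"),
    c("iveness", "ive"), c("fulness", "ful"), c("ousness", "ous"),
    c("aliti", "al"), c("iviti", "ive"), c("biliti", "ble")), 0L)

  # step 3 (m > 0)
  w <- .rule_step(w, list(
    c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
    c("ical", "ic"), c("ful", ""), c("ness", "")), 0L)

  # step 4 (m > 1; -ion additionally requires the stem to end in s or t)
  sufs <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
            "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
            "ous", "ive", "ize")
  for (suf in sufs[order(nchar(sufs), decreasing = TRUE)]) {
    if (endsWith(w, suf) && nchar(w) > nchar(suf)) {
      stem <- substr(w, 1L, nchar(w) - nchar(suf))
      ok <- .m(stem) > 1L
      if (suf == "ion") ok <- ok && (endsWith(stem, "s") || endsWith(stem, "t"))
      if (ok) w <- stem
      break
    }
  }

  # step 5a: drop a final e
  if (endsWith(w, "e")) {
    stem <- substr(w, 1L, nchar(w) - 1L)
    mm <- .m(stem)
    if (mm > 1L || (mm == 1L && !.cvc(stem))) w <- stem
  }

  # step 5b: -ll -> -l for m > 1
  if (.m(w) > 1L && .dbl(w) && endsWith(w, "l")) {
    w <- substr(w, 1L, nchar(w) - 1L)
  }

  w
}

.stem_cache <- new.env(parent = emptyenv())

#' Stem words with the Porter algorithm
#'
#' Lowercases each word and applies the classic Porter suffix-stripping
#' algorithm. This is the normalization used throughout the package for
#' dictionary indexing, candidate matching and relaxed string match, so terms
#' compare case- and inflection-insensitively (`"diseases"` and `"Disease"`
#' both stem to `"diseas"`). Results are cached per word.
#'
#' @param word character vector of nonempty words.
#' @return character vector of stems, same length as `word`.
#' @examples
#' stem_word(c("diseases", "running", "a"))
#' @export
stem_word <- function(word) {
  if (length(word) == 0L) return(character(0))
  if (any(is.na(word)) || any(!nzchar(word))) {
    stop("stem_word: input words must be nonempty")
  }
  word <- tolower(word)
  vapply(word, function(w) {
    hit <- get0(w, envir = .stem_cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    s <- .porter1(w)
    assign(w, s, envir = .stem_cache)
    s
  }, character(1), USE.NAMES = FALSE)
}
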