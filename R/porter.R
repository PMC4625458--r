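# Classic Porter (1980) suffix-stripping stemmer.
#
# Hand-implemented because no stemming library ships with the runtime. The
# algorithm is the original five-step one, with the conventional guard that
# words of fewer than three letters are returned unchanged.

.vowel_mask <- function(chars) {
  # TRUE where the letter acts as a vowel: a,e,i,o,u always; y when the
  # preceding letter is a consonant (y at word start is a consonant).
  n <- length(chars)
  v <- chars %in% c("a", "e", "i", "o", "u")
  if (n == 0L) return(logical(0))
  for (i in seq_len(n)) {
    if (chars[i] == "y") {
      v[i] <- if (i == 1L) FALSE else !v[i - 1L]
    }
  }
  v
}

.measure <- function(stem) {
  # m in [C](VC)^m[V]: the number of vowel->consonant transitions.
  if (!nzchar(stem)) return(0L)
  v <- .vowel_mask(strsplit(stem, "", fixed = TRUE)[[1]])
  sum(v[-length(v)] & !v[-1L])
}

.contains_vowel <- function(stem) {
  nzchar(stem) && any(.vowel_mask(strsplit(stem, "", fixed = TRUE)[[1]]))
}

.ends_double_consonant <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L)
  b <- substr(word, n, n)
  if (a != b) return(FALSE)
  v <- .vowel_mask(strsplit(word, "", fixed = TRUE)[[1]])
  !v[n]
}

.ends_cvc <- function(word) {
  # *o condition: stem ends consonant-vowel-consonant, final not w, x or y.
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  v <- .vowel_mask(strsplit(word, "", fixed = TRUE)[[1]])
  last <- substr(word, n, n)
  !v[n - 2L] && v[n - 1L] && !v[n] && !(last %in% c("w", "x", "y"))
}

.ends_with <- function(word, suffix) {
  n <- nchar(word); s <- nchar(suffix)
  n >= s && substr(word, n - s + 1L, n) == suffix
}

.chop <- function(word, k) substr(word, 1L, nchar(word) - k)

# Rule tables for steps 2-4: suffix -> replacement, applied when the measure
# condition holds on the stem. Longest matching suffix wins within a step.
.step2_rules <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"), c("anci", "ance"),
  c("izer", "ize"), c("abli", "able"), c("alli", "al"), c("entli", "ent"),
  c("eli", "e"), c("ousli", "ous"), c("ization", "ize"), c("ation", "ate"),
  c("ator", "ate"), c("alism", "al"), c("iveness", "ive"), c("fulness", "ful"),
  c("ousness", "ous"), c("aliti", "al"), c("iviti", "ive"), c("biliti", "ble")
)
.step3_rules <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", "")
)
.step4_suffixes <- c(
  "al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement", "ment",
  "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize"
)

.apply_rules <- function(word, rules, min_measure) {
  matches <- Filter(function(r) .ends_with(word, r[1]), rules)
  if (length(matches) == 0L) return(word)
  lens <- vapply(matches, function(r) nchar(r[1]), integer(1))
  rule <- matches[[which.max(lens)]]
  stem <- .chop(word, nchar(rule[1]))
  if (.measure(stem) > min_measure) paste0(stem, rule[2]) else word
}

.porter_one <- function(word) {
  if (nchar(word) < 3L) return(word)

  # Step 1a: plurals.
  if (.ends_with(word, "sses")) {
    word <- .chop(word, 2L)
  } else if (.ends_with(word, "ies")) {
    word <- paste0(.chop(word, 3L), "i")
  } else if (!.ends_with(word, "ss") && .ends_with(word, "s")) {
    word <- .chop(word, 1L)
  }

  # Step 1b: -eed / -ed / -ing.
  if (.ends_with(word, "eed")) {
    if (.measure(.chop(word, 3L)) > 0L) word <- .chop(word, 1L)
  } else {
    stripped <- FALSE
    if (.ends_with(word, "ed") && .contains_vowel(.chop(word, 2L))) {
      word <- .chop(word, 2L); stripped <- TRUE
    } else if (.ends_with(word, "ing") && .contains_vowel(.chop(word, 3L))) {
      word <- .chop(word, 3L); stripped <- TRUE
    }
    if (stripped) {
      if (.ends_with(word, "at") || .ends_with(word, "bl") || .ends_with(word, "iz")) {
        word <- paste0(word, "e")
      } else if (.ends_double_consonant(word) &&
                 !(.ends_with(word, "l") || .ends_with(word, "s") || .ends_with(word, "z"))) {
        word <- .chop(word, 1L)
      } else if (.measure(word) == 1L && .ends_cvc(word)) {
        word <- paste0(word, "e")
      }
    }
  }

  # Step 1c: terminal y -> i when the stem has a vowel.
  if (.ends_with(word, "y") && .contains_vowel(.chop(word, 1L))) {
    word <- paste0(.chop(word, 1L), "i")
  }

  word <- .apply_rules(word, .step2_rules, 0L)
  word <- .apply_rules(word, .step3_rules, 0L)

  # Step 4: drop derivational suffixes when m > 1; -ion only after s or t.
  matches <- Filter(function(s) .ends_with(word, s), .step4_suffixes)
  if (length(matches) > 0L) {
    suffix <- matches[[which.max(nchar(matches))]]
    stem <- .chop(word, nchar(suffix))
    ok <- .measure(stem) > 1L
    if (ok && suffix == "ion") {
      ok <- .ends_with(stem, "s") || .ends_with(stem, "t")
    }
    if (ok) word <- stem
  }

  # Step 5a: terminal e.
  if (.ends_with(word, "e")) {
    stem <- .chop(word, 1L)
    m <- .measure(stem)
    if (m > 1L || (m == 1L && !.ends_cvc(stem))) word <- stem
  }
  # Step 5b: -ll -> -l when m > 1.
  if (.measure(word) > 1L && .ends_double_consonant(word) && .ends_with(word, "l")) {
    word <- .chop(word, 1L)
  }
  word
}

#' Porter stemmer
#'
#' Reduces English words to their stems with the classic Porter
#' suffix-stripping algorithm, the normalization step used throughout the
#' bag-of-words pipeline (e.g. `"binding"`, `"binds"` and `"bind"` all map
#' to the stem `"bind"`). Input is expected to be lowercase; words shorter
#' than three characters are returned unchanged.
#'
#' @param words character vector of lowercase words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("binding", "annotations", "oscillators"))
#' @export
porter_stem <- function(words) {
  vapply(words, .porter_one, character(1), USE.NAMES = FALSE)
}
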