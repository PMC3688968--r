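#' Porter stem a vector of words
#'
#' Classic suffix-stripping stemmer (Porter 1980), operating on lowercase
#' ASCII words. Words of length two or less are returned unchanged.
#'
#' @param words character vector.
#' @return character vector of stems.
#' @examples
#' porter_stem(c("kinases", "serine", "binding", "relational"))
#' @export
porter_stem <- function(words) {
  vapply(tolower(words), porter_stem1, "", USE.NAMES = FALSE)
}

porter_stem1 <- function(w) {
  if (nchar(w) <= 2L) return(w)

  is_cons <- function(s, i) {
    ch <- substr(s, i, i)
    if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
    if (ch == "y") {
      if (i == 1L) return(TRUE)
      return(!is_cons(s, i - 1L))
    }
    TRUE
  }
  measure <- function(s) {
    n <- nchar(s)
    if (!n) return(0L)
    types <- vapply(seq_len(n), function(i) is_cons(s, i), TRUE)
    m <- 0L
    i <- 1L
    while (i <= n && types[i]) i <- i + 1L # leading consonants
    while (i <= n) {
      while (i <= n && !types[i]) i <- i + 1L # vowels
      if (i > n) break
      m <- m + 1L
      while (i <= n && types[i]) i <- i + 1L # consonants
    }
    m
  }
  has_vowel <- function(s) {
    n <- nchar(s)
    n > 0L && any(!vapply(seq_len(n), function(i) is_cons(s, i), TRUE))
  }
  double_cons <- function(s) {
    n <- nchar(s)
    n >= 2L && substr(s, n, n) == substr(s, n - 1L, n - 1L) && is_cons(s, n)
  }
  cvc <- function(s) {
    n <- nchar(s)
    if (n < 3L) return(FALSE)
    if (!(is_cons(s, n) && !is_cons(s, n - 1L) && is_cons(s, n - 2L))) return(FALSE)
    !substr(s, n, n) %in% c("w", "x", "y")
  }
  ends <- function(s, suf) {
    nchar(s) > nchar(suf) && endsWith(s, suf)
  }
  chop <- function(s, suf) substr(s, 1L, nchar(s) - nchar(suf))

  ## step 1a
  if (ends(w, "sses")) w <- chop(w, "es")
  else if (ends(w, "ies")) w <- paste0(chop(w, "ies"), "i")
  else if (!ends(w, "ss") && ends(w, "s")) w <- chop(w, "s")

  ## step 1b
  if (ends(w, "eed")) {
    if (measure(chop(w, "eed")) > 0L) w <- chop(w, "d")
  } else {
    hit <- NULL
    if (ends(w, "ed") && has_vowel(chop(w, "ed"))) hit <- "ed"
    else if (ends(w, "ing") && has_vowel(chop(w, "ing"))) hit <- "ing"
    if (!is.null(hit)) {
      w <- chop(w, hit)
      if (ends(w, "at") || ends(w, "bl") || ends(w, "iz")) w <- paste0(w, "e")
      else if (double_cons(w) && !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
        w <- substr(w, 1L, nchar(w) - 1L)
      } else if (measure(w) == 1L && cvc(w)) w <- paste0(w, "e")
    }
  }

  ## step 1c
  if (ends(w, "y") && has_vowel(chop(w, "y"))) w <- paste0(chop(w, "y"), "i")

  step_map <- function(w, rules, min_m = 0L) {
    for (i in seq(1L, length(rules), by = 2L)) {
      suf <- rules[i]; rep <- rules[i + 1L]
      if (ends(w, suf)) {
        stem <- chop(w, suf)
        if (measure(stem) > min_m) w <- paste0(stem, rep)
        return(w)
      }
    }
    w
  }

  ## step 2 (longest match first within each final letter; ordering below is safe)
  w <- step_map(w, c(
    "ational", "ate", "tional", "tion", "enci", "ence", "anci", "ance",
    "izer", "ize", "abli", "able", "alli", "al", "entli", "ent", "eli", "e",
    "ousli", "ous", "ization", "ize", "ation", "ate", "ator", "ate",
    "alism", "al", "iveness", "ive", "fulness", "ful", "ousness", "ous",
    "aliti", "al", "iviti", "ive", "biliti", "ble"
  ))

  ## step 3
  w <- step_map(w, c(
    "icate", "ic", "ative", "", "alize", "al", "iciti", "ic",
    "ical", "ic", "ful", "", "ness", ""
  ))

  ## step 4
  done <- FALSE
  for (suf in c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
                "ism", "ate", "iti", "ous", "ive", "ize", "ion", "al", "er",
                "ic", "ou")) {
    if (ends(w, suf)) {
      stem <- chop(w, suf)
      if (measure(stem) > 1L) {
        if (suf == "ion" && !substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")) {
          done <- TRUE
          break
        }
        w <- stem
      }
      done <- TRUE
      break
    }
  }

  ## step 5a
  if (ends(w, "e")) {
    stem <- chop(w, "e")
    m <- measure(stem)
    if (m > 1L || (m == 1L && !cvc(stem))) w <- stem
  }
  ## step 5b
  if (measure(w) > 1L && double_cons(w) && endsWith(w, "l")) {
    w <- substr(w, 1L, nchar(w) - 1L)
  }
  w
}

#' English stop-word list
#'
#' The fixed stop-word list used by [tokenize_descriptions()] (the common
#' snowball English function-word inventory).
#'
#' @return character vector.
#' @export
english_stopwords <- function() {
  c(
    "i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you", "your",
    "yours", "yourself", "yourselves", "he", "him", "his", "himself", "she",
    "her", "hers", "herself", "it", "its", "itself", "they", "them", "their",
    "theirs", "themselves", "what", "which", "who", "whom", "this", "that",
    "these", "those", "am", "is", "are", "was", "were", "be", "been", "being",
    "have", "has", "had", "having", "do", "does", "did", "doing", "would",
    "should", "could", "ought", "a", "an", "the", "and", "but", "if", "or",
    "because", "as", "until", "while", "of", "at", "by", "for", "with",
    "about", "against", "between", "into", "through", "during", "before",
    "after", "above", "below", "to", "from", "up", "down", "in", "out", "on",
    "off", "over", "under", "again", "further", "then", "once", "here",
    "there", "when", "where", "why", "how", "all", "any", "both", "each",
    "few", "more", "most", "other", "some", "such", "no", "nor", "not",
    "only", "own", "same", "so", "than", "too", "very", "can", "will", "just",
    "may", "might", "also", "via"
  )
}

#' Tokenize protein descriptions into descriptive stem sets
#'
#' Lowercases, splits on non-alphanumeric characters, removes stop words and
#' single characters, Porter-stems, and finally removes "too general" stems
#' present in more than `max_doc_frac` of all proteins, leaving a set of
#' tokens descriptive for each protein.
#'
#' @param descriptions named character vector: protein id -> free-text
#'   description.
#' @param stopwords stop-word list; defaults to [english_stopwords()].
#' @param max_doc_frac corpus-frequency cutoff for general words: stems
#'   occurring in more than this fraction of all proteins are dropped
#'   (default 0.1).
#' @return named list: protein id -> character vector of stems (set, sorted).
#' @export
tokenize_descriptions <- function(descriptions, stopwords = english_stopwords(),
                                  max_doc_frac = 0.1) {
  stopifnot(!is.null(names(descriptions)))
  sets <- lapply(descriptions, function(d) {
    toks <- strsplit(tolower(d), "[^a-z0-9]+")[[1L]]
    toks <- toks[nchar(toks) > 1L & !toks %in% stopwords]
    sort(unique(porter_stem(toks)))
  })
  if (length(sets) > 1L) {
    doc_freq <- table(unlist(lapply(sets, unique)))
    general <- names(doc_freq)[doc_freq / length(sets) > max_doc_frac]
    sets <- lapply(sets, function(s) setdiff(s, general))
  }
  sets
}
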