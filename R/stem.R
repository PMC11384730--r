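# Porter stemmer. The normalization sieve needs a deterministic,
# widely understood English suffix stemmer for its fuzzy lookup steps; this
# is the classic algorithm (Porter 1980), ported directly so the package has
# no external text-processing dependency. Operates on lowercase words.

#' Porter stem of a word
#'
#' @param words Character vector (lowercased internally).
#' @return Character vector of stems.
#' @export
#' @examples
#' porter_stem(c("phosphatases", "hydrolyzed", "conversion"))
porter_stem <- function(words) {
  vapply(tolower(words), porter_stem_one, character(1), USE.NAMES = FALSE)
}

porter_stem_one <- function(w) {
  if (nchar(w) <= 2) return(w)
  b <- strsplit(w, "", fixed = TRUE)[[1]]

  cons <- function(i) {
    ch <- b[i]
    if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
    if (ch == "y") return(if (i == 1) TRUE else !cons(i - 1))
    TRUE
  }
  # number of VC sequences in b[1..j]
  m <- function(j) {
    n <- 0L; i <- 1L
    while (i <= j && cons(i)) i <- i + 1L
    repeat {
      if (i > j) return(n)
      while (i <= j && !cons(i)) i <- i + 1L
      if (i > j) return(n)
      n <- n + 1L
      while (i <= j && cons(i)) i <- i + 1L
    }
  }
  k <- length(b)
  vowel_in_stem <- function(j) any(!vapply(seq_len(j), cons, logical(1)))
  doublec <- function(j) j >= 2 && b[j] == b[j - 1] && cons(j)
  cvc <- function(j) {
    j >= 3 && cons(j) && !cons(j - 1) && cons(j - 2) &&
      !b[j] %in% c("w", "x", "y")
  }
  ends <- function(s) {
    sc <- strsplit(s, "", fixed = TRUE)[[1]]
    ls <- length(sc)
    ls <= k && identical(b[(k - ls + 1):k], sc)
  }
  stem_len <- function(s) k - nchar(s) # length of stem before suffix s
  setto <- function(s) {
    sc <- if (nzchar(s)) strsplit(s, "", fixed = TRUE)[[1]] else character(0)
    b <<- c(b[seq_len(k)], sc)
    k <<- length(b)
  }
  chop <- function(n) { k <<- k - n; b <<- b[seq_len(k)] }

  # Step 1a
  if (ends("sses")) chop(2)
  else if (ends("ies")) { chop(3); setto("i") }
  else if (!ends("ss") && ends("s")) chop(1)

  # Step 1b
  did_1b <- FALSE
  if (ends("eed")) {
    if (m(stem_len("eed")) > 0) chop(1)
  } else if (ends("ed") && vowel_in_stem(stem_len("ed"))) {
    chop(2); did_1b <- TRUE
  } else if (ends("ing") && vowel_in_stem(stem_len("ing"))) {
    chop(3); did_1b <- TRUE
  }
  if (did_1b) {
    if (ends("at") || ends("bl") || ends("iz")) setto("e")
    else if (doublec(k) && !b[k] %in% c("l", "s", "z")) chop(1)
    else if (m(k) == 1 && cvc(k)) setto("e")
  }

  # Step 1c
  if (ends("y") && vowel_in_stem(stem_len("y"))) { chop(1); setto("i") }

  rule <- function(suffix, repl, min_m = 0) {
    if (ends(suffix) && m(stem_len(suffix)) > min_m) {
      chop(nchar(suffix)); setto(repl); return(TRUE)
    }
    FALSE
  }
  # Step 2
  for (p in list(c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
                 c("anci", "ance"), c("izer", "ize"), c("abli", "able"),
                 c("alli", "al"), c("entli", "ent"), c("eli", "e"),
                 c("ousli", "ous"), c("ization", "ize"), c("ation", "ate"),
                 c("ator", "ate"), c("alism", "al"), c("iveness", "ive"),
                 c("fulness", "ful"), c("ousness", "ous"), c("aliti", "al"),
                 c("iviti", "ive"), c("biliti", "ble"))) {
    if (rule(p[1], p[2])) break
  }
  # Step 3
  for (p in list(c("icate", "ic"), c("ative", ""), c("alize", "al"),
                 c("iciti", "ic"), c("ical", "ic"), c("ful", ""),
                 c("ness", ""))) {
    if (rule(p[1], p[2])) break
  }
  # Step 4 (m > 1)
  for (s in c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
              "ement", "ment", "ent", "ou", "ism", "ate", "iti", "ous",
              "ive", "ize")) {
    if (ends(s) && m(stem_len(s)) > 1) { chop(nchar(s)); break }
    if (s == "ent" && ends("ion") && m(stem_len("ion")) > 1 &&
        stem_len("ion") >= 1 && b[stem_len("ion")] %in% c("s", "t")) {
      chop(3); break
    }
  }
  # Step 5a
  if (ends("e")) {
    a <- m(k - 1)
    if (a > 1 || (a == 1 && !cvc(k - 1))) chop(1)
  }
  # Step 5b
  if (b[k] == "l" && doublec(k) && m(k) > 1) chop(1)

  paste(b, collapse = "")
}
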