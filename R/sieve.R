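#' Construct a chemical lexicon
#'
#' A lexicon is a named store of identifier/synonym rows plus optional
#' cross-references. Cross-references come in two flavours used by the
#' sieve's cross-lexicon mapping: identifier cross-references, whose
#' `xref_type` names another identifier namespace (e.g. `CHEBI`, `MESH`) and
#' drive 'single' mapping, and structural keys (`InChIKey`, `SMILES`, `CAS`)
#' that drive 'pivot' mapping.
#'
#' Processed (`tolower`, non-alphanumerics stripped) and stemmed forms of
#' every synonym are precomputed, since the sieve's fuzzy steps search over
#' them.
#'
#' @param name Lexicon name, conventionally the identifier namespace
#'   (`"CHEBI"`, `"MESH"`).
#' @param synonyms Tibble with columns `id`, `synonym`.
#' @param xrefs Tibble with columns `id`, `xref_type`, `value` (may be empty).
#' @return An object of class `ecr_lexicon`.
#' @export
ecr_lexicon <- function(name, synonyms,
                        xrefs = tibble(id = character(),
                                       xref_type = character(),
                                       value = character())) {
  synonyms <- as_tibble(synonyms)
  stopifnot(all(c("id", "synonym") %in% names(synonyms)))
  synonyms$processed <- process_term(synonyms$synonym)
  synonyms$stemmed <- porter_stem(synonyms$processed)
  structure(list(name = name, synonyms = synonyms, xrefs = as_tibble(xrefs)),
            class = "ecr_lexicon")
}

#' @export
print.ecr_lexicon <- function(x, ...) {
  cat("<ecr_lexicon> ", x$name, ": ", length(unique(x$synonyms$id)),
      " ids, ", nrow(x$synonyms), " synonyms, ", nrow(x$xrefs),
      " xrefs\n", sep = "")
  invisible(x)
}

#' Read a lexicon from TSV
#'
#' Two-column rows are `id TAB synonym`; three-column rows are
#' `id TAB xref_type TAB value`. Lines starting with `#` are ignored.
#'
#' @param path TSV file.
#' @param name Lexicon name; defaults to the namespace of the first id.
#' @return An `ecr_lexicon`.
#' @export
read_lexicon <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(parts)
  syn <- tibble(
    id = map_chr(parts[n == 2], 1),
    synonym = map_chr(parts[n == 2], 2)
  )
  xr <- tibble(
    id = map_chr(parts[n == 3], 1),
    xref_type = map_chr(parts[n == 3], 2),
    value = map_chr(parts[n == 3], 3)
  )
  name <- name %||% sub(":.*$", "", syn$id[1])
  ecr_lexicon(name, syn, xr)
}

#' Processed form of a mention string
#'
#' Lowercases and strips every non-alphanumeric character (including
#' whitespace), the canonical normalization applied before the sieve's fuzzy
#' lookup steps.
#' @param x Character vector.
#' @return Character vector.
#' @export
process_term <- function(x) {
  gsub("[^a-z0-9]", "", tolower(x))
}

#' Build the query forms of a mention
#'
#' @param raw Surface string of the mention.
#' @return Tibble with `raw`, `processed` and `stemmed` (stem of the
#'   processed form) columns — the three forms the sieve steps search with.
#' @export
mention_query <- function(raw) {
  processed <- process_term(raw)
  tibble(raw = raw, processed = processed, stemmed = porter_stem(processed))
}

#' Detect abbreviation definitions in a document
#'
#' Scans for parenthesized short/long form definitions of the form
#' "long form (SF)" and the reverse "SF (long form)", using the classical
#' alignment heuristic: the candidate long form is the up-to
#' `min(|SF| + 5, 2 |SF|)` words before the parenthesis, trimmed to the
#' shortest suffix in which every character of the short form appears in
#' order, with the short form's first character matching the start of a word.
#' Nested parentheses are handled innermost first.
#'
#' @param text Document text.
#' @return Named character vector: names are short forms, values long forms.
#' @export
#' @examples
#' expand_abbreviations("It hydrolyzes triphenyl phosphate (TPP) in vitro.")
expand_abbreviations <- function(text) {
  out <- character()
  if (is.null(text) || !nzchar(text)) return(out)
  m <- str_locate_all(text, "\\(([^()]{1,60})\\)")[[1]]
  for (i in seq_len(nrow(m))) {
    inner <- substring(text, m[i, 1] + 1L, m[i, 2] - 1L)
    before <- substring(text, 1, m[i, 1] - 1L)
    if (is_short_form(inner)) {
      lf <- find_long_form(before, inner)
      if (!is.null(lf)) out[inner] <- lf
    } else {
      # reverse pattern: short form outside, definition inside
      sf <- last_word(before)
      if (!is.null(sf) && is_short_form(sf)) {
        lf <- find_long_form(paste0(inner, " "), sf)
        if (!is.null(lf) && identical(lf, trimws(inner))) out[sf] <- lf
      }
    }
  }
  out
}

is_short_form <- function(x) {
  nchar(x) >= 2 && nchar(x) <= 10 && !grepl("\\s", x) &&
    grepl("^[A-Za-z]", x) && grepl("[A-Z0-9]", x)
}

last_word <- function(x) {
  w <- regmatches(x, regexpr("[A-Za-z0-9-]+\\s*$", x))
  if (length(w) == 0 || !nzchar(trimws(w))) return(NULL)
  trimws(w)
}

# Schwartz-Hearst style right-to-left alignment of the short form against
# the text before the parenthesis.
find_long_form <- function(before, sf) {
  words <- regmatches(before, gregexpr("\\S+", before))[[1]]
  if (!length(words)) return(NULL)
  max_words <- min(nchar(sf) + 5L, 2L * nchar(sf))
  cand_words <- utils::tail(words, max_words)
  candidate <- paste(cand_words, collapse = " ")
  sfl <- tolower(strsplit(sf, "", fixed = TRUE)[[1]])
  cl <- tolower(strsplit(candidate, "", fixed = TRUE)[[1]])
  i <- length(sfl); j <- length(cl)
  while (i > 0) {
    while (j > 0 &&
           !(cl[j] == sfl[i] &&
             (i > 1 || j == 1 || cl[j - 1] %in% c(" ", "-", "(")))) {
      j <- j - 1
    }
    if (j == 0) return(NULL)
    i <- i - 1; j <- j - 1
  }
  lf <- trimws(substring(candidate, j + 1))
  if (!nzchar(lf) || tolower(lf) == tolower(sf)) return(NULL)
  lf
}

#' Sieve lookup of a mention in a target lexicon
#'
#' Runs the five candidate-lookup steps strictly in order, stopping at the
#' first step that yields candidates:
#' 1. the raw surface form against the target lexicon's stored synonyms;
#' 2. the processed form (lowercased, non-alphanumerics stripped) against
#'    the target's processed synonyms;
#' 3. the stemmed processed form against the target's stemmed synonyms;
#' 4. the processed form against all registered lexicons, mapped back to the
#'    target;
#' 5. the stemmed form against all registered lexicons, mapped back to the
#'    target.
#'
#' Cross-lexicon hits (steps 4-5) map to the target either 'single' — via an
#' identifier cross-reference whose `xref_type` equals the target lexicon's
#' name — or 'pivot' — via a shared structural key, trying `InChIKey`, then
#' `SMILES`, then `CAS`. Single mapping is preferred over pivots.
#'
#' @param raw Mention surface string.
#' @param target Name of the target lexicon.
#' @param lexicons Named list of `ecr_lexicon` objects (the registered set;
#'   houses both the target and the union searched by steps 4-5).
#' @return Tibble with `ids` (list column of candidate ids), `step` (1-5, or
#'   0 for no match) and `via` (`"direct"`, `"single"` or `"pivot:<key>"`).
#' @export
sieve_lookup <- function(raw, target, lexicons) {
  if (!target %in% names(lexicons)) {
    abort(paste0("target lexicon ", dQuote(target),
                 " is not among the registered lexicons (",
                 paste(names(lexicons), collapse = ", "), ")"))
  }
  q <- mention_query(raw)
  tl <- lexicons[[target]]
  hit <- function(ids, step, via) tibble(ids = list(sort(unique(ids))),
                                         step = step, via = via)
  ids <- tl$synonyms$id[tl$synonyms$synonym == q$raw]
  if (length(ids)) return(hit(ids, 1L, "direct"))
  ids <- tl$synonyms$id[tl$synonyms$processed == q$processed]
  if (length(ids)) return(hit(ids, 2L, "direct"))
  ids <- tl$synonyms$id[tl$synonyms$stemmed == q$stemmed]
  if (length(ids)) return(hit(ids, 3L, "direct"))
  for (step in 4:5) {
    col <- if (step == 4L) "processed" else "stemmed"
    qv <- q[[col]]
    foreign_ids <- unlist(lapply(lexicons[names(lexicons) != target],
                                 function(lx) lx$synonyms$id[lx$synonyms[[col]] == qv]))
    mapped <- map_to_target(unique(foreign_ids), lexicons, target)
    if (nrow(mapped)) return(hit(mapped$id, step, mapped$via[1]))
  }
  tibble(ids = list(character()), step = 0L, via = NA_character_)
}

PIVOT_KEYS <- c("InChIKey", "SMILES", "CAS")

# Map foreign ids into the target lexicon. 'single' (curated identifier
# cross-references) takes precedence over structural pivots, and pivot keys
# are tried in decreasing collision resistance.
map_to_target <- function(foreign_ids, lexicons, target) {
  if (!length(foreign_ids)) {
    return(tibble(id = character(), via = character()))
  }
  tl <- lexicons[[target]]
  all_xrefs <- bind_rows(lapply(lexicons, function(lx) lx$xrefs))
  target_ids <- unique(tl$synonyms$id)

  # single: a cross-reference on the foreign entry that names a target id,
  # or one on a target entry that names the foreign id
  fx <- all_xrefs[all_xrefs$id %in% foreign_ids &
                    all_xrefs$xref_type == target, ]
  single <- intersect(fx$value, target_ids)
  rx <- tl$xrefs[tl$xrefs$value %in% foreign_ids, ]
  single <- union(single, intersect(rx$id, target_ids))
  if (length(single)) return(tibble(id = single, via = "single"))

  for (key in PIVOT_KEYS) {
    fk <- all_xrefs$value[all_xrefs$id %in% foreign_ids &
                            all_xrefs$xref_type == key]
    if (!length(fk)) next
    tk <- tl$xrefs[tl$xrefs$xref_type == key & tl$xrefs$value %in% fk, ]
    hits <- intersect(unique(tk$id), target_ids)
    if (length(hits)) {
      return(tibble(id = hits, via = paste0("pivot:", key)))
    }
  }
  tibble(id = character(), via = character())
}

#' Normalize the chemical mentions of a document
#'
#' Full per-document pipeline: abbreviation expansion, sieve lookup and
#' post-processing. A short form is replaced by its detected long form only
#' when the short form itself fails lookup and the long form succeeds, so
#' genuine chemical acronyms present in the lexicon are never overridden.
#'
#' @param surfaces Character vector of chemical mention surface strings
#'   (one document's mentions, in document order).
#' @param doc_text Document text used for abbreviation detection.
#' @param target Target lexicon name.
#' @param lexicons Named list of registered lexicons.
#' @param stoplist Character vector of processed forms to drop as
#'   non-chemical (default empty).
#' @return Tibble with one row per input mention: `surface`, `ids` (list),
#'   `id` (final resolved id or NA), `step`, `via`, `dropped` (stoplist flag).
#' @export
normalize_chemicals <- function(surfaces, doc_text = "", target = "CHEBI",
                                lexicons = list(), stoplist = character()) {
  abbrev <- expand_abbreviations(doc_text)
  res <- lapply(surfaces, function(s) {
    r <- sieve_lookup(s, target, lexicons)
    if (r$step == 0L && s %in% names(abbrev)) {
      r2 <- sieve_lookup(abbrev[[s]], target, lexicons)
      if (r2$step > 0L) r <- r2
    }
    r
  })
  out <- tibble(
    surface = surfaces,
    ids = lapply(res, function(r) r$ids[[1]]),
    step = map_int(res, "step"),
    via = map_chr(res, "via")
  )
  postprocess_candidates(out, stoplist = stoplist)
}

#' Resolve ambiguity and drop non-chemical mentions
#'
#' Post-processing of per-mention candidate sets within one document:
#' mentions whose processed form is on the stoplist are dropped; an
#' ambiguous mention (two or more candidates) keeps the candidate that an
#' unambiguous mention of the same document resolved to, preferring
#' unambiguous mentions with the same processed surface form; remaining ties
#' are broken by the lowest numeric identifier, with a warning.
#'
#' @param candidates Tibble with `surface` and `ids` (list) columns.
#' @param stoplist Processed forms to drop.
#' @return The tibble with added `id` (resolved identifier or NA) and
#'   `dropped` columns.
#' @export
postprocess_candidates <- function(candidates, stoplist = character()) {
  proc <- process_term(candidates$surface)
  dropped <- proc %in% process_term(stoplist)
  n_cand <- lengths(candidates$ids)
  unambig <- !dropped & n_cand == 1
  anchors <- tibble(processed = proc[unambig],
                    id = map_chr(candidates$ids[unambig], 1))
  id <- rep(NA_character_, nrow(candidates))
  id[unambig] <- map_chr(candidates$ids[unambig], 1)
  for (i in which(!dropped & n_cand >= 2)) {
    cand <- candidates$ids[[i]]
    same_form <- anchors$id[anchors$processed == proc[i]]
    pick <- intersect(same_form, cand)
    if (!length(pick)) pick <- intersect(unique(anchors$id), cand)
    if (length(pick) == 1) {
      id[i] <- pick
    } else {
      pool <- if (length(pick)) pick else cand
      id[i] <- pool[order(id_number(pool), pool)][1]
      warn(paste0("ambiguous mention ", dQuote(candidates$surface[i]),
                  " tie-broken to lowest numeric id ", id[i]))
    }
  }
  candidates$id <- id
  candidates$dropped <- dropped
  candidates
}

#' Read the pH 7.3 ChEBI remapping table
#'
#' Parses the two-column TSV mapping each ChEBI identifier to the identifier
#' of its major protonation state at pH 7.3 (the form used by the reaction
#' knowledgebase). A header line is tolerated. The mapping is validated to
#' be idempotent: every target id maps to itself.
#'
#' @param path TSV path.
#' @return Named character vector (source id -> pH 7.3 id) of class
#'   `ecr_ph73`.
#' @export
read_ph73 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- parts[vapply(parts, function(p) length(p) >= 2 &&
                         grepl("^CHEBI:\\d+$", p[1]), logical(1))]
  map <- setNames(vapply(rows, `[[`, character(1), 2),
                  vapply(rows, `[[`, character(1), 1))
  bad <- map[map %in% names(map) & map[map] != map]
  if (length(bad)) {
    abort(paste0("pH 7.3 mapping is not idempotent for: ",
                 paste(names(bad), collapse = ", ")))
  }
  structure(map, class = "ecr_ph73")
}

#' Map identifiers to their pH 7.3 protonation state
#'
#' Identifiers present in the mapping are replaced; all others (including
#' non-ChEBI identifiers) pass through unchanged. Idempotent:
#' `apply_ph73(apply_ph73(x, m), m)` equals `apply_ph73(x, m)`.
#'
#' @param ids Character vector of identifiers.
#' @param mapping Result of [read_ph73()] (or any named character vector).
#' @return Character vector, same length.
#' @export
apply_ph73 <- function(ids, mapping) {
  hit <- ids %in% names(mapping)
  ids[hit] <- unname(mapping[ids[hit]])
  ids
}
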