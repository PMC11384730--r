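#' Construct an annotated corpus
#'
#' An `ecr_corpus` holds a set of PubMed abstracts annotated with typed
#' entity mentions (chemicals, proteins, protein domains, mutant enzymes and
#' coreferences) and chemical-conversion relations (binary chemical pairs,
#' optionally linked to one or more "Converter" enzyme mentions). It is the
#' in-memory form of a BioC XML collection and the common currency of every
#' other function in the package.
#'
#' All components are tibbles so the object composes with dplyr directly:
#' `corpus$mentions |> count(entity_type)` works as expected.
#'
#' @param documents Tibble with columns `pmid` (character, unique) and
#'   optionally `infons` (list of named character vectors of document-level
#'   metadata).
#' @param passages Tibble with columns `pmid`, `offset` (0-based character
#'   offset of the passage in the whole document), `text`, and optionally
#'   `type` ("title"/"abstract").
#' @param mentions Tibble with columns `pmid`, `mention_id`, `start`, `end`
#'   (0-based, half-open, document-level offsets), `surface`, `entity_type`
#'   (one of Chemical, Protein, Domain, MutantEnzyme, Coreference) and
#'   `identifiers` (list of character vectors; a mention without identifiers
#'   carries the single empty string `""`).
#' @param relations Tibble with columns `pmid`, `relation_id`,
#'   `relation_type` (Conversion, Indirect_conversion or Non_conversion),
#'   `chem_a`, `chem_b` (mention ids) and `converters` (list of character
#'   vectors of mention ids, possibly empty).
#' @param provenance Free-text metadata string carried through serialization.
#'
#' @return An object of class `ecr_corpus`.
#' @seealso [read_bioc()], [write_bioc()], [validate_corpus()]
#' @export
#' @examples
#' corp <- ecr_corpus(
#'   documents = tibble::tibble(pmid = "1"),
#'   passages  = tibble::tibble(pmid = "1", offset = 0L,
#'                              text = "L-serine is an amino acid.",
#'                              type = "title"),
#'   mentions  = tibble::tibble(pmid = "1", mention_id = "m1",
#'                              start = 0L, end = 8L, surface = "L-serine",
#'                              entity_type = "Chemical",
#'                              identifiers = list("CHEBI:17115"))
#' )
#' corpus_statistics(corp)
ecr_corpus <- function(documents = NULL, passages = NULL, mentions = NULL,
                       relations = NULL, provenance = "enzchemkit") {
  corp <- structure(
    list(
      documents = normalize_documents(documents),
      passages  = normalize_passages(passages),
      mentions  = normalize_mentions_tbl(mentions),
      relations = normalize_relations_tbl(relations),
      provenance = provenance
    ),
    class = "ecr_corpus"
  )
  validate_corpus(corp)
}

empty_documents <- function() {
  tibble(pmid = character(), infons = list())
}

empty_passages <- function() {
  tibble(pmid = character(), offset = integer(), text = character(),
         type = character())
}

empty_mentions_tbl <- function() {
  tibble(pmid = character(), mention_id = character(), start = integer(),
         end = integer(), surface = character(), entity_type = character(),
         identifiers = list())
}

empty_relations_tbl <- function() {
  tibble(pmid = character(), relation_id = character(),
         relation_type = character(), chem_a = character(),
         chem_b = character(), converters = list())
}

normalize_documents <- function(x) {
  if (is.null(x) || nrow(x) == 0) return(empty_documents())
  x <- as_tibble(x)
  if (!"infons" %in% names(x)) x$infons <- rep(list(character()), nrow(x))
  x$pmid <- as.character(x$pmid)
  x[c("pmid", "infons")]
}

normalize_passages <- function(x) {
  if (is.null(x) || nrow(x) == 0) return(empty_passages())
  x <- as_tibble(x)
  if (!"type" %in% names(x)) x$type <- NA_character_
  x$pmid <- as.character(x$pmid)
  x$offset <- as.integer(x$offset)
  x[c("pmid", "offset", "text", "type")]
}

normalize_mentions_tbl <- function(x) {
  if (is.null(x) || nrow(x) == 0) return(empty_mentions_tbl())
  x <- as_tibble(x)
  if (!"identifiers" %in% names(x)) x$identifiers <- rep(list(""), nrow(x))
  x$identifiers <- lapply(x$identifiers, function(ids) {
    ids <- as.character(ids)
    if (length(ids) == 0) "" else ids
  })
  x$pmid <- as.character(x$pmid)
  x$mention_id <- as.character(x$mention_id)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x[c("pmid", "mention_id", "start", "end", "surface", "entity_type",
      "identifiers")]
}

normalize_relations_tbl <- function(x) {
  if (is.null(x) || nrow(x) == 0) return(empty_relations_tbl())
  x <- as_tibble(x)
  if (!"converters" %in% names(x)) x$converters <- rep(list(character()), nrow(x))
  x$converters <- lapply(x$converters, as.character)
  x$pmid <- as.character(x$pmid)
  x$relation_id <- as.character(x$relation_id)
  x[c("pmid", "relation_id", "relation_type", "chem_a", "chem_b",
      "converters")]
}

#' Validate the structural invariants of a corpus
#'
#' Checks that pmids are unique, passage offsets strictly increase within a
#' document, spans are well-formed (`0 <= start < end`) and match the passage
#' text, entity and relation types are drawn from the schema's closed sets,
#' and every relation participant resolves to an existing mention of a
#' compatible type. Relations referencing missing mentions are reported with
#' their pmid and relation id.
#'
#' @param corpus An `ecr_corpus`.
#' @return The corpus, invisibly usable in a pipe; errors on violation.
#' @export
validate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "ecr_corpus"))
  docs <- corpus$documents
  if (anyDuplicated(docs$pmid)) {
    abort(paste0("duplicate pmids in corpus: ",
                 paste(unique(docs$pmid[duplicated(docs$pmid)]), collapse = ", ")))
  }
  pas <- corpus$passages
  if (nrow(pas)) {
    bad <- pas |>
      group_by(.data$pmid) |>
      summarise(ok = all(diff(.data$offset) > 0) || n() == 1) |>
      filter(!.data$ok)
    if (nrow(bad)) {
      abort(paste0("passage offsets not strictly increasing for pmid ",
                   paste(bad$pmid, collapse = ", ")))
    }
    orphan <- setdiff(pas$pmid, docs$pmid)
    if (length(orphan)) abort(paste0("passages for unknown pmid: ",
                                     paste(orphan, collapse = ", ")))
  }
  men <- corpus$mentions
  if (nrow(men)) {
    if (any(men$start < 0 | men$start >= men$end)) {
      abort("mention spans must satisfy 0 <= start < end")
    }
    bad_type <- setdiff(unique(men$entity_type), ENTITY_TYPES)
    if (length(bad_type)) {
      abort(paste0("unknown entity type(s): ", paste(bad_type, collapse = ", ")))
    }
    if (anyDuplicated(paste(men$pmid, men$mention_id))) {
      abort("mention ids must be unique within a document")
    }
    # surface string must equal the document text at the recorded span
    for (pm in unique(men$pmid)) {
      txt <- document_text(corpus, pm)
      mm <- men[men$pmid == pm, ]
      got <- substring(txt, mm$start + 1L, mm$end)
      off <- which(got != mm$surface)
      if (length(off)) {
        abort(paste0("mention ", mm$mention_id[off[1]], " in pmid ", pm,
                     ": span text ", dQuote(got[off[1]]),
                     " does not match surface ", dQuote(mm$surface[off[1]])))
      }
    }
  }
  rel <- corpus$relations
  if (nrow(rel)) {
    bad_type <- setdiff(unique(rel$relation_type), RELATION_TYPES)
    if (length(bad_type)) {
      abort(paste0("unknown relation type(s): ",
                   paste(bad_type, collapse = ", "),
                   " ('None' is synthesized at instance enumeration, never stored)"))
    }
    for (i in seq_len(nrow(rel))) {
      r <- rel[i, ]
      ids <- men$mention_id[men$pmid == r$pmid]
      refs <- c(r$chem_a, r$chem_b, r$converters[[1]])
      missing <- setdiff(refs, ids)
      if (length(missing)) {
        abort(paste0("relation ", r$relation_id, " in pmid ", r$pmid,
                     " references missing mention(s): ",
                     paste(missing, collapse = ", ")))
      }
      if (r$chem_a == r$chem_b) {
        abort(paste0("relation ", r$relation_id, " in pmid ", r$pmid,
                     " links a mention to itself"))
      }
      for (m in c(r$chem_a, r$chem_b)) {
        row <- men[men$pmid == r$pmid & men$mention_id == m, ]
        if (!ref_is_chemical(row$entity_type, row$identifiers[[1]])) {
          abort(paste0("relation ", r$relation_id, " in pmid ", r$pmid,
                       ": participant ", m, " is not a chemical mention"))
        }
      }
      for (m in r$converters[[1]]) {
        row <- men[men$pmid == r$pmid & men$mention_id == m, ]
        if (!row$entity_type %in% c("Protein", "Domain", "MutantEnzyme",
                                    "Coreference")) {
          abort(paste0("relation ", r$relation_id, " in pmid ", r$pmid,
                       ": converter ", m, " is not a protein-like mention"))
        }
      }
    }
  }
  invisible(corpus)
}

#' Reconstruct the full document text from its passages
#'
#' Passage texts are placed at their recorded offsets; any gap between
#' passages (conventionally a single separator character) is filled with
#' spaces, so mention offsets index directly into the returned string.
#'
#' @param corpus An `ecr_corpus`.
#' @param pmid Document identifier.
#' @return A single string.
#' @export
document_text <- function(corpus, pmid) {
  text_from_passages(corpus$passages[corpus$passages$pmid == pmid, ])
}

text_from_passages <- function(pas) {
  if (nrow(pas) == 0) return("")
  total <- max(pas$offset + nchar(pas$text))
  out <- strrep(" ", total)
  for (i in seq_len(nrow(pas))) {
    substr(out, pas$offset[i] + 1L, pas$offset[i] + nchar(pas$text[i])) <-
      pas$text[i]
  }
  out
}

#' @export
print.ecr_corpus <- function(x, ...) {
  cat("<ecr_corpus> ", nrow(x$documents), " document(s), ",
      nrow(x$mentions), " mention(s), ", nrow(x$relations), " relation(s)\n",
      sep = "")
  invisible(x)
}

#' @export
format.ecr_corpus <- function(x, ...) {
  paste0("<ecr_corpus: ", nrow(x$documents), " docs>")
}

# Field-level equality of two corpora, ignoring row order. Used by the
# round-trip tests and exported because it is the natural oracle for
# serialization identity.

#' Structural equality of two corpora
#'
#' Compares documents, passages, mentions and relations field by field,
#' ignoring row order. This is the round-trip oracle for
#' `read_bioc(write_bioc(x))`.
#'
#' @param a,b `ecr_corpus` objects.
#' @return TRUE or FALSE.
#' @export
corpus_identical <- function(a, b) {
  ord <- function(tb, cols) tb[do.call(order, unname(as.list(tb[cols]))), ]
  eq_tbl <- function(ta, tb, cols) {
    ta <- ord(ta, cols); tb <- ord(tb, cols)
    if (nrow(ta) != nrow(tb)) return(FALSE)
    for (cl in names(ta)) {
      va <- ta[[cl]]; vb <- tb[[cl]]
      if (is.list(va)) {
        same <- mapply(function(x, y) identical(sort(as.character(x)),
                                                sort(as.character(y))),
                       va, vb)
        if (!all(same)) return(FALSE)
      } else if (!identical(as.vector(va), as.vector(vb))) {
        return(FALSE)
      }
    }
    TRUE
  }
  eq_tbl(a$documents["pmid"], b$documents["pmid"], "pmid") &&
    eq_tbl(a$passages, b$passages, c("pmid", "offset")) &&
    eq_tbl(a$mentions, b$mentions, c("pmid", "mention_id")) &&
    eq_tbl(a$relations, b$relations, c("pmid", "relation_id"))
}
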