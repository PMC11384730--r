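#' Summary statistics of an annotated corpus
#'
#' Counts entity mentions, binary chemical pairs and ternary enzyme tuples,
#' both raw (every occurrence) and unique (deduplicated by identifier).
#' Uniqueness is identifier-based: a mention carrying several identifiers
#' contributes each of them to the unique tally for its entity type (the
#' empty string, marking an identifier-less mention, is never counted as an
#' identifier); pairs deduplicate as unordered pairs of identifier-set keys;
#' tuples additionally carry the converter's identifier key. The "All" row of
#' the pair and tuple blocks deduplicates across relation types, so it can be
#' smaller than the sum of its parts, whereas raw "All" counts are always
#' additive.
#'
#' @param corpus An `ecr_corpus`.
#' @return A tibble of class `ecr_stats` with columns `block`
#'   (`entity`/`binary_pair`/`ternary_tuple`), `type`, `n` and `n_unique`.
#' @export
#' @examples
#' corpus_statistics(ecr_corpus())
corpus_statistics <- function(corpus) {
  men <- corpus$mentions
  rel <- corpus$relations

  ent_types <- union(c("Chemical", "Protein"),
                     intersect(ENTITY_TYPES, unique(men$entity_type)))
  ent_types <- intersect(ENTITY_TYPES, ent_types) # schema order
  ent <- map(ent_types, function(tp) {
    mm <- men[men$entity_type == tp, ]
    ids <- unique(unlist(mm$identifiers))
    tibble(block = "entity", type = tp, n = nrow(mm),
           n_unique = sum(nzchar(ids)))
  }) |> bind_rows()
  ent_all <- tibble(block = "entity", type = "All",
                    n = sum(ent$n), n_unique = sum(ent$n_unique))

  pair_key_of <- function(r) {
    ka <- mention_idkey(men, r$pmid, r$chem_a)
    kb <- mention_idkey(men, r$pmid, r$chem_b)
    paste(sort(c(ka, kb)), collapse = "||")
  }
  pair_keys <- if (nrow(rel)) {
    vapply(seq_len(nrow(rel)), function(i) pair_key_of(rel[i, ]), character(1))
  } else character()

  pair_block <- map(RELATION_TYPES, function(tp) {
    sel <- rel$relation_type == tp
    tibble(block = "binary_pair", type = tp, n = sum(sel),
           n_unique = length(unique(pair_keys[sel])))
  }) |> bind_rows()
  pair_all <- tibble(block = "binary_pair", type = "All", n = nrow(rel),
                     n_unique = length(unique(pair_keys)))

  # one tuple per (relation, converter occurrence)
  tup <- if (nrow(rel)) {
    tibble(
      relation_type = rep(rel$relation_type, lengths(rel$converters)),
      key = unlist(lapply(seq_len(nrow(rel)), function(i) {
        cvs <- rel$converters[[i]]
        if (!length(cvs)) return(character())
        paste0(pair_keys[i], "##",
               vapply(cvs, function(cv) mention_idkey(men, rel$pmid[i], cv),
                      character(1)))
      }))
    )
  } else tibble(relation_type = character(), key = character())

  tup_block <- map(RELATION_TYPES, function(tp) {
    sel <- tup$relation_type == tp
    tibble(block = "ternary_tuple", type = tp, n = sum(sel),
           n_unique = length(unique(tup$key[sel])))
  }) |> bind_rows()
  tup_all <- tibble(block = "ternary_tuple", type = "All", n = nrow(tup),
                    n_unique = length(unique(tup$key)))

  out <- bind_rows(ent_all, ent, pair_all, pair_block, tup_all, tup_block)
  class(out) <- c("ecr_stats", class(out))
  out
}

mention_idkey <- function(mentions, pmid, mention_id) {
  ids <- mentions$identifiers[mentions$pmid == pmid &
                                mentions$mention_id == mention_id][[1]]
  paste(sort(unique(ids)), collapse = ",")
}

#' Inter-annotator agreement between two annotation copies
#'
#' Agreement between two independently annotated copies of the same document
#' set, reported as the F1 score between the two annotation sets (which is
#' symmetric in the two annotators). At `level = "entity"` a match requires
#' an identical span, entity type and identifier set; at
#' `level = "binary_pair"` it requires identical chemical spans and
#' identifier sets plus the same relation type.
#'
#' @param corpus_a,corpus_b `ecr_corpus` objects covering the same pmids.
#' @param level `"entity"` or `"binary_pair"`.
#' @return Agreement percentage in \[0, 100\].
#' @export
compute_iaa <- function(corpus_a, corpus_b,
                        level = c("entity", "binary_pair")) {
  level <- match.arg(level)
  pa <- corpus_a$documents$pmid
  pb <- corpus_b$documents$pmid
  if (!setequal(pa, pb)) {
    abort(paste0("corpora cover different pmids; only in a: ",
                 paste(setdiff(pa, pb), collapse = ", "),
                 "; only in b: ", paste(setdiff(pb, pa), collapse = ", ")))
  }
  keys <- switch(level,
    entity = list(entity_keys(corpus_a), entity_keys(corpus_b)),
    binary_pair = list(pair_match_keys(corpus_a), pair_match_keys(corpus_b))
  )
  a <- unique(keys[[1]]); b <- unique(keys[[2]])
  if (length(a) == 0 && length(b) == 0) return(100)
  tp <- length(intersect(a, b))
  100 * 2 * tp / (length(a) + length(b))
}

entity_keys <- function(corpus) {
  men <- corpus$mentions
  if (!nrow(men)) return(character())
  paste(men$pmid, men$start, men$end, men$entity_type,
        id_key(men$identifiers), sep = "|")
}

pair_match_keys <- function(corpus) {
  rel <- corpus$relations
  men <- corpus$mentions
  if (!nrow(rel)) return(character())
  vapply(seq_len(nrow(rel)), function(i) {
    r <- rel[i, ]
    side <- function(m) {
      row <- men[men$pmid == r$pmid & men$mention_id == m, ]
      paste(row$start, row$end, id_key(row$identifiers), sep = ";")
    }
    paste(r$pmid, paste(sort(c(side(r$chem_a), side(r$chem_b))),
                        collapse = "~"),
          r$relation_type, sep = "|")
  }, character(1))
}
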