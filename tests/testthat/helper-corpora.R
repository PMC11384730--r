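# Hand-construction helpers: build a corpus from plain title/abstract
# strings, locating mention surfaces in the text so spans never have to be
# counted by hand.

mk_corpus <- function(docs, provenance = "test") {
  documents <- tibble::tibble(pmid = character())
  passages <- tibble::tibble(pmid = character(), offset = integer(),
                             text = character(), type = character())
  mentions <- tibble::tibble(pmid = character(), mention_id = character(),
                             start = integer(), end = integer(),
                             surface = character(), entity_type = character(),
                             identifiers = list())
  relations <- tibble::tibble(pmid = character(), relation_id = character(),
                              relation_type = character(),
                              chem_a = character(), chem_b = character(),
                              converters = list())
  for (d in docs) {
    documents <- tibble::add_row(documents, pmid = d$pmid)
    title <- d$title %||% ""
    abstract <- d$abstract %||% ""
    passages <- tibble::add_row(passages, pmid = d$pmid, offset = 0L,
                                text = title, type = "title")
    if (nzchar(abstract)) {
      passages <- tibble::add_row(passages, pmid = d$pmid,
                                  offset = nchar(title) + 1L,
                                  text = abstract, type = "abstract")
    }
    full <- paste0(title, " ", abstract)
    for (m in d$mentions %||% list()) {
      occ <- m$n %||% 1L
      hits <- gregexpr(m$surface, full, fixed = TRUE)[[1]]
      stopifnot(hits[1] != -1, length(hits) >= occ)
      start <- hits[occ] - 1L
      mentions <- tibble::add_row(
        mentions, pmid = d$pmid, mention_id = m$id,
        start = start, end = start + nchar(m$surface),
        surface = m$surface, entity_type = m$type %||% "Chemical",
        identifiers = list(m$ids %||% "")
      )
    }
    for (r in d$relations %||% list()) {
      relations <- tibble::add_row(
        relations, pmid = d$pmid, relation_id = r$id,
        relation_type = r$type, chem_a = r$a, chem_b = r$b,
        converters = list(r$conv %||% character())
      )
    }
  }
  ecr_corpus(documents, passages, mentions, relations,
             provenance = provenance)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# The tautomerase abstract pattern: one enzyme converting a chemical (with a
# parenthesized synonym) into a product -- three chemicals, two curated
# conversions sharing the product.
dopachrome_doc <- function() {
  list(
    pmid = "9480844",
    title = "Tautomerase activity.",
    abstract = paste0("DDT converts 2-carboxy-2,3-dihydroindole-5,6-quinone ",
                      "(D-dopachrome) into 5,6-dihydroxyindole."),
    mentions = list(
      list(id = "p1", surface = "DDT", type = "Protein", ids = "P30046"),
      list(id = "c1", surface = "2-carboxy-2,3-dihydroindole-5,6-quinone",
           ids = "CHEBI:75846"),
      list(id = "c2", surface = "D-dopachrome", ids = "CHEBI:75846"),
      list(id = "c3", surface = "5,6-dihydroxyindole", ids = "CHEBI:27404")
    ),
    relations = list(
      list(id = "R1", type = "Conversion", a = "c1", b = "c3", conv = "p1"),
      list(id = "R2", type = "Conversion", a = "c2", b = "c3", conv = "p1")
    )
  )
}
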