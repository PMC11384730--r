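#' Read a BioC XML collection
#'
#' Parses a PubTator-style BioC XML file into an [ecr_corpus()]. Annotations
#' are expected to carry `type` and `identifier` infons; relations reference
#' annotation ids through `<node refid=... role=.../>` elements, with roles
#' taken from `dialect` (the serialization keys are configurable because the
#' released data's keys are a convention, not part of the schema). Unknown
#' document-level infons are preserved in `documents$infons`.
#'
#' Offsets follow the BioC convention: 0-based character offsets into the
#' whole document, with each passage's `<offset>` giving the position of its
#' text.
#'
#' A BioC annotation with several `<location>` elements (a discontinuous
#' mention) is split into one mention per location, all sharing the
#' annotation's identifiers.
#'
#' @param path Path to a BioC XML file.
#' @param dialect Named list of relation role keys, see [bioc_dialect()].
#' @return An `ecr_corpus`.
#' @export
read_bioc <- function(path, dialect = bioc_dialect()) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) abort(paste0("malformed BioC XML in ", path, ": ",
                                     conditionMessage(e)))
  )
  docs <- xml2::xml_find_all(doc, ".//document")
  doc_rows <- list(); pas_rows <- list(); men_rows <- list()
  rel_rows <- list()
  prov <- xml2::xml_text(xml2::xml_find_first(doc, "./source"))
  if (is.na(prov)) prov <- ""

  for (d in docs) {
    pmid <- xml2::xml_text(xml2::xml_find_first(d, "./id"))
    doc_infons <- read_infons(d, exclude = character())
    doc_rows[[length(doc_rows) + 1L]] <-
      tibble(pmid = pmid, infons = list(doc_infons))

    for (p in xml2::xml_find_all(d, "./passage")) {
      p_inf <- read_infons(p)
      p_text <- xml2::xml_text(xml2::xml_find_first(p, "./text"))
      pas_rows[[length(pas_rows) + 1L]] <- tibble(
        pmid = pmid,
        offset = as.integer(xml2::xml_text(xml2::xml_find_first(p, "./offset"))),
        text = if (is.na(p_text)) "" else p_text,
        type = infon_get(p_inf, "type")
      )
      for (a in xml2::xml_find_all(p, "./annotation")) {
        men_rows[[length(men_rows) + 1L]] <- read_mention_rows(a, pmid)
      }
    }
    rel_nodes <- c(xml2::xml_find_all(d, "./relation"),
                   xml2::xml_find_all(d, "./passage/relation"))
    for (r in rel_nodes) {
      inf <- read_infons(r)
      nodes <- xml2::xml_find_all(r, "./node")
      roles <- xml2::xml_attr(nodes, "role")
      refs <- xml2::xml_attr(nodes, "refid")
      chem_a <- refs[roles == dialect$chem_a]
      chem_b <- refs[roles == dialect$chem_b]
      conv <- refs[roles == dialect$converter]
      rid <- xml2::xml_attr(r, "id")
      if (length(chem_a) != 1 || length(chem_b) != 1) {
        abort(paste0("relation ", rid, " in pmid ", pmid,
                     " must have exactly one ", dialect$chem_a, " and one ",
                     dialect$chem_b, " node"))
      }
      rel_rows[[length(rel_rows) + 1L]] <- tibble(
        pmid = pmid, relation_id = rid,
        relation_type = infon_get(inf, "type"),
        chem_a = chem_a, chem_b = chem_b, converters = list(conv)
      )
    }
  }
  documents <- if (length(doc_rows)) bind_rows(doc_rows) else
    empty_documents()
  passages <- if (length(pas_rows)) bind_rows(pas_rows) else
    empty_passages()
  mentions <- if (length(men_rows)) bind_rows(men_rows) else
    empty_mentions_tbl()
  relations <- if (length(rel_rows)) bind_rows(rel_rows) else
    empty_relations_tbl()
  # discontinuous annotations were split into per-location mentions whose
  # surface is only known once all passages are read: recover it now
  if (nrow(mentions) && anyNA(mentions$surface)) {
    for (i in which(is.na(mentions$surface))) {
      txt <- text_from_passages(passages[passages$pmid == mentions$pmid[i], ])
      mentions$surface[i] <- substring(txt, mentions$start[i] + 1L,
                                       mentions$end[i])
    }
  }
  ecr_corpus(documents, passages, mentions, relations, provenance = prov)
}

read_infons <- function(node, exclude = character()) {
  infs <- xml2::xml_find_all(node, "./infon")
  keys <- xml2::xml_attr(infs, "key")
  vals <- xml2::xml_text(infs)
  keep <- !keys %in% exclude
  setNames(vals[keep], keys[keep])
}

infon_get <- function(infons, key) {
  if (key %in% names(infons)) infons[[key]] else NA_character_
}

read_mention_rows <- function(a, pmid) {
  inf <- read_infons(a)
  idstr <- infon_get(inf, "identifier")
  if (is.na(idstr)) idstr <- ""
  ids <- strsplit(idstr, ",", fixed = TRUE)[[1]]
  if (length(ids) == 0) ids <- ""
  locs <- xml2::xml_find_all(a, "./location")
  aid <- xml2::xml_attr(a, "id")
  surface <- xml2::xml_text(xml2::xml_find_first(a, "./text"))
  starts <- as.integer(xml2::xml_attr(locs, "offset"))
  lens <- as.integer(xml2::xml_attr(locs, "length"))
  n <- length(locs)
  # discontinuous annotations become one mention per location; the surface
  # of each piece is recovered later from the document text, so for the
  # (typical) single-location case we use the annotation text directly.
  tibble(
    pmid = pmid,
    mention_id = if (n == 1) aid else paste0(aid, ".", seq_len(n)),
    start = starts, end = starts + lens,
    surface = if (n == 1) surface else NA_character_,
    entity_type = infon_get(inf, "type"),
    identifiers = rep(list(ids), n)
  )
}

#' Relation role keys used in BioC serialization
#'
#' @param chem_a,chem_b Role labels of the two chemical participants.
#' @param converter Role label of enzyme participants.
#' @return A named list.
#' @export
bioc_dialect <- function(chem_a = "Chemical1", chem_b = "Chemical2",
                         converter = "Converter") {
  list(chem_a = chem_a, chem_b = chem_b, converter = converter)
}

#' Write a corpus as BioC XML
#'
#' Inverse of [read_bioc()]: `read_bioc(write_bioc(x))` is structurally
#' identical to `x` (see [corpus_identical()]). Mentions are serialized as
#' annotations inside the passage containing their span, with `type` and
#' `identifier` infons (an identifier-less mention writes the empty string,
#' matching how such mentions are treated in evaluation); relations are
#' serialized at document level with role-labelled nodes.
#'
#' @param corpus An `ecr_corpus`.
#' @param path Output file path.
#' @param dialect Role keys, see [bioc_dialect()].
#' @return `path`, invisibly.
#' @export
write_bioc <- function(corpus, path, dialect = bioc_dialect()) {
  validate_corpus(corpus)
  root <- xml2::xml_new_root("collection")
  xml2::xml_add_child(root, "source", corpus$provenance %||% "")
  xml2::xml_add_child(root, "date", "")
  xml2::xml_add_child(root, "key", "enzchemkit.key")
  for (i in seq_len(nrow(corpus$documents))) {
    pm <- corpus$documents$pmid[i]
    d <- xml2::xml_add_child(root, "document")
    xml2::xml_add_child(d, "id", pm)
    for (key in names(corpus$documents$infons[[i]])) {
      inf <- xml2::xml_add_child(d, "infon", corpus$documents$infons[[i]][[key]])
      xml2::xml_set_attr(inf, "key", key)
    }
    pas <- corpus$passages[corpus$passages$pmid == pm, ]
    men <- corpus$mentions[corpus$mentions$pmid == pm, ]
    for (j in seq_len(nrow(pas))) {
      p <- xml2::xml_add_child(d, "passage")
      if (!is.na(pas$type[j])) {
        inf <- xml2::xml_add_child(p, "infon", pas$type[j])
        xml2::xml_set_attr(inf, "key", "type")
      }
      xml2::xml_add_child(p, "offset", as.character(pas$offset[j]))
      xml2::xml_add_child(p, "text", pas$text[j])
      p_end <- pas$offset[j] + nchar(pas$text[j])
      inside <- men[men$start >= pas$offset[j] & men$end <= p_end, ]
      for (k in seq_len(nrow(inside))) {
        a <- xml2::xml_add_child(p, "annotation")
        xml2::xml_set_attr(a, "id", inside$mention_id[k])
        it <- xml2::xml_add_child(a, "infon", inside$entity_type[k])
        xml2::xml_set_attr(it, "key", "type")
        ii <- xml2::xml_add_child(
          a, "infon", paste(inside$identifiers[[k]], collapse = ","))
        xml2::xml_set_attr(ii, "key", "identifier")
        loc <- xml2::xml_add_child(a, "location")
        xml2::xml_set_attr(loc, "offset", as.character(inside$start[k]))
        xml2::xml_set_attr(loc, "length",
                           as.character(inside$end[k] - inside$start[k]))
        xml2::xml_add_child(a, "text", inside$surface[k])
      }
      covered <- men$start >= pas$offset[j] & men$end <= p_end
      men <- men[!covered, ]
    }
    if (nrow(men)) {
      abort(paste0("mention(s) ", paste(men$mention_id, collapse = ", "),
                   " in pmid ", pm,
                   " fall outside every passage and cannot be serialized"))
    }
    rel <- corpus$relations[corpus$relations$pmid == pm, ]
    for (k in seq_len(nrow(rel))) {
      r <- xml2::xml_add_child(d, "relation")
      xml2::xml_set_attr(r, "id", rel$relation_id[k])
      it <- xml2::xml_add_child(r, "infon", rel$relation_type[k])
      xml2::xml_set_attr(it, "key", "type")
      add_node <- function(refid, role) {
        nd <- xml2::xml_add_child(r, "node")
        xml2::xml_set_attr(nd, "refid", refid)
        xml2::xml_set_attr(nd, "role", role)
      }
      add_node(rel$chem_a[k], dialect$chem_a)
      add_node(rel$chem_b[k], dialect$chem_b)
      for (cv in rel$converters[[k]]) add_node(cv, dialect$converter)
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}
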