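# Deterministic synthetic fixtures. Generated corpora follow the annotation
# schema exactly and come with a ledger of planted counts, so corpus
# statistics, encoders and evaluators can be checked against exact expected
# values without any external data.

CHEM_POOL <- tibble::tibble(
  name = c("L-serine", "pyruvate", "glycine", "acetaldehyde", "ethanol",
           "fumarate", "succinate", "mesaconate", "glyoxylate",
           "oxaloacetate", "citrate", "isocitrate"),
  id = c("CHEBI:17115", "CHEBI:15361", "CHEBI:57305", "CHEBI:15343",
         "CHEBI:16236", "CHEBI:29806", "CHEBI:30031", "CHEBI:36986",
         "CHEBI:36655", "CHEBI:16452", "CHEBI:16947", "CHEBI:30887")
)

PROT_POOL <- tibble::tibble(
  name = c("AbcD1", "YhfQ", "SerC", "MdpJ", "PucG", "CdoA"),
  id = sprintf("P%05d", 11111 * 1:6)
)

# A template is a list of parts; character parts are literals, list parts
# plant a mention. Returns text, mentions (relative offsets) and relations
# (by slot name).
build_sentence <- function(parts) {
  text <- ""
  slot <- character(); start <- integer(); end <- integer()
  surface <- character(); etype <- character(); id <- character()
  for (p in parts) {
    if (is.character(p)) {
      text <- paste0(text, p)
    } else {
      slot <- c(slot, p$slot)
      start <- c(start, nchar(text))
      text <- paste0(text, p$name)
      end <- c(end, nchar(text))
      surface <- c(surface, p$name)
      etype <- c(etype, p$type)
      id <- c(id, p$id)
    }
  }
  list(text = text,
       mentions = tibble(slot = slot, start = start, end = end,
                         surface = surface, entity_type = etype, id = id))
}

chem_part <- function(slot, row) {
  list(slot = slot, name = row$name, type = "Chemical", id = row$id)
}
prot_part <- function(slot, row) {
  list(slot = slot, name = row$name, type = "Protein", id = row$id)
}

# Template library: each entry builds one sentence and declares its planted
# relations as (type, chem slots, converter slots). The forms mirror common
# enzymology phrasings, including the substrates-then-products
# "respectively" construction that is a known hard case for relation
# classifiers.
sentence_templates <- function() {
  list(
    conversion_enzyme = function(chems, prots) {
      s <- build_sentence(list(
        prot_part("p1", prots[1, ]), " converts ",
        chem_part("c1", chems[1, ]), " into ",
        chem_part("c2", chems[2, ]), "."
      ))
      s$relations <- list(list(type = "Conversion", chems = c("c1", "c2"),
                               converters = "p1"))
      s
    },
    conversion_plain = function(chems, prots) {
      s <- build_sentence(list(
        chem_part("c1", chems[1, ]), " is converted to ",
        chem_part("c2", chems[2, ]), " by the purified enzyme."
      ))
      s$relations <- list(list(type = "Conversion", chems = c("c1", "c2"),
                               converters = character()))
      s
    },
    conversion_respectively = function(chems, prots) {
      s <- build_sentence(list(
        prot_part("p1", prots[1, ]), " formed ",
        chem_part("c1", chems[1, ]), " and ",
        chem_part("c2", chems[2, ]), " from ",
        chem_part("c3", chems[3, ]), " and ",
        chem_part("c4", chems[4, ]), ", respectively."
      ))
      s$relations <- list(
        list(type = "Conversion", chems = c("c3", "c1"), converters = "p1"),
        list(type = "Conversion", chems = c("c4", "c2"), converters = "p1")
      )
      s
    },
    indirect = function(chems, prots) {
      s <- build_sentence(list(
        chem_part("c1", chems[1, ]), " is converted to ",
        chem_part("c2", chems[2, ]),
        " via a series of phosphorylated intermediates."
      ))
      s$relations <- list(list(type = "Indirect_conversion",
                               chems = c("c1", "c2"),
                               converters = character()))
      s
    },
    non_conversion = function(chems, prots) {
      s <- build_sentence(list(
        prot_part("p1", prots[1, ]), " did not convert ",
        chem_part("c1", chems[1, ]), " into ",
        chem_part("c2", chems[2, ]),
        " under any of the conditions tested."
      ))
      s$relations <- list(list(type = "Non_conversion",
                               chems = c("c1", "c2"),
                               converters = character()))
      s
    }
  )
}

#' Generate a deterministic synthetic corpus with a count ledger
#'
#' Builds schema-valid annotated abstracts from enzymology sentence
#' templates ("P converts C1 into C2", substrates/products linked by
#' "respectively", negated conversions, pathway-level interconversions).
#' Each document has a title passage introducing a protein and an abstract
#' passage of `relations_per_doc` relation-bearing sentences. The returned
#' ledger records the exact planted counts, which `corpus_statistics()`
#' must reproduce. Generation is a pure function of `(seed, config)`.
#'
#' @param n_docs Number of documents.
#' @param relations_per_doc Relation sentences per document.
#' @param relation_mix Named probabilities over the three relation types.
#' @param ternary_fraction Probability that a Conversion sentence names the
#'   catalysing enzyme (yielding a ternary tuple).
#' @param respectively_fraction Probability that an enzyme-bearing
#'   Conversion sentence uses the two-pair "respectively" construction.
#' @param seed Integer seed.
#' @return A list with `corpus` (an `ecr_corpus`) and `ledger` (a list of
#'   planted counts: `n_docs`, `mentions` by entity type, `relations` by
#'   type, `tuples` by type).
#' @export
generate_corpus <- function(n_docs = 5, relations_per_doc = 2,
                            relation_mix = c(Conversion = 0.7,
                                             Indirect_conversion = 0.2,
                                             Non_conversion = 0.1),
                            ternary_fraction = 0.6,
                            respectively_fraction = 0.15,
                            seed = 1) {
  stopifnot(abs(sum(relation_mix) - 1) < 1e-8,
            all(relation_mix >= 0),
            all(names(relation_mix) %in% RELATION_TYPES))
  tmpl <- sentence_templates()
  with_seed(seed, {
    doc_rows <- list(); pas_rows <- list(); men_rows <- list()
    rel_rows <- list()
    led_m <- setNames(rep(0L, length(ENTITY_TYPES)), ENTITY_TYPES)
    led_r <- setNames(rep(0L, 3), RELATION_TYPES)
    led_t <- setNames(rep(0L, 3), RELATION_TYPES)

    for (d in seq_len(n_docs)) {
      pmid <- sprintf("9%06d", d)
      title_prot <- PROT_POOL[sample(nrow(PROT_POOL), 1), ]
      title <- build_sentence(list(
        "Characterization of ", prot_part("tp", title_prot), "."
      ))
      abs_sents <- list()
      for (k in seq_len(relations_per_doc)) {
        rtype <- sample(names(relation_mix), 1, prob = relation_mix)
        tname <- switch(rtype,
          Conversion = {
            if (runif(1) < ternary_fraction) {
              if (runif(1) < respectively_fraction) {
                "conversion_respectively"
              } else "conversion_enzyme"
            } else "conversion_plain"
          },
          Indirect_conversion = "indirect",
          Non_conversion = "non_conversion"
        )
        chems <- CHEM_POOL[sample(nrow(CHEM_POOL), 4), ]
        prots <- PROT_POOL[sample(nrow(PROT_POOL), 1), ]
        abs_sents[[k]] <- tmpl[[tname]](chems, prots)
      }
      title_text <- title$text
      abstract_text <- paste(vapply(abs_sents, `[[`, character(1), "text"),
                             collapse = " ")
      abs_offset <- nchar(title_text) + 1L
      pas_rows[[length(pas_rows) + 1L]] <- tibble(
        pmid = pmid, offset = c(0L, abs_offset),
        text = c(title_text, abstract_text),
        type = c("title", "abstract")
      )
      doc_rows[[length(doc_rows) + 1L]] <-
        tibble(pmid = pmid, infons = list(character()))

      # flat per-document mention accumulators
      m_id <- character(); m_start <- integer(); m_end <- integer()
      m_surf <- character(); m_type <- character(); m_ids <- list()
      mcount <- 0L
      add_mentions <- function(mens, base) {
        n <- nrow(mens)
        ids <- paste0("T", mcount + seq_len(n))
        mcount <<- mcount + n
        m_id <<- c(m_id, ids)
        m_start <<- c(m_start, base + mens$start)
        m_end <<- c(m_end, base + mens$end)
        m_surf <<- c(m_surf, mens$surface)
        m_type <<- c(m_type, mens$entity_type)
        m_ids <<- c(m_ids, as.list(mens$id))
        for (tp in mens$entity_type) led_m[tp] <<- led_m[tp] + 1L
        setNames(ids, mens$slot)
      }
      add_mentions(title$mentions, 0L)
      rcount <- 0L
      cursor <- abs_offset
      for (s in abs_sents) {
        slot_ids <- add_mentions(s$mentions, cursor)
        for (r in s$relations) {
          rcount <- rcount + 1L
          conv_ids <- unname(slot_ids[r$converters])
          rel_rows[[length(rel_rows) + 1L]] <- tibble(
            pmid = pmid, relation_id = paste0("R", rcount),
            relation_type = r$type,
            chem_a = unname(slot_ids[r$chems[1]]),
            chem_b = unname(slot_ids[r$chems[2]]),
            converters = list(conv_ids)
          )
          led_r[r$type] <- led_r[r$type] + 1L
          led_t[r$type] <- led_t[r$type] + length(conv_ids)
        }
        cursor <- cursor + nchar(s$text) + 1L
      }
      men_rows[[length(men_rows) + 1L]] <- tibble(
        pmid = pmid, mention_id = m_id, start = m_start, end = m_end,
        surface = m_surf, entity_type = m_type, identifiers = m_ids
      )
    }
    documents <- if (length(doc_rows)) bind_rows(doc_rows) else NULL
    passages <- if (length(pas_rows)) bind_rows(pas_rows) else NULL
    mentions <- if (length(men_rows)) bind_rows(men_rows) else NULL
    relations <- if (length(rel_rows)) bind_rows(rel_rows) else NULL
    corpus <- ecr_corpus(documents, passages, mentions, relations,
                         provenance = paste0("enzchemkit synthetic seed=", seed))
    list(corpus = corpus,
         ledger = list(n_docs = n_docs, mentions = led_m,
                       relations = led_r, tuples = led_t))
  })
}

#' Plant annotation errors in a corpus, with an exact error ledger
#'
#' Produces a corrupted copy of a corpus together with the exact planted
#' error counts, so evaluation functions can be checked against closed-form
#' precision/recall. Corruptions, applied to Chemical/Protein mentions:
#' dropped mentions (only mentions not participating in any relation are
#' eligible, keeping the corpus valid; capped with a warning if fewer are
#' available), spurious mentions (new spans over unannotated words),
#' identifier substitutions (span kept, identifiers replaced — invisible to
#' recognition scoring, an error for normalization scoring), and relation
#' label flips.
#'
#' Against the original as gold, the corrupted copy scores exactly:
#' recognition `tp = n_eval - n_dropped`, `fp = n_spurious`,
#' `fn = n_dropped`; normalization additionally moves each substituted
#' mention from tp to one fp plus one fn.
#'
#' @param corpus An `ecr_corpus`.
#' @param n_drop,n_spurious,n_substitute,n_flip Error counts to plant.
#' @param seed Integer seed.
#' @return A list with `corpus` (corrupted copy) and `ledger` (actual
#'   planted counts plus the implied recognition/normalization tp/fp/fn).
#' @export
corrupt_corpus <- function(corpus, n_drop = 0, n_spurious = 0,
                           n_substitute = 0, n_flip = 0, seed = 1) {
  with_seed(seed, {
    men <- corpus$mentions
    rel <- corpus$relations
    eval_rows <- which(men$entity_type %in% c("Chemical", "Protein"))

    in_relation <- unique(unlist(lapply(seq_len(nrow(rel)), function(i) {
      paste(rel$pmid[i],
            c(rel$chem_a[i], rel$chem_b[i], rel$converters[[i]]))
    })))
    droppable <- eval_rows[!paste(men$pmid[eval_rows],
                                  men$mention_id[eval_rows]) %in% in_relation]
    if (n_drop > length(droppable)) {
      warn(paste0("only ", length(droppable),
                  " mention(s) can be dropped without breaking relations; ",
                  "capping n_drop"))
      n_drop <- length(droppable)
    }
    drop_idx <- if (n_drop > 0) sample(droppable, n_drop) else integer()

    sub_pool <- setdiff(eval_rows, drop_idx)
    if (n_substitute > length(sub_pool)) {
      warn("capping n_substitute to available mentions")
      n_substitute <- length(sub_pool)
    }
    sub_idx <- if (n_substitute > 0) sample(sub_pool, n_substitute) else integer()
    for (j in seq_along(sub_idx)) {
      men$identifiers[[sub_idx[j]]] <- sprintf("CHEBI:990%03d", j)
    }

    if (length(drop_idx)) men <- men[-drop_idx, ]

    # spurious mentions over unannotated alphabetic tokens
    added <- 0L
    for (pm in corpus$documents$pmid) {
      if (added >= n_spurious) break
      txt <- document_text(corpus, pm)
      toks <- segment_text(txt)
      toks <- toks[nchar(toks$surface) >= 3 &
                     grepl("^[a-z]+$", toks$surface), ]
      # spans must be free both in the corrupted copy and in the original
      # (a spurious mention recreating a dropped gold span would silently
      # turn a planted fp+fn into a tp)
      mm <- bind_rows(men[men$pmid == pm, c("start", "end")],
                      corpus$mentions[corpus$mentions$pmid == pm,
                                      c("start", "end")])
      free <- vapply(seq_len(nrow(toks)), function(i) {
        !any(mm$start < toks$end[i] & mm$end > toks$start[i])
      }, logical(1))
      toks <- toks[free, ]
      if (!nrow(toks)) next
      take <- head(seq_len(nrow(toks)), n_spurious - added)
      for (i in take) {
        added <- added + 1L
        men <- add_row(men, pmid = pm,
                       mention_id = paste0("SP", added),
                       start = toks$start[i], end = toks$end[i],
                       surface = toks$surface[i],
                       entity_type = sample(c("Chemical", "Protein"), 1),
                       identifiers = list(sprintf("CHEBI:880%03d", added)))
      }
    }
    if (added < n_spurious) {
      warn(paste0("only ", added, " spurious mention(s) could be planted"))
    }

    flip_pool <- seq_len(nrow(rel))
    if (n_flip > length(flip_pool)) {
      warn("capping n_flip to available relations")
      n_flip <- length(flip_pool)
    }
    flip_idx <- if (n_flip > 0) sample(flip_pool, n_flip) else integer()
    for (i in flip_idx) {
      rel$relation_type[i] <- sample(setdiff(RELATION_TYPES,
                                             rel$relation_type[i]), 1)
    }

    out <- ecr_corpus(corpus$documents, corpus$passages, men, rel,
                      provenance = corpus$provenance)
    n_eval <- length(eval_rows)
    ledger <- list(
      n_dropped = n_drop, n_spurious = added,
      n_substituted = n_substitute, n_flipped = n_flip,
      ner = list(tp = n_eval - n_drop, fp = added, fn = n_drop),
      nen = list(tp = n_eval - n_drop - n_substitute,
                 fp = added + n_substitute,
                 fn = n_drop + n_substitute)
    )
    list(corpus = out, ledger = ledger)
  })
}

#' Generate the chemistry-side fixtures
#'
#' Returns a coherent toy set of every tabular input the chemistry modules
#' consume: two lexicons (a ChEBI-style target and a MeSH-style second
#' lexicon sharing structural keys, with planted cases for every sieve
#' step), an idempotent pH 7.3 mapping with an acid-to-anion row, a small
#' reaction set including a ubiquitous cofactor (present in every reaction)
#' and an identical-id transport reaction, a SMILES table, and an acyclic
#' three-level ontology fragment for relaxed identifier matching. The
#' `sieve_cases` ledger lists each planted term with the sieve step and
#' candidate ids it must resolve to.
#'
#' @param seed Integer seed (the fixture content is fixed; the seed is
#'   accepted for interface uniformity and reserved for future randomized
#'   variants).
#' @return Named list: `lexicons`, `ph73`, `reactions`, `smiles`,
#'   `ontology`, `sieve_cases`.
#' @export
generate_chem_fixtures <- function(seed = 1) {
  chebi <- ecr_lexicon(
    "CHEBI",
    synonyms = tibble(
      id = c("CHEBI:17115", "CHEBI:17115", "CHEBI:15361", "CHEBI:16236",
             "CHEBI:15343", "CHEBI:17234", "CHEBI:17790", "CHEBI:15366"),
      synonym = c("L-serine", "serine", "pyruvate", "ethanol",
                  "acetaldehyde", "glucose", "methanol", "acetic acid")
    ),
    xrefs = tibble(
      id = c("CHEBI:17790", "CHEBI:16236"),
      xref_type = c("InChIKey", "InChIKey"),
      value = c("OKKJLVBELUTLKV-UHFFFAOYSA-N", "LFQSCWFLJHTTHZ-UHFFFAOYSA-N")
    )
  )
  mesh <- ecr_lexicon(
    "MESH",
    synonyms = tibble(
      id = c("MESH:D012694", "MESH:D012694", "MESH:D000432", "MESH:D000432"),
      synonym = c("serine", "ser", "methyl alcohol", "wood alcohol")
    ),
    xrefs = tibble(
      id = c("MESH:D012694", "MESH:D000432"),
      xref_type = c("CHEBI", "InChIKey"),
      value = c("CHEBI:17115", "OKKJLVBELUTLKV-UHFFFAOYSA-N")
    )
  )
  sieve_cases <- tibble(
    term = c("L-serine", "Serine,", "pyruvates", "ser", "wood alcohol",
             "wood alcohols", "unobtainium"),
    step = c(1L, 2L, 3L, 4L, 4L, 5L, 0L),
    id = c("CHEBI:17115", "CHEBI:17115", "CHEBI:15361", "CHEBI:17115",
           "CHEBI:17790", "CHEBI:17790", NA),
    via = c("direct", "direct", "direct", "single", "pivot:InChIKey",
            "pivot:InChIKey", NA)
  )
  ph73 <- structure(
    c("CHEBI:15366" = "CHEBI:30089",  # acetic acid -> acetate
      "CHEBI:30089" = "CHEBI:30089",
      "CHEBI:17234" = "CHEBI:17234"),
    class = "ecr_ph73"
  )
  water <- "CHEBI:15377"
  reactions <- tibble(
    rhea_id = c("RHEA:1", "RHEA:1", "RHEA:1",
                "RHEA:2", "RHEA:2", "RHEA:2",
                "RHEA:3", "RHEA:3", "RHEA:3",
                "RHEA:4", "RHEA:4", "RHEA:4",
                "RHEA:5", "RHEA:5"),
    side = c("left", "left", "right",
             "left", "right", "right",
             "left", "left", "right",
             "left", "right", "right",
             "left", "right"),
    chebi_id = c("CHEBI:16236", water, "CHEBI:15343",
                 "CHEBI:15361", water, "CHEBI:15343",
                 "CHEBI:17234", water, "CHEBI:15361",
                 "CHEBI:30089", water, "CHEBI:16236",
                 water, water),  # RHEA:5 is a water transport reaction
    coefficient = 1
  )
  smiles <- tibble(
    chebi_id = c("CHEBI:16236", "CHEBI:15343", "CHEBI:16183", "CHEBI:30089",
                 "CHEBI:15361", water),
    smiles = c("CCO", "CC=O", "C", "CC([O-])=O",
               "CC(=O)C([O-])=O", "O")
  )
  ontology <- ontology_graph(tibble(
    child = c("CHEBI:33384", "CHEBI:35243"),
    parent = c("CHEBI:35243", "CHEBI:33709")
  ))
  list(lexicons = list(CHEBI = chebi, MESH = mesh), ph73 = ph73,
       reactions = reactions, smiles = smiles, ontology = ontology,
       sieve_cases = sieve_cases)
}

#' Write the chemistry fixtures as plain-text files
#'
#' Serializes [generate_chem_fixtures()] output in the interchange formats
#' the readers consume: lexicon TSVs, the two-column pH 7.3 TSV, the
#' reaction participant TSV, a SMILES TSV and a minimal OBO fragment.
#'
#' @param fixtures Result of [generate_chem_fixtures()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_chem_fixtures <- function(fixtures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(fixtures$lexicons)) {
    lx <- fixtures$lexicons[[nm]]
    lines <- c(paste(lx$synonyms$id, lx$synonyms$synonym, sep = "\t"),
               paste(lx$xrefs$id, lx$xrefs$xref_type, lx$xrefs$value,
                     sep = "\t"))
    writeLines(lines, file.path(dir, paste0(tolower(nm), "_lexicon.tsv")))
  }
  writeLines(c("CHEBI_ID\tCHEBI_ID_PH7_3",
               paste(names(fixtures$ph73), fixtures$ph73, sep = "\t")),
             file.path(dir, "chebi_pH7_3_mapping.tsv"))
  rx <- fixtures$reactions
  writeLines(c("rhea_id\tside\tchebi_id\tcoefficient",
               paste(rx$rhea_id, rx$side, rx$chebi_id, rx$coefficient,
                     sep = "\t")),
             file.path(dir, "reactions.tsv"))
  writeLines(paste(fixtures$smiles$chebi_id, fixtures$smiles$smiles,
                   sep = "\t"),
             file.path(dir, "smiles.tsv"))
  e <- fixtures$ontology$edges
  terms <- unique(c(e$child, e$parent))
  obo <- c("format-version: 1.2", "")
  for (tm in terms) {
    obo <- c(obo, "[Term]", paste0("id: ", tm))
    for (p in e$parent[e$child == tm]) obo <- c(obo, paste0("is_a: ", p))
    obo <- c(obo, "")
  }
  writeLines(obo, file.path(dir, "ontology.obo"))
  invisible(dir)
}
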