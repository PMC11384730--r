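test_that("precision/recall/F1 follow the closed forms and conventions", {
  r <- prf(40, 5, 10)
  expect_equal(r$precision, 100 * 40 / 45, tolerance = 1e-12)
  expect_equal(r$recall, 80)
  expect_equal(r$f1, 2 * r$precision * r$recall / (r$precision + r$recall))
  expect_equal(prf(0, 0, 0)[, c("precision", "recall", "f1")],
               tibble::tibble(precision = 0, recall = 0, f1 = 0))
  expect_equal(prf(0, 7, 3)$f1, 0)   # no NaN when tp = 0
})

test_that("recognition scoring matches spans and types, not identifiers", {
  g <- generate_corpus(n_docs = 4, relations_per_doc = 2, seed = 21)
  gold <- g$corpus
  self <- evaluate_ner(gold, gold)
  expect_true(all(self$precision == 100 & self$recall == 100 &
                    self$f1 == 100))

  # identifier substitutions are invisible to recognition scoring but each
  # one costs normalization scoring exactly fp+fn
  cc <- corrupt_corpus(gold, n_substitute = 3, seed = 2)
  ner <- evaluate_ner(gold, cc$corpus)
  expect_true(all(ner$f1 == 100))
  nen <- evaluate_nen(gold, cc$corpus)
  ov <- nen[nen$type == "Overall", ]
  led <- cc$ledger$nen
  expect_equal(c(ov$tp, ov$fp, ov$fn), c(led$tp, led$fp, led$fn))

  # empty predictions: recall 0, precision defined as 0
  empty <- ecr_corpus(gold$documents, gold$passages)
  e <- evaluate_ner(gold, empty)
  expect_true(all(e$precision == 0 & e$recall == 0 & e$f1 == 0))
})

test_that("planted corruption ledgers reproduce closed-form scores", {
  g <- generate_corpus(n_docs = 12, relations_per_doc = 2, seed = 77)
  cc <- corrupt_corpus(g$corpus, n_drop = 6, n_spurious = 4,
                       n_substitute = 5, seed = 3)
  led <- cc$ledger
  ner <- evaluate_ner(g$corpus, cc$corpus)
  ov <- ner[ner$type == "Overall", ]
  expected <- prf(led$ner$tp, led$ner$fp, led$ner$fn)
  expect_equal(c(ov$tp, ov$fp, ov$fn, ov$precision, ov$recall, ov$f1),
               c(expected$tp, expected$fp, expected$fn, expected$precision,
                 expected$recall, expected$f1))
  nen <- evaluate_nen(g$corpus, cc$corpus)
  ovn <- nen[nen$type == "Overall", ]
  expn <- prf(led$nen$tp, led$nen$fp, led$nen$fn)
  expect_equal(c(ovn$tp, ovn$fp, ovn$fn), c(expn$tp, expn$fp, expn$fn))
  expect_equal(ovn$f1, expn$f1)
  # micro consistency: the Overall row reproduces from per-type counts
  per <- ner[ner$type %in% c("Chemical", "Protein"), ]
  again <- prf(sum(per$tp), sum(per$fp), sum(per$fn))
  expect_equal(ov$f1, again$f1)
})

test_that("binary classification mode merges the two conversion flavours", {
  corp <- mk_corpus(list(list(
    pmid = "1", title = "Erythritol is converted to dihydroxyacetone.",
    mentions = list(
      list(id = "c1", surface = "Erythritol", ids = "CHEBI:17113"),
      list(id = "c2", surface = "dihydroxyacetone", ids = "CHEBI:16016")
    ),
    relations = list(list(id = "R1", type = "Indirect_conversion",
                          a = "c1", b = "c2"))
  )))
  gi <- enumerate_binary(corp)
  pi <- gi
  pi$pred_label <- "Conversion"   # predicted as direct conversion
  bin <- evaluate_relations(gi, pi, mode = "binary")
  expect_equal(c(bin$tp, bin$fp, bin$fn), c(1, 0, 0))
  multi <- evaluate_relations(gi, pi, mode = "multiclass")
  expect_equal(c(multi$tp, multi$fp, multi$fn), c(0, 1, 1))
})

test_that("perfect predictions score 100 in both modes on a mixed corpus", {
  g <- generate_corpus(n_docs = 6, relations_per_doc = 3, seed = 13)
  gi <- enumerate_binary(g$corpus)
  expect_true(any(gi$gold_label == "Indirect_conversion"))
  for (mode in c("binary", "multiclass")) {
    r <- evaluate_relations(gi, gi, mode = mode)
    expect_equal(c(r$precision, r$recall, r$f1), c(100, 100, 100))
  }
  ti <- enumerate_ternary(g$corpus)
  r3 <- evaluate_relations(ti, ti, mode = "binary")
  expect_equal(r3$f1, 100)
})

test_that("relation scoring equals exhaustive counting on random labelings", {
  set.seed(99)
  labels <- c("Conversion", "Indirect_conversion", "Non_conversion", "None")
  for (rep in 1:10) {
    n <- 200
    keys <- sprintf("k%03d", seq_len(n))
    gold <- tibble::tibble(
      pmid = "1", sentence_index = 1L,
      chem_a = keys, chem_b = paste0(keys, "x"),
      start_a = seq_len(n) * 10L, end_a = seq_len(n) * 10L + 3L,
      ids_a = as.list(sprintf("CHEBI:%d", seq_len(n))),
      start_b = seq_len(n) * 10L + 5L, end_b = seq_len(n) * 10L + 8L,
      ids_b = as.list(sprintf("CHEBI:%d", seq_len(n) + 1000)),
      gold_label = sample(labels, n, replace = TRUE,
                          prob = c(.3, .15, .05, .5))
    )
    pred <- gold
    pred$pred_label <- ifelse(runif(n) < 0.6, gold$gold_label,
                              sample(labels, n, replace = TRUE))
    for (mode in c("binary", "multiclass")) {
      collapse <- function(x) {
        if (mode == "binary") {
          ifelse(x == "Indirect_conversion", "Conversion", x)
        } else x
      }
      got <- evaluate_relations(gold, pred, mode = mode)
      want <- oracle_prf_counts(keys, collapse(gold$gold_label),
                                keys, collapse(pred$pred_label))
      expect_equal(c(got$tp, got$fp, got$fn), unname(want))
    }
  }
})

test_that("duplicate instance keys are rejected", {
  corp <- mk_corpus(list(dopachrome_doc()))
  gi <- enumerate_binary(corp)
  expect_error(evaluate_relations(dplyr::bind_rows(gi, gi), gi),
               "duplicate gold")
})

test_that("relaxed matching accepts one is_a edge and nothing farther", {
  fx <- generate_chem_fixtures()
  mk <- function(id1) {
    mk_corpus(list(list(
      pmid = "1", title = "Serine is converted to pyruvate.",
      mentions = list(
        list(id = "c1", surface = "Serine", ids = id1),
        list(id = "c2", surface = "pyruvate", ids = "CHEBI:15361")
      ),
      relations = list(list(id = "R1", type = "Conversion",
                            a = "c1", b = "c2"))
    )))
  }
  gold <- mk("CHEBI:33384")
  pred_parent <- mk("CHEBI:35243")      # one edge up
  pred_grand <- mk("CHEBI:33709")       # two edges up
  exact <- evaluate_end_to_end(gold, pred_parent, matching = "exact")
  expect_equal(exact$tp, 0)
  relax <- evaluate_end_to_end(gold, pred_parent, ontology = fx$ontology,
                               matching = "relaxed")
  expect_equal(c(relax$tp, relax$f1), c(1, 100))
  # child direction also matches
  relax_dn <- evaluate_end_to_end(pred_parent, gold,
                                  ontology = fx$ontology,
                                  matching = "relaxed")
  expect_equal(relax_dn$tp, 1)
  far <- evaluate_end_to_end(gold, pred_grand, ontology = fx$ontology,
                             matching = "relaxed")
  expect_equal(far$tp, 0)
  expect_error(evaluate_end_to_end(gold, pred_parent, matching = "relaxed"),
               "ontology")
  # identical corpora are perfect under exact matching
  same <- evaluate_end_to_end(gold, gold, matching = "exact")
  expect_equal(c(same$precision, same$recall, same$f1), c(100, 100, 100))
})

test_that("non-ChEBI identifiers are never relaxed", {
  fx <- generate_chem_fixtures()
  mk <- function(ids) {
    mk_corpus(list(list(
      pmid = "1", title = "Serine is converted to pyruvate.",
      mentions = list(
        list(id = "c1", surface = "Serine", ids = ids),
        list(id = "c2", surface = "pyruvate", ids = "CHEBI:15361")
      ),
      relations = list(list(id = "R1", type = "Conversion",
                            a = "c1", b = "c2"))
    )))
  }
  ont <- ontology_graph(tibble::tibble(child = "MESH:D012694",
                                       parent = "MESH:D000001"))
  got <- evaluate_end_to_end(mk("MESH:D012694"), mk("MESH:D000001"),
                             ontology = ont, matching = "relaxed")
  expect_equal(got$tp, 0)
})

test_that("relaxation is monotone: relaxed true positives >= exact", {
  fx <- generate_chem_fixtures()
  for (seed in c(4, 9, 15)) {
    g <- generate_corpus(n_docs = 4, relations_per_doc = 2, seed = seed)
    cc <- corrupt_corpus(g$corpus, n_substitute = 4, seed = seed + 1)
    ex <- evaluate_end_to_end(g$corpus, cc$corpus, matching = "exact")
    rx <- evaluate_end_to_end(g$corpus, cc$corpus, ontology = fx$ontology,
                              matching = "relaxed")
    expect_gte(rx$tp, ex$tp)
    expect_gte(rx$f1, ex$f1)
  }
})

test_that("cyclic ontologies are rejected and OBO parsing keeps is_a only", {
  expect_error(ontology_graph(tibble::tibble(child = c("A", "B"),
                                             parent = c("B", "A"))),
               "cycle")
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: CHEBI:1", "name: one",
               "is_a: CHEBI:2 ! two", "xref: CAS:50-00-0", "",
               "[Typedef]", "id: part_of", ""), f)
  ont <- read_obo(f)
  expect_equal(ont$edges, tibble::tibble(child = "CHEBI:1",
                                         parent = "CHEBI:2"))
})
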