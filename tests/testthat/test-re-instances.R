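test_that("binary enumeration labels curated pairs and synthesizes None", {
  corp <- mk_corpus(list(dopachrome_doc()))
  inst <- enumerate_binary(corp)
  expect_equal(nrow(inst), 3)   # C(3,2) pairs in the one sentence
  expect_equal(sum(inst$gold_label == "Conversion"), 2)
  none <- inst[inst$gold_label == "None", ]
  expect_equal(nrow(none), 1)
  # the None pair is the synonym pair (c1, c2)
  expect_setequal(c(none$chem_a, none$chem_b), c("c1", "c2"))
  # mentions ordered by span start
  expect_true(all(inst$start_a < inst$start_b))
})

test_that("degenerate sentences yield no instances", {
  single <- mk_corpus(list(list(
    pmid = "1", title = "Only pyruvate here.",
    mentions = list(list(id = "c1", surface = "pyruvate",
                         ids = "CHEBI:15361"))
  )))
  expect_equal(nrow(enumerate_binary(single)), 0)
  expect_equal(nrow(enumerate_ternary(single)), 0)
})

test_that("five unrelated chemicals yield all C(5,2) None pairs", {
  corp <- mk_corpus(list(list(
    pmid = "1",
    title = "Levels of citrate, isocitrate, fumarate, succinate and pyruvate.",
    mentions = list(
      list(id = "c1", surface = "citrate", ids = "CHEBI:16947"),
      list(id = "c2", surface = "isocitrate", ids = "CHEBI:30887"),
      list(id = "c3", surface = "fumarate", ids = "CHEBI:29806"),
      list(id = "c4", surface = "succinate", ids = "CHEBI:30031"),
      list(id = "c5", surface = "pyruvate", ids = "CHEBI:15361")
    )
  )))
  inst <- enumerate_binary(corp)
  expect_equal(nrow(inst), choose(5, 2))
  expect_true(all(inst$gold_label == "None"))
})

test_that("ternary tuples follow the converter-linkage None rules", {
  # no protein in sentence scope: zero ternary instances
  mesa <- mk_corpus(list(list(
    pmid = "19670200",
    title = "Amination direction.",
    abstract = paste0("They catalyze the conversion of mesaconate to yield ",
                      "only methylaspartate, with no detectable formation ",
                      "of threo-methylaspartate."),
    mentions = list(
      list(id = "c1", surface = "mesaconate", ids = "CHEBI:36986"),
      list(id = "c2", surface = "methylaspartate", ids = "CHEBI:58259", n = 1),
      list(id = "c3", surface = "threo-methylaspartate", ids = "CHEBI:0001")
    ),
    relations = list(
      list(id = "R1", type = "Conversion", a = "c1", b = "c2"),
      list(id = "R2", type = "Non_conversion", a = "c1", b = "c3")
    )
  )))
  expect_equal(nrow(enumerate_ternary(mesa)), 0)
  bi <- enumerate_binary(mesa)
  expect_setequal(bi$gold_label, c("Conversion", "Non_conversion", "None"))

  # one protein linked as converter: one Conversion tuple
  one <- mk_corpus(list(list(
    pmid = "2", title = "YhfN converts citrate into isocitrate.",
    mentions = list(
      list(id = "p1", surface = "YhfN", type = "Protein", ids = "P00001"),
      list(id = "c1", surface = "citrate", ids = "CHEBI:16947"),
      list(id = "c2", surface = "isocitrate", ids = "CHEBI:30887")
    ),
    relations = list(list(id = "R1", type = "Conversion", a = "c1", b = "c2",
                          conv = "p1"))
  )))
  t1 <- enumerate_ternary(one)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$gold_label, "Conversion")

  # two proteins, only one linked: the unlinked one gets None
  two <- mk_corpus(list(list(
    pmid = "12147680",
    title = "YhfQ and YhfN were assayed; YhfN converts citrate into isocitrate.",
    mentions = list(
      list(id = "pA", surface = "YhfQ", type = "Protein", ids = "P00002"),
      list(id = "pB", surface = "YhfN", type = "Protein", ids = "P00001",
           n = 2),
      list(id = "c1", surface = "citrate", ids = "CHEBI:16947"),
      list(id = "c2", surface = "isocitrate", ids = "CHEBI:30887")
    ),
    relations = list(list(id = "R1", type = "Conversion", a = "c1", b = "c2",
                          conv = "pB"))
  )))
  t2 <- enumerate_ternary(two)
  expect_equal(nrow(t2), 2)
  expect_equal(t2$gold_label[t2$protein == "pB"], "Conversion")
  expect_equal(t2$gold_label[t2$protein == "pA"], "None")
})

test_that("a repeated protein produces one instance per occurrence", {
  corp <- mk_corpus(list(list(
    pmid = "1", title = "CDO and CDO convert cysteine into sulfinate.",
    mentions = list(
      list(id = "p1", surface = "CDO", type = "Protein", ids = "P60334",
           n = 1),
      list(id = "p2", surface = "CDO", type = "Protein", ids = "P60334",
           n = 2),
      list(id = "c1", surface = "cysteine", ids = "CHEBI:35235"),
      list(id = "c2", surface = "sulfinate", ids = "CHEBI:61085")
    ),
    relations = list(list(id = "R1", type = "Conversion", a = "c1", b = "c2",
                          conv = c("p1", "p2")))
  )))
  t3 <- enumerate_ternary(corp)
  expect_equal(nrow(t3), 2)
  expect_true(all(t3$gold_label == "Conversion"))
})

test_that("cross-sentence relations are excluded from enumeration but kept", {
  corp <- mk_corpus(list(list(
    pmid = "1",
    title = "Substrate overview.",
    abstract = "We studied citrate in detail. Isocitrate was the product.",
    mentions = list(
      list(id = "c1", surface = "citrate", ids = "CHEBI:16947"),
      list(id = "c2", surface = "Isocitrate", ids = "CHEBI:30887")
    ),
    relations = list(list(id = "R1", type = "Conversion", a = "c1", b = "c2"))
  )))
  expect_message(inst <- enumerate_binary(corp), "cross-sentence")
  expect_equal(nrow(inst), 0)
  expect_equal(nrow(corp$relations), 1)
})

test_that("instance counts match the combinatorial closed form", {
  for (seed in c(2, 17, 23)) {
    g <- generate_corpus(n_docs = 3, relations_per_doc = 3, seed = seed)
    bi <- enumerate_binary(g$corpus)
    ti <- enumerate_ternary(g$corpus)
    for (pm in g$corpus$documents$pmid) {
      txt <- document_text(g$corpus, pm)
      sents <- sentence_spans(segment_text(txt))
      men <- g$corpus$mentions[g$corpus$mentions$pmid == pm, ]
      for (s in sents$sentence_index) {
        srow <- sents[sents$sentence_index == s, ]
        inside <- men[men$start >= srow$start & men$end <= srow$end, ]
        k <- sum(inside$entity_type == "Chemical")
        p <- sum(inside$entity_type == "Protein")
        expect_equal(sum(bi$pmid == pm & bi$sentence_index == s),
                     choose(k, 2))
        expect_equal(sum(ti$pmid == pm & ti$sentence_index == s),
                     p * choose(k, 2))
      }
    }
    # label conservation: every in-sentence curated relation appears exactly
    # once as a non-None instance
    expect_equal(sum(bi$gold_label != "None"), nrow(g$corpus$relations))
  }
})

test_that("rendering wraps targets and is length-accountable", {
  corp <- mk_corpus(list(list(
    pmid = "2", title = "YhfN converts citrate into isocitrate.",
    mentions = list(
      list(id = "p1", surface = "YhfN", type = "Protein", ids = "P00001"),
      list(id = "c1", surface = "citrate", ids = "CHEBI:16947"),
      list(id = "c2", surface = "isocitrate", ids = "CHEBI:30887")
    ),
    relations = list(list(id = "R1", type = "Conversion", a = "c1", b = "c2",
                          conv = "p1"))
  )))
  ti <- enumerate_ternary(corp)
  out <- render_instance(ti[1, ], corp)
  expect_match(out, "<P>YhfN</P>", fixed = TRUE)
  expect_match(out, "<C1>citrate</C1>", fixed = TRUE)
  expect_match(out, "<C2>isocitrate</C2>", fixed = TRUE)
  expect_true(startsWith(out, "[Reaction] "))
  sent <- "YhfN converts citrate into isocitrate."
  markers <- nchar("<P></P><C1></C1><C2></C2>")
  expect_equal(nchar(out), nchar("[Reaction] ") + nchar(sent) + markers)

  # empty markers reduce to the task tag plus the untouched sentence
  plain <- tag_dialect(c1_open = "", c1_close = "", c2_open = "",
                       c2_close = "", p_open = "", p_close = "")
  expect_equal(render_instance(ti[1, ], corp, dialect = plain),
               paste("[Reaction]", sent))
})

test_that("rendering refuses overlapping target mentions", {
  corp <- mk_corpus(list(list(
    pmid = "1", title = "The citrate synthase complex.",
    mentions = list(
      list(id = "c1", surface = "citrate", ids = "CHEBI:16947"),
      list(id = "c2", surface = "citrate synthase", ids = "CHEBI:9999")
    )
  )))
  inst <- enumerate_binary(corp)
  expect_equal(nrow(inst), 1)
  expect_error(render_instance(inst[1, ], corp), "overlap")
})

test_that("the trigger baseline labels template sentences as planted", {
  expect_equal(baseline_classify("YhfN converts citrate into isocitrate."),
               "Conversion")
  expect_equal(baseline_classify("It catalyzes the conversion of A to B."),
               "Conversion")
  expect_equal(baseline_classify("The esterase hydrolyzes the substrate."),
               "Conversion")
  expect_equal(baseline_classify("The protein binds DNA."), "None")
  expect_equal(
    baseline_classify("A is converted to B via a series of intermediates."),
    "Indirect_conversion")
  expect_equal(
    baseline_classify("YhfN did not convert citrate into isocitrate."),
    "Non_conversion")

  # across generated template corpora, the baseline agrees with the planted
  # label of every curated (non-None) instance sentence
  for (seed in c(5, 31)) {
    g <- generate_corpus(n_docs = 5, relations_per_doc = 2, seed = seed)
    bi <- enumerate_binary(g$corpus)
    bi <- bi[bi$gold_label != "None", ]
    for (i in seq_len(nrow(bi))) {
      txt <- document_text(g$corpus, bi$pmid[i])
      sents <- sentence_spans(segment_text(txt))
      srow <- sents[sents$sentence_index == bi$sentence_index[i], ]
      sent <- substring(txt, srow$start + 1, srow$end)
      expect_equal(baseline_classify(sent), bi$gold_label[i], info = sent)
    }
  }
})
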