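test_that("top compound ranking counts reaction participation", {
  fx <- generate_chem_fixtures()
  expect_error(top_compounds(fx$reactions, k = 0), "positive")
  expect_error(top_compounds(fx$reactions, k = -3), "positive")
  # water participates in all five toy reactions: ranked first
  expect_equal(top_compounds(fx$reactions, k = 1), "CHEBI:15377")
})

test_that("frequency ties at rank k include all tied compounds", {
  rx <- tibble::tibble(
    rhea_id = c("R1", "R1", "R1", "R2", "R2", "R2"),
    side = "left",
    chebi_id = c("CHEBI:1", "CHEBI:2", "CHEBI:3",
                 "CHEBI:1", "CHEBI:2", "CHEBI:4"),
    coefficient = 1
  )
  # frequencies: 1 -> 2, 2 -> 2, 3 -> 1, 4 -> 1; k = 3 cuts inside the tie
  expect_warning(top <- top_compounds(rx, k = 3), "tie")
  expect_equal(sort(top), sprintf("CHEBI:%d", 1:4))
})

test_that("pair enumeration is literal all-pairs minus exclusions", {
  rx <- tibble::tibble(
    rhea_id = "R1", side = c("left", "left", "right"),
    chebi_id = c("CHEBI:10", "CHEBI:20", "CHEBI:30"), coefficient = 1
  )
  got <- rhea_pairs(rx)
  expect_equal(nrow(got), 3)   # AB, AC, BC: within- and cross-side
  expect_setequal(paste(got$id_a, got$id_b),
                  c("CHEBI:10 CHEBI:20", "CHEBI:10 CHEBI:30",
                    "CHEBI:20 CHEBI:30"))
  cross <- rhea_pairs(rx, cross_side_only = TRUE)
  expect_setequal(paste(cross$id_a, cross$id_b),
                  c("CHEBI:10 CHEBI:30", "CHEBI:20 CHEBI:30"))

  excl <- rhea_pairs(rx, excluded = "CHEBI:20")
  expect_equal(paste(excl$id_a, excl$id_b), "CHEBI:10 CHEBI:30")

  transport <- tibble::tibble(rhea_id = "R2", side = c("left", "right"),
                              chebi_id = c("CHEBI:5", "CHEBI:5"),
                              coefficient = 1)
  expect_equal(nrow(rhea_pairs(transport)), 0)
})

test_that("pair enumeration matches brute force on random reaction sets", {
  set.seed(606)
  for (rep in 1:20) {
    rx <- random_reactions()
    excl <- sample(unique(rx$chebi_id), sample(0:2, 1))
    got <- rhea_pairs(rx, excluded = excl)
    keys <- sort(unique(paste(got$id_a, got$id_b)))
    expect_equal(keys, oracle_pairs(rx, excl))
    # invariants: no excluded member, no identical-id pair, canonical order
    expect_false(any(got$id_a %in% excl | got$id_b %in% excl))
    expect_true(all(got$id_a != got$id_b))
    expect_true(all(vapply(got$id_a, function(x) {
      as.integer(sub("CHEBI:", "", x))
    }, 1L) <= vapply(got$id_b, function(x) {
      as.integer(sub("CHEBI:", "", x))
    }, 1L)))
  }
})

test_that("prediction normalization applies its filters in order", {
  fx <- generate_chem_fixtures()
  excl <- "CHEBI:15377"
  pairs <- tibble::tibble(
    id_a = c("MESH:D1", "CHEBI:15366", "CHEBI:15377", "CHEBI:15377",
             "CHEBI:15377", "CHEBI:16236", "CHEBI:15343",
             "CHEBI:15361", "CHEBI:17234", "CHEBI:15361"),
    id_b = c("CHEBI:1", "CHEBI:30089", "CHEBI:16236", "CHEBI:15343",
             "CHEBI:15361", "CHEBI:15343", "CHEBI:16236",
             "CHEBI:17234", "CHEBI:16236", "CHEBI:16236")
  )
  # planted outcomes: 1 non-ChEBI; 1 collapses to identical after pH 7.3
  # (acetic acid / acetate); 3 contain the excluded compound; of the
  # remaining 5 rows two are the same unordered pair, so 4 survive
  out <- normalize_predictions(pairs, ph_map = fx$ph73, excluded = excl)
  sc <- attr(out, "stage_counts")
  expect_equal(sc$removed[sc$stage == "non_chebi"], 1)
  expect_equal(sc$removed[sc$stage == "excluded_compound"], 3)
  expect_equal(sc$removed[sc$stage == "identical_after_ph73"], 1)
  expect_equal(sc$removed[sc$stage == "duplicate"], 1)
  expect_equal(nrow(out), 4)
  expect_equal(nrow(pairs) - sum(sc$removed), nrow(out))
  # untouched pair survives unchanged
  expect_true(any(out$id_a == "CHEBI:15343" & out$id_b == "CHEBI:16236"))
})

test_that("pair comparison reports overlap percentages per relation type", {
  ref <- tibble::tibble(id_a = c("CHEBI:1", "CHEBI:2"),
                        id_b = c("CHEBI:9", "CHEBI:8"))
  subset_pred <- tibble::tibble(id_a = "CHEBI:1", id_b = "CHEBI:9")
  expect_equal(compare_pairs(subset_pred, ref)$pct_in_reference, 100)
  disjoint <- tibble::tibble(id_a = "CHEBI:3", id_b = "CHEBI:4")
  expect_equal(compare_pairs(disjoint, ref)$pct_in_reference, 0)

  pred <- tibble::tibble(
    id_a = sprintf("CHEBI:%d", 1:8),
    id_b = sprintf("CHEBI:%d", 101:108),
    relation_type = rep(c("Conversion", "Indirect_conversion"), each = 4)
  )
  ref2 <- tibble::tibble(id_a = c("CHEBI:1", "CHEBI:5"),
                         id_b = c("CHEBI:101", "CHEBI:105"))
  cmp <- compare_pairs(pred, ref2)
  expect_equal(cmp$pct_in_reference[cmp$relation_type == "All"], 25)
  expect_equal(cmp$n_shared[cmp$relation_type == "All"], 2)
  expect_equal(cmp$pct_in_reference[cmp$relation_type == "Conversion"], 25)
})

test_that("atom conservation reproduces the hand-derived small cases", {
  same <- atom_conservation("CCO", "OCC")
  expect_equal(same$percent, 100)
  redu <- atom_conservation("CCO", "CC=O")   # single-bond reduction unifies
  expect_equal(redu$percent, 100)
  part <- atom_conservation("CCO", "C")
  expect_equal(part$n_mcs, 1)
  expect_equal(part$percent, 0.5 * (1 / 3 + 1) * 100, tolerance = 1e-10)
  # symmetry
  expect_equal(atom_conservation("CC=O", "CCO")$percent, 100)
  expect_equal(atom_conservation("C", "CCO")$percent, part$percent)
  expect_error(atom_conservation("not_smiles(", "C"), "left")
  expect_error(atom_conservation("C", "zz("), "right")
})

test_that("the clique-based MCS equals exhaustive subgraph search", {
  set.seed(777)
  for (rep in 1:25) {
    a <- random_molecule(sample(2:6, 1))
    b <- random_molecule(sample(2:6, 1))
    got <- enzchemkit:::mcs_size(a, b)
    want <- oracle_mcs(a, b)
    expect_equal(got, want)
    expect_lte(got, min(length(a$elements), length(b$elements)))
    # symmetry
    expect_equal(enzchemkit:::mcs_size(b, a), got)
  }
  # and for the SMILES-derived graphs of the hand cases
  eth <- enzchemkit:::parse_smiles("CCO")
  ald <- enzchemkit:::parse_smiles("CC=O")
  met <- enzchemkit:::parse_smiles("C")
  expect_equal(oracle_mcs(eth, ald), 3)
  expect_equal(oracle_mcs(eth, met), 1)
})

test_that("the conservation filter keeps high-overlap structured pairs", {
  fx <- generate_chem_fixtures()
  pairs <- tibble::tibble(
    id_a = c("CHEBI:16236", "CHEBI:16236", "CHEBI:16236"),
    id_b = c("CHEBI:15343", "CHEBI:16183", "CHEBI:99999")
  )
  kept <- filter_conserved(pairs, fx$smiles)
  # ethanol/acetaldehyde conserves 100%; ethanol/methane 66.7% falls below
  # the default threshold; the unstructured pair cannot be scored
  expect_equal(nrow(kept), 1)
  expect_equal(kept$id_b, "CHEBI:15343")
  expect_equal(kept$atom_conservation, 100)
  lenient <- filter_conserved(pairs, fx$smiles, threshold = 50)
  expect_equal(nrow(lenient), 2)
})

test_that("the fingerprint adapter is order-invariant and needs a provider", {
  expect_error(drfp_distance(c("CCO", "CC=O"), c("CCO", "CC=O")),
               "provider")
  # deterministic toy provider: character 4-gram membership fingerprint
  provider <- function(pair) {
    joined <- paste(pair, collapse = ">")
    grams <- vapply(seq_len(max(nchar(joined) - 3, 1)),
                    function(i) substr(joined, i, i + 3), "")
    vapply(c("CCO>", "C=O ", ">CC=", "CO>C", "O>CC", "CCN>", ">CCN"),
           function(g) g %in% grams, logical(1))
  }
  a <- c("CCO", "CC=O")
  expect_equal(drfp_distance(a, a, provider = provider), 0)
  expect_equal(drfp_distance(a, rev(a), provider = provider), 0)
  d <- drfp_distance(a, c("CCN", "CCO"), provider = provider)
  expect_gt(d, 0)
  expect_lte(d, 1)
})
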