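# Independent oracles, deliberately written as direct brute force so they
# share no code path with the implementation they check.

# Minimal matching sieve step by evaluating all five steps independently.
oracle_sieve_step <- function(raw, target, lexicons) {
  tl <- lexicons[[target]]
  proc <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  p <- proc(raw)
  st <- porter_stem(p)
  others <- lexicons[names(lexicons) != target]
  foreign_hit <- function(form, col) {
    ids <- unlist(lapply(others, function(lx) {
      vals <- if (col == "processed") proc(lx$synonyms$synonym) else
        porter_stem(proc(lx$synonyms$synonym))
      lx$synonyms$id[vals == form]
    }))
    unique(ids)
  }
  maps_to_target <- function(fids) {
    if (!length(fids)) return(FALSE)
    xr <- dplyr::bind_rows(lapply(lexicons, function(lx) lx$xrefs))
    tids <- unique(tl$synonyms$id)
    single <- any(xr$value[xr$id %in% fids & xr$xref_type == target] %in%
                    tids) ||
      any(tl$xrefs$value %in% fids)
    pivot <- FALSE
    for (key in c("InChIKey", "SMILES", "CAS")) {
      fk <- xr$value[xr$id %in% fids & xr$xref_type == key]
      pivot <- pivot ||
        any(tl$xrefs$id[tl$xrefs$xref_type == key &
                          tl$xrefs$value %in% fk] %in% tids)
    }
    single || pivot
  }
  steps <- c(
    any(tl$synonyms$synonym == raw),
    any(proc(tl$synonyms$synonym) == p),
    any(porter_stem(proc(tl$synonyms$synonym)) == st),
    maps_to_target(foreign_hit(p, "processed")),
    maps_to_target(foreign_hit(st, "stemmed"))
  )
  if (any(steps)) which(steps)[1] else 0L
}

# Exhaustive maximum-common-induced-subgraph size on small element-labelled
# graphs: enumerate all vertex subsets of both graphs in decreasing size and
# test induced-subgraph isomorphism with element colours.
oracle_mcs <- function(mol_a, mol_b) {
  gr <- function(mol) {
    g <- igraph::make_empty_graph(length(mol$elements), directed = FALSE)
    if (nrow(mol$bonds)) g <- igraph::add_edges(g, t(mol$bonds))
    igraph::set_vertex_attr(g, "color",
                            value = as.integer(factor(
                              mol$elements,
                              levels = sort(unique(c(mol_a$elements,
                                                     mol_b$elements))))))
  }
  ga <- gr(mol_a); gb <- gr(mol_b)
  na <- length(mol_a$elements); nb <- length(mol_b$elements)
  subsets <- function(n, k) utils::combn(n, k, simplify = FALSE)
  for (s in seq(min(na, nb), 1)) {
    for (sa in subsets(na, s)) {
      ia <- igraph::induced_subgraph(ga, sa)
      for (sb in subsets(nb, s)) {
        ib <- igraph::induced_subgraph(gb, sb)
        if (igraph::isomorphic(ia, ib, method = "vf2",
                               vertex.color1 = igraph::V(ia)$color,
                               vertex.color2 = igraph::V(ib)$color)) {
          return(s)
        }
      }
    }
  }
  0L
}

# Random element-labelled connected small molecule graph (no SMILES needed).
random_molecule <- function(n_atoms, elements = c("C", "C", "C", "N", "O")) {
  els <- sample(elements, n_atoms, replace = TRUE)
  bonds <- if (n_atoms >= 2) {
    # random spanning tree, plus occasionally one extra (ring-forming) edge
    b <- cbind(2:n_atoms, vapply(2:n_atoms,
                                 function(i) sample.int(i - 1, 1), 1L))
    if (n_atoms >= 4 && runif(1) < 0.4) {
      extra <- sort(sample.int(n_atoms, 2))
      present <- any(b[, 1] == extra[2] & b[, 2] == extra[1]) ||
        any(b[, 1] == extra[1] & b[, 2] == extra[2])
      if (!present) b <- rbind(b, rev(extra))
    }
    b
  } else {
    matrix(integer(), ncol = 2)
  }
  list(elements = els, bonds = bonds)
}

# Brute-force PRF over labelled instance sets by direct counting.
oracle_prf_counts <- function(gold_keys, gold_labels, pred_keys,
                              pred_labels) {
  gold <- unique(paste(gold_keys, gold_labels)[gold_labels != "None"])
  pred <- unique(paste(pred_keys, pred_labels)[pred_labels != "None"])
  tp <- sum(pred %in% gold)
  c(tp = tp, fp = length(pred) - tp, fn = length(gold) - tp)
}

# Random toy reaction table.
random_reactions <- function(n_reactions = 6, n_compounds = 8) {
  ids <- sprintf("CHEBI:%d", sample(100:999, n_compounds))
  rows <- lapply(seq_len(n_reactions), function(r) {
    nl <- sample(1:3, 1); nr <- sample(1:3, 1)
    tibble::tibble(
      rhea_id = sprintf("RHEA:%d", r),
      side = c(rep("left", nl), rep("right", nr)),
      chebi_id = sample(ids, nl + nr, replace = TRUE),
      coefficient = 1
    )
  })
  dplyr::bind_rows(rows)
}

# Brute-force pair enumeration for one reaction table.
oracle_pairs <- function(reactions, excluded) {
  out <- character()
  for (rid in unique(reactions$rhea_id)) {
    ids <- setdiff(unique(reactions$chebi_id[reactions$rhea_id == rid]),
                   excluded)
    if (length(ids) < 2) next
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i < j && ids[i] != ids[j]) {
          k <- sort(c(ids[i], ids[j]))
          out <- c(out, paste(k[1], k[2]))
        }
      }
    }
  }
  sort(unique(out))
}

# Random lexicon pair with structural keys for sieve property tests.
random_lexicons <- function(n_target = 12, n_other = 10) {
  rand_word <- function() {
    paste(sample(letters, sample(4:9, 1), replace = TRUE), collapse = "")
  }
  t_ids <- sprintf("CHEBI:%d", sample(1000:9999, n_target))
  o_ids <- sprintf("MESH:D%06d", sample(1:999999, n_other))
  t_syn <- tibble::tibble(id = rep(t_ids, each = 2),
                          synonym = replicate(2 * n_target, rand_word()))
  o_syn <- tibble::tibble(id = rep(o_ids, each = 2),
                          synonym = replicate(2 * n_other, rand_word()))
  keys <- replicate(5, paste0(toupper(rand_word()), "-KEY"))
  t_x <- tibble::tibble(
    id = sample(t_ids, 4), xref_type = "InChIKey",
    value = sample(keys, 4, replace = TRUE)
  )
  o_x <- dplyr::bind_rows(
    tibble::tibble(id = sample(o_ids, 4), xref_type = "InChIKey",
                   value = sample(keys, 4, replace = TRUE)),
    tibble::tibble(id = sample(o_ids, 2), xref_type = "CHEBI",
                   value = sample(t_ids, 2))
  )
  list(CHEBI = ecr_lexicon("CHEBI", t_syn, t_x),
       MESH = ecr_lexicon("MESH", o_syn, o_x))
}

# Query terms exercising every step: verbatim synonyms, case/punctuation
# variants, plural forms, and random misses.
random_query_terms <- function(lexicons, n = 20) {
  syns <- unlist(lapply(lexicons, function(lx) lx$synonyms$synonym))
  base <- sample(syns, min(n, length(syns)), replace = TRUE)
  vapply(base, function(s) {
    switch(sample(1:5, 1),
           s,
           paste0(toupper(substr(s, 1, 1)), substring(s, 2), ","),
           paste0(s, "s"),
           paste0(s, "ing"),
           paste(sample(letters, 8, replace = TRUE), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}
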