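#' Precision/recall/F1 from counts
#'
#' Percentages in \[0, 100\]; with a zero denominator the component is 0,
#' and F1 is 0 whenever precision + recall is 0 (avoiding NaN).
#'
#' @param tp,fp,fn Non-negative counts.
#' @return A one-row tibble with `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`.
#' @export
#' @examples
#' prf(40, 5, 10)
prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  tibble(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f)
}

prf_from_keys <- function(gold_keys, pred_keys) {
  gold_keys <- unique(gold_keys); pred_keys <- unique(pred_keys)
  tp <- length(intersect(gold_keys, pred_keys))
  prf(tp, length(pred_keys) - tp, length(gold_keys) - tp)
}

check_same_pmids <- function(gold, pred) {
  a <- gold$documents$pmid; b <- pred$documents$pmid
  if (!setequal(a, b)) {
    abort(paste0("gold and predicted corpora cover different pmids",
                 "; only in gold: ", paste(setdiff(a, b), collapse = ", "),
                 "; only in pred: ", paste(setdiff(b, a), collapse = ", ")))
  }
}

eval_mentions <- function(gold, pred, with_ids) {
  check_same_pmids(gold, pred)
  keys <- function(corpus, type) {
    men <- corpus$mentions[corpus$mentions$entity_type == type, ]
    if (!nrow(men)) return(character())
    k <- paste(men$pmid, men$start, men$end, men$entity_type, sep = "|")
    if (with_ids) k <- paste(k, id_key(men$identifiers), sep = "|")
    k
  }
  rows <- lapply(c("Chemical", "Protein"), function(etype) {
    r <- prf_from_keys(keys(gold, etype), keys(pred, etype))
    r$type <- etype
    r
  })
  per_type <- bind_rows(rows)
  micro <- prf(sum(per_type$tp), sum(per_type$fp), sum(per_type$fn))
  micro$type <- "Overall"
  macro <- micro
  macro$type <- "Overall (macro)"
  macro$precision <- mean(per_type$precision)
  macro$recall <- mean(per_type$recall)
  macro$f1 <- mean(per_type$f1)
  out <- bind_rows(per_type, micro, macro)
  out <- out[c("type", "tp", "fp", "fn", "precision", "recall", "f1")]
  class(out) <- c("ecr_prf", class(out))
  out
}

#' Evaluate named entity recognition
#'
#' A predicted mention is a true positive only when its entity type and its
#' start and end character positions match a gold mention of the same
#' document. Only Chemical and Protein mentions are scored (the other three
#' entity types are not curated exhaustively); the `Overall` row is
#' micro-averaged across the two types, with a macro-averaged row also
#' emitted.
#'
#' @param gold,pred `ecr_corpus` objects over the same pmids.
#' @return A tibble of class `ecr_prf`, one row per entity type plus
#'   overall rows.
#' @export
evaluate_ner <- function(gold, pred) {
  eval_mentions(gold, pred, with_ids = FALSE)
}

#' Evaluate recognition + normalization jointly
#'
#' As [evaluate_ner()], but a true positive additionally requires identifier
#' -set equality; mentions without identifiers match on the empty string.
#'
#' @inheritParams evaluate_ner
#' @return A tibble of class `ecr_prf`.
#' @export
evaluate_nen <- function(gold, pred) {
  eval_mentions(gold, pred, with_ids = TRUE)
}

# Canonical match key of instance rows: pmid + span/id of each chemical
# (unordered) [+ protein span/id] + label is handled separately.
instance_keys <- function(instances) {
  if (!nrow(instances)) return(character())
  side_a <- paste(instances$start_a, instances$end_a,
                  id_key(instances$ids_a), sep = ";")
  side_b <- paste(instances$start_b, instances$end_b,
                  id_key(instances$ids_b), sep = ";")
  lo <- pmin(side_a, side_b); hi <- pmax(side_a, side_b)
  k <- paste(instances$pmid, lo, hi, sep = "|")
  if ("protein" %in% names(instances)) {
    k <- paste(k, instances$start_p, instances$end_p,
               id_key(instances$ids_p), sep = "|")
  }
  k
}

collapse_binary <- function(labels) {
  ifelse(labels == "Indirect_conversion", "Conversion", labels)
}

#' Evaluate relation extraction
#'
#' Scores predicted against gold classification instances (binary chemical
#' pairs or ternary enzyme tuples). The match key covers the pmid, the two
#' chemical spans and identifier sets (unordered) and, for ternary
#' instances, the protein span and identifier. Instances labelled `"None"`
#' are negatives: they are never counted, on either side. In `"binary"`
#' classification mode `Conversion` and `Indirect_conversion` are treated
#' as equivalent (collapsed to one positive class; `Non_conversion` stays
#' distinct); `"multiclass"` mode keeps all three distinct.
#'
#' @param gold_instances,pred_instances Instance tibbles as produced by
#'   [enumerate_binary()]/[enumerate_ternary()], with label columns
#'   `gold_label` and (for predictions) `pred_label` (falling back to
#'   `gold_label` if absent).
#' @param mode `"binary"` or `"multiclass"`.
#' @return A one-row tibble of class `ecr_prf`.
#' @export
evaluate_relations <- function(gold_instances, pred_instances,
                               mode = c("binary", "multiclass")) {
  mode <- match.arg(mode)
  gk <- instance_keys(gold_instances)
  pk <- instance_keys(pred_instances)
  if (anyDuplicated(gk)) abort("duplicate gold instance keys")
  if (anyDuplicated(pk)) abort("duplicate predicted instance keys")
  gl <- gold_instances$gold_label
  pl <- if ("pred_label" %in% names(pred_instances)) {
    pred_instances$pred_label
  } else {
    pred_instances$gold_label
  }
  if (mode == "binary") {
    gl <- collapse_binary(gl)
    pl <- collapse_binary(pl)
  }
  gold_pos <- paste(gk, gl)[gl != "None"]
  pred_pos <- paste(pk, pl)[pl != "None"]
  out <- prf_from_keys(gold_pos, pred_pos)
  out$type <- "relation"
  out <- out[c("type", "tp", "fp", "fn", "precision", "recall", "f1")]
  class(out) <- c("ecr_prf", class(out))
  out
}

#' Parse an OBO ontology file (is_a edges only)
#'
#' Reads `[Term]` stanzas, keeping ids and `is_a` parents. Cycles are
#' rejected. Everything else in the file is ignored.
#'
#' @param path OBO file path.
#' @return Object of class `ecr_ontology`: a list with an `edges` tibble
#'   (`child`, `parent`).
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  edges <- tibble(child = character(), parent = character())
  cur <- NA_character_
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { in_term <- TRUE; cur <- NA_character_; next }
    if (startsWith(ln, "[")) { in_term <- FALSE; next }
    if (!in_term) next
    if (startsWith(ln, "id:")) cur <- trimws(sub("^id:", "", ln))
    if (startsWith(ln, "is_a:")) {
      parent <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      edges <- add_row(edges, child = cur, parent = parent)
    }
  }
  ontology_graph(edges)
}

#' Build an ontology graph from an edge table
#'
#' @param edges Tibble with `child` and `parent` columns (directed is_a
#'   edges, child -> parent).
#' @return Object of class `ecr_ontology`.
#' @export
ontology_graph <- function(edges) {
  edges <- as_tibble(edges)[c("child", "parent")]
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  if (!igraph::is_dag(g)) abort("ontology is_a graph contains a cycle")
  structure(list(edges = edges), class = "ecr_ontology")
}

# TRUE when a and b are identical or one single is_a edge apart (parent or
# child), the "relaxed" identifier match. Only ChEBI ids are relaxed; any
# other namespace requires exact equality.
ids_match_relaxed <- function(a, b, ontology) {
  if (a == b) return(TRUE)
  if (!(is_chebi(a) && is_chebi(b))) return(FALSE)
  e <- ontology$edges
  any(e$child == a & e$parent == b) || any(e$child == b & e$parent == a)
}

# Relaxed equality of two identifier sets: a perfect one-to-one pairing in
# which every matched pair is equal-or-adjacent. Sets of unequal size never
# match. Exhaustive over permutations; identifier sets are tiny.
idsets_match <- function(ids_a, ids_b, ontology = NULL, relaxed = FALSE) {
  ids_a <- sort(unique(ids_a)); ids_b <- sort(unique(ids_b))
  if (!relaxed) return(identical(ids_a, ids_b))
  if (length(ids_a) != length(ids_b)) return(FALSE)
  if (length(ids_a) == 0) return(TRUE)
  recurse <- function(a, b) {
    if (!length(a)) return(TRUE)
    for (j in seq_along(b)) {
      if (ids_match_relaxed(a[1], b[j], ontology) &&
          recurse(a[-1], b[-j])) {
        return(TRUE)
      }
    }
    FALSE
  }
  recurse(ids_a, ids_b)
}

#' Evaluate an end-to-end extraction chain
#'
#' Scores predicted binary-pair relations against gold at the end of a full
#' recognition + normalization + relation-extraction chain, in binary
#' classification mode. Under `matching = "exact"` chemical identifier sets
#' must be equal; under `"relaxed"` a ChEBI identifier also matches a direct
#' parent or child in the ontology's is_a graph (one edge — a grandparent
#' does not match). Non-ChEBI identifiers always require exact equality.
#'
#' @param gold,pred `ecr_corpus` objects (relations are taken from each
#'   corpus and converted to in-sentence binary instances).
#' @param ontology An `ecr_ontology`; required when `matching = "relaxed"`.
#' @param matching `"exact"` or `"relaxed"`.
#' @return A one-row tibble of class `ecr_prf`.
#' @export
evaluate_end_to_end <- function(gold, pred, ontology = NULL,
                                matching = c("exact", "relaxed")) {
  matching <- match.arg(matching)
  if (matching == "relaxed" && is.null(ontology)) {
    abort("relaxed matching requires an ontology")
  }
  check_same_pmids(gold, pred)
  gi <- enumerate_binary(gold)
  pi <- enumerate_binary(pred)
  gi <- gi[collapse_binary(gi$gold_label) != "None", ]
  pi <- pi[collapse_binary(pi$gold_label) != "None", ]
  gi$label <- collapse_binary(gi$gold_label)
  pi$label <- collapse_binary(pi$gold_label)
  if (matching == "exact") {
    gold_pos <- paste(instance_keys(gi), gi$label)
    pred_pos <- paste(instance_keys(pi), pi$label)
    out <- prf_from_keys(gold_pos, pred_pos)
  } else {
    # greedy one-to-one matching on pmid + spans + label, identifiers
    # equal-or-adjacent
    used <- rep(FALSE, nrow(gi))
    tp <- 0L
    span_key <- function(x) {
      a <- paste(x$start_a, x$end_a, sep = ";")
      b <- paste(x$start_b, x$end_b, sep = ";")
      paste(x$pmid, pmin(a, b), pmax(a, b), x$label)
    }
    gkey <- if (nrow(gi)) span_key(gi) else character()
    for (i in seq_len(nrow(pi))) {
      pkey <- span_key(pi[i, ])
      cand <- which(!used & gkey == pkey)
      for (j in cand) {
        # align identifier sets side-by-side in both orientations
        straight <-
          idsets_match(pi$ids_a[[i]], gi$ids_a[[j]], ontology, TRUE) &&
          idsets_match(pi$ids_b[[i]], gi$ids_b[[j]], ontology, TRUE)
        crossed <-
          idsets_match(pi$ids_a[[i]], gi$ids_b[[j]], ontology, TRUE) &&
          idsets_match(pi$ids_b[[i]], gi$ids_a[[j]], ontology, TRUE)
        if (straight || crossed) {
          used[j] <- TRUE
          tp <- tp + 1L
          break
        }
      }
    }
    out <- prf(tp, nrow(pi) - tp, nrow(gi) - tp)
  }
  out$type <- paste0("end_to_end (", matching, ")")
  out <- out[c("type", "tp", "fp", "fn", "precision", "recall", "f1")]
  class(out) <- c("ecr_prf", class(out))
  out
}
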