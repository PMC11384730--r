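#' Marker configuration for rendered relation instances
#'
#' The tagged input representation prefixes a task tag and wraps the target
#' mentions in boundary markers: the two chemicals of the pair and, for
#' ternary instances, the candidate enzyme (`<P>`/`</P>`).
#'
#' @param task_tag Task tag prefixed to the sentence.
#' @param c1_open,c1_close,c2_open,c2_close Chemical-pair markers.
#' @param p_open,p_close Protein markers.
#' @return A named list of class `ecr_dialect`.
#' @export
tag_dialect <- function(task_tag = "[Reaction]",
                        c1_open = "<C1>", c1_close = "</C1>",
                        c2_open = "<C2>", c2_close = "</C2>",
                        p_open = "<P>", p_close = "</P>") {
  structure(list(task_tag = task_tag, c1_open = c1_open, c1_close = c1_close,
                 c2_open = c2_open, c2_close = c2_close,
                 p_open = p_open, p_close = p_close),
            class = "ecr_dialect")
}

# Per-document scaffolding shared by the two enumerators: sentence spans,
# the in-sentence chemical and protein-like mentions, and the curated
# relations restricted to within-sentence evidence.
instance_scaffold <- function(corpus, pmid) {
  txt <- document_text(corpus, pmid)
  tokens <- segment_text(txt)
  sents <- sentence_spans(tokens)
  men <- corpus$mentions[corpus$mentions$pmid == pmid, ]
  men$sentence_index <- vapply(seq_len(nrow(men)), function(i) {
    s <- sents$sentence_index[sents$start <= men$start[i] &
                                sents$end >= men$end[i]]
    if (length(s) == 1) s else NA_integer_
  }, integer(1))
  men$is_chem <- vapply(seq_len(nrow(men)), function(i) {
    ref_is_chemical(men$entity_type[i], men$identifiers[[i]])
  }, logical(1))
  men$is_prot <- vapply(seq_len(nrow(men)), function(i) {
    ref_is_protein(men$entity_type[i], men$identifiers[[i]])
  }, logical(1))
  rel <- corpus$relations[corpus$relations$pmid == pmid, ]
  list(text = txt, sentences = sents, mentions = men, relations = rel)
}

#' Enumerate binary chemical-pair classification instances
#'
#' Every unordered pair of chemical mentions co-occurring in a sentence
#' yields exactly one instance. The gold label is the curated relation type
#' linking the two mentions when one exists, and `"None"` otherwise (the
#' synthetic negative class of the classification task). Curated relations
#' whose evidence spans several sentences are excluded from enumeration
#' (with a message) but remain in the corpus.
#'
#' @param corpus An `ecr_corpus`.
#' @param pmids Documents to enumerate; defaults to all.
#' @return Tibble with columns `pmid`, `sentence_index`, `chem_a`, `chem_b`
#'   (mention ids, ordered by span start), per-mention spans/ids
#'   (`start_a`, `end_a`, `ids_a`, ...), and `gold_label`.
#' @export
enumerate_binary <- function(corpus, pmids = corpus$documents$pmid) {
  bind_rows(lapply(pmids, function(pm) enumerate_binary_doc(corpus, pm)))
}

enumerate_binary_doc <- function(corpus, pmid) {
  sc <- instance_scaffold(corpus, pmid)
  men <- sc$mentions
  chem <- men[men$is_chem & !is.na(men$sentence_index), ]
  out <- tibble(pmid = character(), sentence_index = integer(),
                chem_a = character(), chem_b = character(),
                start_a = integer(), end_a = integer(), ids_a = list(),
                start_b = integer(), end_b = integer(), ids_b = list(),
                gold_label = character())
  # curated pairs, keyed on unordered mention-id pairs, in-sentence only
  rel <- sc$relations
  if (nrow(rel)) {
    sent_of <- setNames(men$sentence_index, men$mention_id)
    same <- !is.na(sent_of[rel$chem_a]) &
      sent_of[rel$chem_a] == sent_of[rel$chem_b]
    if (any(!same)) {
      inform(paste0("pmid ", pmid, ": ", sum(!same),
                    " relation(s) with cross-sentence evidence excluded",
                    " from instance enumeration"))
    }
    rel <- rel[same, ]
  }
  rel_key <- if (nrow(rel)) {
    vapply(seq_len(nrow(rel)), function(i) {
      paste(sort(c(rel$chem_a[i], rel$chem_b[i])), collapse = "|")
    }, character(1))
  } else character()

  for (s in unique(chem$sentence_index)) {
    cm <- chem[chem$sentence_index == s, ]
    cm <- cm[order(cm$start), ]
    if (nrow(cm) < 2) next
    idx <- combn(nrow(cm), 2)
    for (k in seq_len(ncol(idx))) {
      a <- cm[idx[1, k], ]; b <- cm[idx[2, k], ]
      key <- paste(sort(c(a$mention_id, b$mention_id)), collapse = "|")
      lab <- rel$relation_type[match(key, rel_key)]
      out <- add_row(out, pmid = pmid, sentence_index = s,
                     chem_a = a$mention_id, chem_b = b$mention_id,
                     start_a = a$start, end_a = a$end,
                     ids_a = a$identifiers,
                     start_b = b$start, end_b = b$end,
                     ids_b = b$identifiers,
                     gold_label = if (is.na(lab)) "None" else lab)
    }
  }
  out
}

#' Enumerate ternary enzyme-tuple classification instances
#'
#' The cross product of every protein-like mention in a sentence with every
#' chemical pair of the same sentence. A tuple's label is the pair's curated
#' relation type when the protein is among that relation's converters, and
#' `"None"` otherwise — including tuples whose chemical pair is curated but
#' whose protein was not linked to it, and tuples over uncurated pairs. Each
#' occurrence of a repeated protein is its own instance.
#'
#' @inheritParams enumerate_binary
#' @return The [enumerate_binary()] columns plus `protein`, `start_p`,
#'   `end_p`, `ids_p`.
#' @export
enumerate_ternary <- function(corpus, pmids = corpus$documents$pmid) {
  bind_rows(lapply(pmids, function(pm) enumerate_ternary_doc(corpus, pm)))
}

enumerate_ternary_doc <- function(corpus, pmid) {
  pairs <- enumerate_binary_doc(corpus, pmid)
  sc <- instance_scaffold(corpus, pmid)
  men <- sc$mentions
  prot <- men[men$is_prot & !is.na(men$sentence_index), ]
  rel <- sc$relations
  out <- pairs[0, ]
  out$protein <- character()
  out$start_p <- integer(); out$end_p <- integer(); out$ids_p <- list()
  for (i in seq_len(nrow(pairs))) {
    pr <- prot[prot$sentence_index == pairs$sentence_index[i], ]
    if (!nrow(pr)) next
    key <- paste(sort(c(pairs$chem_a[i], pairs$chem_b[i])), collapse = "|")
    conv <- character()
    if (pairs$gold_label[i] != "None" && nrow(rel)) {
      hit <- vapply(seq_len(nrow(rel)), function(j) {
        paste(sort(c(rel$chem_a[j], rel$chem_b[j])), collapse = "|") == key &&
          rel$relation_type[j] == pairs$gold_label[i]
      }, logical(1))
      conv <- unique(unlist(rel$converters[hit]))
    }
    for (j in seq_len(nrow(pr))) {
      lab <- if (pr$mention_id[j] %in% conv) pairs$gold_label[i] else "None"
      row <- pairs[i, ]
      row$gold_label <- lab
      row$protein <- pr$mention_id[j]
      row$start_p <- pr$start[j]; row$end_p <- pr$end[j]
      row$ids_p <- pr$identifiers[j]
      out <- bind_rows(out, row)
    }
  }
  out
}

#' Render the tagged input representation of an instance
#'
#' Produces the classifier input text for one enumerated instance: the
#' sentence with the chemical pair (and, for ternary instances, the protein)
#' wrapped in boundary markers, prefixed by the task tag. Markers are
#' inserted right-to-left so earlier offsets stay valid; all original
#' characters are preserved, so
#' `nchar(out) == nchar(task prefix) + nchar(sentence) + nchar(markers)`.
#'
#' @param instance One row of [enumerate_binary()] or [enumerate_ternary()].
#' @param corpus The corpus the instance came from.
#' @param dialect A [tag_dialect()].
#' @return The tagged sentence string.
#' @export
render_instance <- function(instance, corpus, dialect = tag_dialect()) {
  stopifnot(nrow(instance) == 1)
  txt <- document_text(corpus, instance$pmid)
  sents <- sentence_spans(segment_text(txt))
  srow <- sents[sents$sentence_index == instance$sentence_index, ]
  sent <- substring(txt, srow$start + 1L, srow$end)
  ins <- tibble(
    start = c(instance$start_a, instance$start_b) - srow$start,
    end = c(instance$end_a, instance$end_b) - srow$start,
    open = c(dialect$c1_open, dialect$c2_open),
    close = c(dialect$c1_close, dialect$c2_close)
  )
  if ("protein" %in% names(instance) && !is.na(instance$protein)) {
    ins <- add_row(ins, start = instance$start_p - srow$start,
                   end = instance$end_p - srow$start,
                   open = dialect$p_open, close = dialect$p_close)
  }
  ins <- ins[order(ins$start), ]
  if (any(ins$start[-1] < ins$end[-nrow(ins)])) {
    abort("target mentions overlap; markers cannot be nested")
  }
  for (i in rev(seq_len(nrow(ins)))) {
    sent <- paste0(substring(sent, 1, ins$start[i]),
                   ins$open[i],
                   substring(sent, ins$start[i] + 1L, ins$end[i]),
                   ins$close[i],
                   substring(sent, ins$end[i] + 1L))
  }
  paste0(dialect$task_tag, " ", sent)
}

#' Deterministic trigger-word relation baseline
#'
#' A naive rule-based classifier over the instance's sentence text, provided
#' so that evaluation and end-to-end plumbing can be exercised without any
#' trained model. It is documented as a baseline, not a reimplementation of
#' a neural classifier: negation and pathway cues are checked first, then
#' conversion trigger words (`"converts"`, `"catalyzes the conversion of"`,
#' `"hydrolyzes"`, ...), else `"None"`.
#'
#' @param sentence Sentence text (untagged or tagged).
#' @return One of `"Conversion"`, `"Indirect_conversion"`,
#'   `"Non_conversion"`, `"None"`.
#' @export
baseline_classify <- function(sentence) {
  s <- tolower(sentence)
  if (grepl("no detectable formation|did not convert|not converted|failed to convert",
            s)) {
    return("Non_conversion")
  }
  if (grepl("via a series of|through .*intermediates|indirect", s)) {
    return("Indirect_conversion")
  }
  if (grepl(paste0("converts|catalyzes the conversion of|hydrolyzes|",
                   "is converted to|converted .* into|formed .* from|into"),
            s)) {
    return("Conversion")
  }
  "None"
}
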