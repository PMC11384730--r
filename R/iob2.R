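#' Segment text into sentences and tokens
#'
#' A lightweight rule-based segmenter: sentence boundaries are placed after
#' runs of `.`, `!` or `?` that are followed by whitespace; tokens are
#' maximal alphanumeric runs, with every other non-whitespace character its
#' own token. The segmentation contract is what matters downstream, not the
#' particular tokenizer: every non-whitespace character belongs to exactly
#' one token, token spans are strictly increasing and never cross sentence
#' boundaries.
#'
#' @param text Document text (offsets in the result index into it, 0-based,
#'   half-open).
#' @return A tibble with columns `sentence_index` (1-based), `token_index`,
#'   `surface`, `start`, `end`. Empty text yields zero rows.
#' @export
#' @examples
#' segment_text("ABC1 is a hydrolase. It acts on lipids.")
segment_text <- function(text) {
  empty <- tibble(sentence_index = integer(), token_index = integer(),
                  surface = character(), start = integer(), end = integer())
  if (is.null(text) || !nzchar(text)) return(empty)
  # sentence boundaries: after terminal punctuation followed by whitespace
  m <- gregexpr("[.!?]+(?=[[:space:]])", text, perl = TRUE)[[1]]
  bounds <- if (m[1] == -1) integer() else as.integer(m) +
    attr(m, "match.length") - 1L
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, nchar(text))
  out <- empty
  sent_i <- 0L
  for (k in seq_along(starts)) {
    seg <- substring(text, starts[k], ends[k])
    tm <- gregexpr("[A-Za-z0-9]+|[^A-Za-z0-9[:space:]]", seg)[[1]]
    if (tm[1] == -1) next
    sent_i <- sent_i + 1L
    tok_start <- as.integer(tm) + starts[k] - 2L      # 0-based
    tok_end <- tok_start + attr(tm, "match.length")
    out <- bind_rows(out, tibble(
      sentence_index = sent_i,
      token_index = seq_along(tok_start),
      surface = substring(text, tok_start + 1L, tok_end),
      start = tok_start, end = tok_end
    ))
  }
  out
}

#' Sentence spans of a document
#'
#' Collapses [segment_text()] output to one row per sentence with the span
#' covering its first to last token.
#' @param tokens Output of [segment_text()].
#' @return Tibble with `sentence_index`, `start`, `end`.
#' @export
sentence_spans <- function(tokens) {
  if (!nrow(tokens)) {
    return(tibble(sentence_index = integer(), start = integer(),
                  end = integer()))
  }
  tokens |>
    group_by(.data$sentence_index) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop")
}

# Label set of the sequence-labelling task. The outside label carries the
# task name ("O-Reaction") so a single tagger can be trained across corpora;
# protein mentions map to the Gene labels used by general-purpose biomedical
# taggers.
IOB2_LABELS <- c("O-Reaction", "B-Chemical", "I-Chemical", "B-Gene", "I-Gene")

#' Encode mention annotations as IOB2 label sequences
#'
#' Converts the mentions of one document into token-aligned IOB2 labels over
#' the closed set `O-Reaction, B-Chemical, I-Chemical, B-Gene, I-Gene`:
#' chemical mentions become `B-/I-Chemical`, protein mentions `B-/I-Gene`,
#' everything else `O-Reaction`. Domain, MutantEnzyme and Coreference
#' mentions are excluded by default (they are not curated exhaustively and
#' are excluded from evaluation); `include_extra = TRUE` maps them to the
#' Gene labels for experimentation. A mention whose span does not fall on
#' token boundaries is snapped outward to the covering tokens, with a
#' message.
#'
#' @param corpus An `ecr_corpus`.
#' @param pmid Document to encode.
#' @param tokens Optional [segment_text()] output for the document; computed
#'   from the document text when omitted.
#' @param include_extra Also encode Domain/MutantEnzyme/Coreference (as Gene).
#' @return `tokens` with an added `label` column.
#' @export
encode_iob2 <- function(corpus, pmid, tokens = NULL, include_extra = FALSE) {
  tokens <- tokens %||% segment_text(document_text(corpus, pmid))
  men <- corpus$mentions[corpus$mentions$pmid == pmid, ]
  keep_types <- c("Chemical", "Protein")
  if (include_extra) keep_types <- ENTITY_TYPES
  men <- men[men$entity_type %in% keep_types, ]
  labels <- rep("O-Reaction", nrow(tokens))
  if (nrow(men)) {
    men$iob_type <- ifelse(men$entity_type == "Chemical", "Chemical", "Gene")
    claimed <- rep(NA_character_, nrow(tokens)) # mention id claiming a token
    for (i in order(men$start)) {
      cover <- which(tokens$end > men$start[i] & tokens$start < men$end[i])
      if (!length(cover)) next
      if (tokens$start[min(cover)] != men$start[i] ||
          tokens$end[max(cover)] != men$end[i]) {
        inform(paste0("mention ", men$mention_id[i], " in pmid ", pmid,
                      " snapped outward to token boundaries"))
      }
      if (length(unique(tokens$sentence_index[cover])) > 1) {
        abort(paste0("mention ", men$mention_id[i],
                     " crosses a sentence boundary"))
      }
      clash <- cover[!is.na(claimed[cover])]
      if (length(clash)) {
        abort(paste0("overlapping mentions on token(s) ",
                     paste(tokens$surface[clash], collapse = ", "),
                     " in pmid ", pmid, ": ", men$mention_id[i], " vs ",
                     paste(unique(claimed[clash]), collapse = ", ")))
      }
      claimed[cover] <- men$mention_id[i]
      labels[cover] <- paste0("I-", men$iob_type[i])
      labels[min(cover)] <- paste0("B-", men$iob_type[i])
    }
  }
  tokens$label <- labels
  tokens
}

#' Decode IOB2 labels back to mentions
#'
#' Inverse of [encode_iob2()] for boundary-aligned mentions. An `I-X` label
#' that does not continue a chunk of type `X` (e.g. at sentence start or
#' after `O-Reaction`) is repaired by treating it as `B-X`, with a warning.
#'
#' @param tokens Tibble with token spans and a `label` column (as produced by
#'   [encode_iob2()], or labels supplied separately via `labels`).
#' @param labels Optional character vector, length `nrow(tokens)`.
#' @param full_text Optional document text used to recover the exact surface
#'   (including original whitespace) of multi-token mentions; token surfaces
#'   joined by single spaces are used when omitted.
#' @return Tibble of decoded mentions: `start`, `end`, `surface`,
#'   `entity_type` (`Chemical` or `Protein`), `sentence_index`.
#' @export
decode_iob2 <- function(tokens, labels = NULL, full_text = NULL) {
  labels <- labels %||% tokens$label
  if (length(labels) != nrow(tokens)) {
    abort("labels and tokens have different lengths")
  }
  bad <- setdiff(unique(labels), IOB2_LABELS)
  if (length(bad)) abort(paste0("labels outside the label set: ",
                                paste(bad, collapse = ", ")))
  out <- tibble(start = integer(), end = integer(), surface = character(),
                entity_type = character(), sentence_index = integer())
  cur <- NULL
  flush <- function(out, cur) {
    if (is.null(cur)) return(out)
    surface <- if (!is.null(full_text)) {
      substring(full_text, cur$start + 1L, cur$end)
    } else cur$surface
    add_row(out, start = cur$start, end = cur$end, surface = surface,
            entity_type = if (cur$type == "Gene") "Protein" else "Chemical",
            sentence_index = cur$sent)
  }
  for (i in seq_len(nrow(tokens))) {
    lab <- labels[i]
    if (lab == "O-Reaction") {
      out <- flush(out, cur); cur <- NULL
      next
    }
    prefix <- substr(lab, 1, 1)
    type <- substring(lab, 3)
    new_sentence <- !is.null(cur) && tokens$sentence_index[i] != cur$sent
    continues <- !is.null(cur) && cur$type == type && !new_sentence
    if (prefix == "I" && !continues) {
      warn(paste0("ill-formed I-", type, " at token ", i,
                  " treated as B-", type))
      prefix <- "B"
    }
    if (prefix == "B") {
      out <- flush(out, cur)
      cur <- list(start = tokens$start[i], end = tokens$end[i],
                  surface = tokens$surface[i], type = type,
                  sent = tokens$sentence_index[i])
    } else {
      cur$end <- tokens$end[i]
      cur$surface <- paste(cur$surface, tokens$surface[i])
    }
  }
  flush(out, cur)
}

#' Write token/label sequences as CoNLL-style TSV
#'
#' Two columns (token TAB label), one token per line, a blank line between
#' sentences.
#' @param encoded Output of [encode_iob2()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conll <- function(encoded, path) {
  lines <- character()
  for (s in unique(encoded$sentence_index)) {
    seg <- encoded[encoded$sentence_index == s, ]
    lines <- c(lines, paste0(seg$surface, "\t", seg$label), "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read CoNLL-style token/label TSV
#' @param path Input path.
#' @return Tibble with `sentence_index`, `token_index`, `surface`, `label`
#'   (no character offsets: the TSV format does not carry them).
#' @export
read_conll <- function(path) {
  lines <- readLines(path)
  out <- tibble(sentence_index = integer(), token_index = integer(),
                surface = character(), label = character())
  sent <- 1L; tok <- 0L; any_tok <- FALSE
  for (ln in lines) {
    if (!nzchar(ln)) {
      if (any_tok) { sent <- sent + 1L; tok <- 0L; any_tok <- FALSE }
      next
    }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    tok <- tok + 1L; any_tok <- TRUE
    out <- add_row(out, sentence_index = sent, token_index = tok,
                   surface = parts[1], label = parts[2])
  }
  out
}
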