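#' Read reaction participants from TSV
#'
#' Format: `rhea_id TAB side TAB chebi_id TAB coefficient`, where `side` is
#' `left` or `right`. Lines starting with `#` and a header line are ignored.
#'
#' @param path TSV path.
#' @return Tibble with those four columns.
#' @export
read_reactions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  parts <- parts[vapply(parts, function(p) length(p) >= 3 &&
                          p[2] %in% c("left", "right"), logical(1))]
  tibble(
    rhea_id = map_chr(parts, 1),
    side = map_chr(parts, 2),
    chebi_id = map_chr(parts, 3),
    coefficient = vapply(parts, function(p) {
      if (length(p) >= 4) as.numeric(p[4]) else 1
    }, numeric(1))
  )
}

#' Most frequent compounds across a reaction set
#'
#' The `k` compounds participating in the largest number of reactions —
#' ubiquitous species such as water, oxygen and protons — to be excluded
#' before pair enumeration. Frequency is the number of distinct reactions a
#' compound occurs in. Ties at rank `k` include every tied compound (so the
#' result can exceed `k`), with a warning.
#'
#' @param reactions Tibble as from [read_reactions()].
#' @param k Number of top compounds (default 100).
#' @return Character vector of ChEBI ids.
#' @export
top_compounds <- function(reactions, k = 100) {
  if (k <= 0) abort("k must be a positive count")
  freq <- reactions |>
    distinct(.data$rhea_id, .data$chebi_id) |>
    count(.data$chebi_id, sort = TRUE)
  if (nrow(freq) <= k) return(freq$chebi_id)
  cut <- freq$n[k]
  keep <- freq$n >= cut
  if (sum(keep) > k) {
    warn(paste0("frequency tie at rank ", k, ": returning ", sum(keep),
                " compounds"))
  }
  freq$chebi_id[keep]
}

#' Enumerate reference chemical pairs from reactions
#'
#' For each reaction, all unordered pairs of its participants after removing
#' the excluded (ubiquitous) compounds. By default pairs are formed across
#' the whole participant set — both within one side and across sides, the
#' literal reading of "all possible pairs"; `cross_side_only = TRUE`
#' restricts to left-right pairs. Pairs of identical ChEBI ids (which arise
#' from transport reactions) are removed. Members are canonically ordered by
#' numeric id.
#'
#' @param reactions Tibble as from [read_reactions()].
#' @param excluded Character vector of ids to exclude (typically
#'   [top_compounds()] output).
#' @param cross_side_only Only pair compounds from opposite sides.
#' @return Tibble with `id_a`, `id_b` (id_a < id_b numerically), `rhea_id`.
#' @export
rhea_pairs <- function(reactions, excluded = character(),
                       cross_side_only = FALSE) {
  out <- tibble(id_a = character(), id_b = character(), rhea_id = character())
  for (rid in unique(reactions$rhea_id)) {
    rx <- reactions[reactions$rhea_id == rid &
                      !reactions$chebi_id %in% excluded, ]
    prs <- if (cross_side_only) {
      left <- unique(rx$chebi_id[rx$side == "left"])
      right <- unique(rx$chebi_id[rx$side == "right"])
      if (!length(left) || !length(right)) next
      expand.grid(a = left, b = right, stringsAsFactors = FALSE)
    } else {
      ids <- unique(rx$chebi_id)
      if (length(ids) < 2) next
      m <- combn(ids, 2)
      data.frame(a = m[1, ], b = m[2, ], stringsAsFactors = FALSE)
    }
    prs <- prs[prs$a != prs$b, , drop = FALSE]
    if (!nrow(prs)) next
    swap <- id_number(prs$a) > id_number(prs$b)
    tmp <- prs$a[swap]; prs$a[swap] <- prs$b[swap]; prs$b[swap] <- tmp
    out <- bind_rows(out, tibble(id_a = prs$a, id_b = prs$b, rhea_id = rid) |>
                       distinct())
  }
  out
}

#' Distinct unordered id pairs
#'
#' Collapses a pair table to its unique canonical id pairs, dropping
#' provenance columns.
#' @param pairs Tibble with `id_a`, `id_b`.
#' @return Tibble with distinct `id_a`, `id_b` rows (id_a before id_b
#'   numerically).
#' @export
distinct_pairs <- function(pairs) {
  swap <- id_number(pairs$id_a) > id_number(pairs$id_b)
  tmp <- pairs$id_a[swap]; pairs$id_a[swap] <- pairs$id_b[swap]
  pairs$id_b[swap] <- tmp
  distinct(pairs[c("id_a", "id_b")])
}

#' Normalize predicted chemical pairs for reference comparison
#'
#' Applies, in order: (0) removal of pairs with a non-ChEBI member (counted,
#' not silently dropped); (1) pH 7.3 remapping of both members; (2) removal
#' of pairs containing an excluded (ubiquitous) compound; (3) removal of
#' pairs whose members collapsed to the same id (a symptom of span errors
#' upstream); then deduplication to unique unordered pairs. The rows removed
#' at each stage are recorded in the `stage_counts` attribute, whose
#' `removed` column reconciles: `sum(removed) == nrow(in) - nrow(out)` up to
#' the final dedup stage, which is also listed.
#'
#' @param pairs Tibble with `id_a`, `id_b` (plus any provenance columns,
#'   dropped on dedup).
#' @param ph_map Mapping from [read_ph73()] (optional).
#' @param excluded Ids to exclude.
#' @return Tibble of unique normalized pairs, with attribute
#'   `stage_counts`.
#' @export
normalize_predictions <- function(pairs, ph_map = NULL,
                                  excluded = character()) {
  n0 <- nrow(pairs)
  chebi_ok <- is_chebi(pairs$id_a) & is_chebi(pairs$id_b)
  pairs <- pairs[chebi_ok, , drop = FALSE]
  n_nonchebi <- n0 - nrow(pairs)
  if (!is.null(ph_map)) {
    pairs$id_a <- apply_ph73(pairs$id_a, ph_map)
    pairs$id_b <- apply_ph73(pairs$id_b, ph_map)
  }
  keep <- !(pairs$id_a %in% excluded | pairs$id_b %in% excluded)
  n_excluded <- sum(!keep)
  pairs <- pairs[keep, , drop = FALSE]
  keep <- pairs$id_a != pairs$id_b
  n_identical <- sum(!keep)
  pairs <- pairs[keep, , drop = FALSE]
  before_dedup <- nrow(pairs)
  out <- distinct_pairs(pairs)
  attr(out, "stage_counts") <- tibble(
    stage = c("non_chebi", "excluded_compound", "identical_after_ph73",
              "duplicate"),
    removed = c(n_nonchebi, n_excluded, n_identical,
                before_dedup - nrow(out))
  )
  out
}

#' Compare predicted pairs to a reference pair set
#'
#' Counts, per relation type and overall, how many unique predicted pairs
#' are present in the reference set, and the percentage.
#'
#' @param pred Tibble with `id_a`, `id_b` and optionally `relation_type`.
#' @param reference Tibble with `id_a`, `id_b`.
#' @return Tibble of class `ecr_comparison` with `relation_type`, `n_pred`,
#'   `n_shared`, `pct_in_reference`.
#' @export
compare_pairs <- function(pred, reference) {
  ref_keys <- with(distinct_pairs(reference), paste(id_a, id_b))
  row_for <- function(label, prs) {
    u <- distinct_pairs(prs)
    keys <- paste(u$id_a, u$id_b)
    shared <- sum(keys %in% ref_keys)
    tibble(relation_type = label, n_pred = nrow(u), n_shared = shared,
           pct_in_reference = if (nrow(u)) 100 * shared / nrow(u) else 0)
  }
  out <- row_for("All", pred)
  if ("relation_type" %in% names(pred)) {
    for (tp in intersect(RELATION_TYPES, unique(pred$relation_type))) {
      out <- bind_rows(out,
                       row_for(tp, pred[pred$relation_type == tp, ]))
    }
  }
  class(out) <- c("ecr_comparison", class(out))
  out
}
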