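#' Molecular graph of a SMILES string
#'
#' Parses SMILES (via ChemmineR/ChemmineOB, i.e. Open Babel) and reduces the
#' molecule to the form used by the atom-conservation metric: heavy atoms
#' only (hydrogens implicit) and every bond replaced by a single bond, so
#' the molecule becomes a plain vertex-labelled graph of elements.
#'
#' @param smiles A single SMILES string.
#' @param side Label used in error messages (`"left"`/`"right"`).
#' @return A list with `elements` (character vector, one per heavy atom) and
#'   `bonds` (two-column integer matrix of atom indices).
#' @export
parse_smiles <- function(smiles, side = "molecule") {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    abort("SMILES parsing requires the ChemmineOB package (Open Babel)")
  }
  sdf <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", source = paste0(smiles, "\n")),
    error = function(e) ""
  )
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  # V2000 counts line is the 4th line of the MOL block
  counts <- if (length(lines) >= 4) lines[4] else ""
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || n_atoms == 0 || !grepl("V2000", counts)) {
    abort(paste0("cannot parse SMILES on the ", side, " side: ",
                 dQuote(smiles)))
  }
  atom_lines <- lines[5:(4 + n_atoms)]
  elements <- vapply(strsplit(trimws(atom_lines), "\\s+"), `[[`,
                     character(1), 4)
  bonds <- if (n_bonds > 0) {
    bl <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    # fixed-width fields: atom indices in columns 1-3 and 4-6
    cbind(as.integer(substr(bl, 1, 3)), as.integer(substr(bl, 4, 6)))
  } else {
    matrix(integer(), ncol = 2)
  }
  heavy <- which(elements != "H")
  if (!length(heavy)) {
    abort(paste0("no heavy atoms in SMILES on the ", side, " side: ",
                 dQuote(smiles)))
  }
  remap <- match(seq_along(elements), heavy)
  keep <- !is.na(remap[bonds[, 1]]) & !is.na(remap[bonds[, 2]])
  bonds <- cbind(remap[bonds[keep, 1]], remap[bonds[keep, 2]])
  list(elements = elements[heavy], bonds = bonds)
}

mol_igraph <- function(mol) {
  g <- igraph::make_empty_graph(n = length(mol$elements), directed = FALSE)
  if (nrow(mol$bonds)) g <- igraph::add_edges(g, t(mol$bonds))
  igraph::set_vertex_attr(g, "element", value = mol$elements)
}

#' Maximum common substructure size of two molecular graphs
#'
#' Number of atoms in the largest common element-labelled induced subgraph
#' of the two single-bond molecular graphs, computed as a maximum clique in
#' their modular product (vertices are element-matched atom pairs; edges
#' require agreement on adjacency). The common substructure is allowed to be
#' disconnected, which makes the matching permissive across ring fusions.
#' Exact but exponential in the worst case — intended for the small-molecule
#' regime of metabolic chemistry.
#'
#' @param mol_a,mol_b Results of [parse_smiles()].
#' @return Integer atom count (0 when no elements are shared).
#' @export
mcs_size <- function(mol_a, mol_b) {
  na <- length(mol_a$elements); nb <- length(mol_b$elements)
  adj <- function(mol, n) {
    m <- matrix(FALSE, n, n)
    if (nrow(mol$bonds)) {
      m[mol$bonds] <- TRUE
      m[mol$bonds[, c(2, 1), drop = FALSE]] <- TRUE
    }
    m
  }
  aa <- adj(mol_a, na); ab <- adj(mol_b, nb)
  pairs <- which(outer(mol_a$elements, mol_b$elements, "=="), arr.ind = TRUE)
  np <- nrow(pairs)
  if (np == 0) return(0L)
  edges <- integer()
  for (i in seq_len(np - 1L)) {
    for (j in seq.int(i + 1L, np)) {
      u1 <- pairs[i, 1]; v1 <- pairs[i, 2]
      u2 <- pairs[j, 1]; v2 <- pairs[j, 2]
      if (u1 != u2 && v1 != v2 && aa[u1, u2] == ab[v1, v2]) {
        edges <- c(edges, i, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n = np, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  as.integer(igraph::clique_num(g))
}

#' Atom conservation between the two members of a chemical pair
#'
#' The average fraction of atoms shared through the maximum common
#' substructure:
#' `percent = 1/2 * (n_MCS / n_L + n_MCS / n_R) * 100`,
#' where `n_MCS` is the atom count of the maximum common substructure of the
#' two single-bond heavy-atom graphs and `n_L`, `n_R` the heavy-atom counts
#' of the left and right molecule. 100 means the smaller molecule's graph
#' covers both (identical graphs when sizes agree); genuine
#' substrate-product pairs score high, spurious pairs low, which makes the
#' metric a useful filter on text-mined pairs.
#'
#' @param smiles_l,smiles_r SMILES of the left and right member.
#' @return A one-row tibble with `n_mcs`, `n_l`, `n_r`, `percent`.
#' @export
#' @examples
#' \dontrun{
#' atom_conservation("CCO", "CC=O")  # 100: both reduce to C-C-O
#' atom_conservation("CCO", "C")    # 1 shared atom: 66.67
#' }
atom_conservation <- function(smiles_l, smiles_r) {
  ml <- parse_smiles(smiles_l, side = "left")
  mr <- parse_smiles(smiles_r, side = "right")
  n_mcs <- mcs_size(ml, mr)
  n_l <- length(ml$elements)
  n_r <- length(mr$elements)
  tibble(n_mcs = n_mcs, n_l = n_l, n_r = n_r,
         percent = 0.5 * (n_mcs / n_l + n_mcs / n_r) * 100)
}

#' Filter chemical pairs by atom conservation
#'
#' Computes the atom-conservation percentage for each pair whose two members
#' have a SMILES in `smiles` and keeps pairs at or above `threshold`. The
#' default threshold of 79.76% is the mean atom conservation over curated
#' reference reaction pairs with defined structures, which separates
#' plausible substrate-product pairs from incidental co-mentions; pairs
#' without structures for both members are dropped (they cannot be scored).
#'
#' @param pairs Tibble with `id_a`, `id_b`.
#' @param smiles Tibble with `chebi_id`, `smiles`.
#' @param threshold Minimum percentage to keep.
#' @return The filtered tibble with an added `atom_conservation` column.
#' @export
filter_conserved <- function(pairs, smiles, threshold = 79.76) {
  sm <- setNames(smiles$smiles, smiles$chebi_id)
  has <- pairs$id_a %in% names(sm) & pairs$id_b %in% names(sm)
  pairs <- pairs[has, , drop = FALSE]
  pairs$atom_conservation <- vapply(seq_len(nrow(pairs)), function(i) {
    atom_conservation(sm[[pairs$id_a[i]]], sm[[pairs$id_b[i]]])$percent
  }, numeric(1))
  pairs[pairs$atom_conservation >= threshold, , drop = FALSE]
}

#' Jaccard distance between reaction fingerprints of two chemical pairs
#'
#' Thin adapter over an external differential reaction fingerprint (DRFP)
#' provider: `provider` must be a function taking a character vector of two
#' SMILES (the canonically ordered pair) and returning a logical or 0/1
#' fingerprint vector. The distance is the Jaccard distance between the two
#' pairs' fingerprints; pairs are sorted before fingerprinting, so member
#' order never affects the result. Fingerprint hashing itself is not
#' implemented here.
#'
#' @param smiles_pair_a,smiles_pair_b Character vectors of two SMILES each.
#' @param provider Fingerprint function; without one the feature is
#'   unavailable and an informative error is raised.
#' @return Distance in \[0, 1\]; identical inputs give 0.
#' @export
drfp_distance <- function(smiles_pair_a, smiles_pair_b, provider = NULL) {
  if (is.null(provider)) {
    abort(paste0("no DRFP provider configured: pass a fingerprint function ",
                 "(e.g. wrapping an external DRFP implementation) as ",
                 "`provider`"))
  }
  fa <- as.logical(provider(sort(smiles_pair_a)))
  fb <- as.logical(provider(sort(smiles_pair_b)))
  if (length(fa) != length(fb)) {
    abort("provider returned fingerprints of different lengths")
  }
  union <- sum(fa | fb)
  if (union == 0) return(0)
  1 - sum(fa & fb) / union
}
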