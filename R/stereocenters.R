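#' Find candidate one-hydrogen stereogenic carbons
#'
#' A candidate center is a tetrahedral (all single bonds, non-aromatic,
#' uncharged) carbon bearing exactly one hydrogen and three heavy-atom
#' substituents whose branches are mutually distinguishable. Centers are
#' reported whether or not stereochemistry is drawn in the input: the
#' racemization risk attaches to the center itself, not to the depiction.
#' Branch distinguishability is decided on canonical branch invariants
#' (iterative neighborhood refinement on the molecular graph with the center
#' removed), not on wedge/hash annotations, so equivalent SMILES spellings
#' give identical results.
#'
#' @param mol a parsed `racemol` (see [parse_smiles()]).
#' @return an integer vector of candidate atom indices, ascending; empty when
#'   the molecule has no candidate center.
#' @examples
#' find_stereocenters(parse_smiles("CC1NC(=O)NC1=O"))  # the hydantoin C5-H
#' @export
find_stereocenters <- function(mol) {
  .check_parsed(mol)
  out <- integer(0)
  for (i in seq_len(mol$n_atoms)) {
    if (mol$symbol[i] != "C" || mol$aromatic_atom[i]) next
    if (mol$charge[i] != 0L) next
    if (mol$hcount[i] != 1L) next
    hv <- .heavy_neighbors(mol, i)
    if (length(hv) != 3L) next
    if (any(mol$bond_order[[i]] != 1L)) next
    codes <- vapply(hv, function(u) .branch_code(mol, i, u), character(1))
    if (anyDuplicated(codes)) next
    out <- c(out, i)
  }
  out
}

# Canonical branch invariant: Weisfeiler-Lehman colors on the heavy-atom
# graph with the center deleted, read off in breadth-first shells from the
# branch root. Two branches with equal codes are treated as constitutionally
# equivalent. This is a graph-invariant heuristic: it cannot see meso-type
# parity, which is out of scope for risk screening.
.branch_code <- function(mol, center, root) {
  heavy_idx <- which(mol$heavy)
  keep <- setdiff(heavy_idx, center)
  colors <- paste(mol$symbol[keep], mol$charge[keep], mol$hcount[keep],
                  sep = "/")
  names(colors) <- keep
  adj <- lapply(keep, function(i) {
    nb <- mol$adj[[i]]
    sel <- nb %in% keep
    list(nb = nb[sel], ord = mol$bond_order[[i]][sel])
  })
  names(adj) <- keep
  for (iter in seq_len(length(keep))) {
    new_colors <- vapply(seq_along(keep), function(k) {
      a <- adj[[k]]
      env <- sort(paste(a$ord, colors[as.character(a$nb)], sep = ":"))
      paste(colors[k], paste(env, collapse = ","), sep = "|")
    }, character(1))
    new_ids <- match(new_colors, sort(unique(new_colors)))
    relabeled <- paste0("c", new_ids)
    if (identical(match(relabeled, unique(relabeled)),
                  match(colors, unique(colors)))) break
    colors <- relabeled
    names(colors) <- keep
  }
  # breadth-first shells from the root within the center-deleted graph
  dist <- setNames(rep(NA_integer_, length(keep)), keep)
  dist[as.character(root)] <- 0L
  frontier <- root
  d <- 0L
  shells <- character(0)
  while (length(frontier)) {
    shells <- c(shells, paste(sort(colors[as.character(frontier)]),
                              collapse = ","))
    nxt <- integer(0)
    for (i in frontier) {
      for (j in adj[[match(i, keep)]]$nb) {
        if (is.na(dist[as.character(j)])) {
          dist[as.character(j)] <- d + 1L
          nxt <- c(nxt, j)
        }
      }
    }
    frontier <- nxt
    d <- d + 1L
  }
  paste(shells, collapse = ";")
}

#' Assess whether deprotonation at a center can give an aromatic cyclic anion
#'
#' Checks every ring of size 6 or less through the center: removing the
#' center's hydrogen as a proton leaves a carbanion contributing two
#' electrons from a p-orbital; the ring is counted as potentially aromatic
#' when every other ring atom can hold a p-orbital in conjugation (a multiple
#' bond, an exocyclic carbonyl/thiocarbonyl, or a heteroatom lone pair) and
#' the Hueckel pi-electron count is 4n+2. Acyclic centers are never aromatic.
#'
#' Because the Hueckel count is a heuristic, the decision can be overridden
#' per stereogenic-center type through `overrides` (see
#' [default_aromatic_overrides()]); an override, when present for
#' `center_type`, wins.
#'
#' @param mol a parsed `racemol`.
#' @param center atom index of the candidate center.
#' @param center_type optional center-type letter code used to look up an
#'   override; `NULL` or `"unclassified"` skips the override table.
#' @param overrides named logical vector mapping center-type codes to forced
#'   aromatic-anion values.
#' @return `TRUE` or `FALSE`.
#' @export
assess_aromatic_anion <- function(mol, center, center_type = NULL,
                                  overrides = default_aromatic_overrides()) {
  .check_parsed(mol)
  if (!is.null(center_type) && !identical(center_type, "unclassified") &&
      !is.null(overrides) && center_type %in% names(overrides)) {
    return(unname(overrides[[center_type]]))
  }
  for (ring in mol$rings) {
    if (length(ring) > 6L) next
    if (!(center %in% ring)) next
    if (.ring_is_aromatic(mol, ring, anion_at = center)) return(TRUE)
  }
  FALSE
}

#' Default per-center-type aromatic-anion overrides
#'
#' The split of the fourteen stereogenic-center types between the
#' aromatic-anion and non-aromatic calibration domains is reference data the
#' package does not ship; the conservative default routes every classified
#' type through the non-aromatic relationship. Users holding the published
#' per-type assignment can supply their own vector (e.g.
#' `c(D = TRUE, F = TRUE)`); unclassified centers always fall back to the
#' Hueckel assessment.
#'
#' @return a named logical vector over the center-type codes A-N.
#' @export
default_aromatic_overrides <- function() {
  setNames(rep(FALSE, length(CENTER_TYPES)), names(CENTER_TYPES))
}
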