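#' Parse a SMILES string into a molecule record
#'
#' Converts a SMILES string into an internal connection-table representation
#' (`racemol`) via Open Babel (through \pkg{ChemmineOB}), with explicit
#' hydrogens added so that hydrogen counts are unambiguous. Heavy atoms keep
#' the order in which they appear in the SMILES string; atom indices reported
#' elsewhere in the package are 1-based positions in that order.
#'
#' @param smiles a single SMILES string.
#' @param identifier a non-empty identifier for the record; defaults to the
#'   SMILES string itself.
#' @return an object of class `racemol` with fields `identifier`, `smiles`
#'   and `parse_status` (`"ok"` or `"failed"`). For `parse_status = "ok"` the
#'   object additionally carries the connection table (atoms, bonds, ring
#'   systems, aromaticity flags and hydrogen counts).
#' @examples
#' mol <- parse_smiles("CC1NC(=O)NC1=O", "5-methylhydantoin")
#' mol$parse_status
#' @export
parse_smiles <- function(smiles, identifier = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!is.character(identifier) || length(identifier) != 1L ||
      is.na(identifier) || !nzchar(identifier)) {
    stop("'identifier' must be a non-empty string")
  }
  sdf_text <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF",
      source = paste0(smiles, "\t", "mol", "\n"),
      options = data.frame(names = "h", args = "", stringsAsFactors = FALSE)
    )),
    error = function(e) ""
  )
  if (!is.character(sdf_text) || length(sdf_text) != 1L || !nzchar(sdf_text)) {
    return(structure(
      list(identifier = identifier, smiles = smiles, parse_status = "failed"),
      class = "racemol"
    ))
  }
  mol <- .mol_from_sdf_text(sdf_text)
  mol$identifier <- identifier
  mol$smiles <- smiles
  mol$parse_status <- "ok"
  class(mol) <- "racemol"
  mol
}

#' Read a SMILES file into a list of molecule records
#'
#' Reads one molecule per line; an optional tab-separated second field is the
#' identifier (defaulting to `line<n>`). Unparsable lines yield records with
#' `parse_status = "failed"` rather than aborting the batch.
#'
#' @param path path to a SMILES file.
#' @return a list of `racemol` records.
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) stop("SMILES file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    smi <- trimws(parts[[1]])
    id <- if (length(parts) >= 2L && nzchar(trimws(parts[[2]]))) {
      trimws(parts[[2]])
    } else {
      paste0("line", i)
    }
    out[[i]] <- parse_smiles(smi, id)
  }
  out
}

#' @export
print.racemol <- function(x, ...) {
  cat("<racemol> ", x$identifier, "\n", sep = "")
  cat("  SMILES: ", x$smiles, "\n", sep = "")
  cat("  status: ", x$parse_status, "\n", sep = "")
  if (identical(x$parse_status, "ok")) {
    cat("  heavy atoms: ", sum(x$heavy),
        ", rings: ", length(x$rings), "\n", sep = "")
  }
  invisible(x)
}

# -- internal: build the connection table from Open Babel SDF output ---------

.mol_from_sdf_text <- function(sdf_text) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(sdf_text, tf)
  sdfset <- ChemmineR::read.SDFset(tf)
  sdf <- sdfset[[1]]

  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  symbol <- sub("_[0-9]+$", "", rownames(ab))

  charge <- integer(n)
  # modern M CHG lines override the (deprecated) atom-block charge column
  chg_lines <- grep("^M  CHG", strsplit(sdf_text, "\n", fixed = TRUE)[[1]],
                    value = TRUE)
  for (ln in chg_lines) {
    flds <- as.integer(strsplit(trimws(substring(ln, 7)), "[[:space:]]+")[[1]])
    k <- flds[1]
    for (j in seq_len(k)) {
      charge[flds[2 * j]] <- flds[2 * j + 1]
    }
  }

  heavy <- symbol != "H"
  adj <- vector("list", n)
  bond_order <- vector("list", n)
  if (!is.null(bb) && nrow(bb) > 0) {
    for (r in seq_len(nrow(bb))) {
      a1 <- bb[r, 1]; a2 <- bb[r, 2]; o <- bb[r, 3]
      adj[[a1]] <- c(adj[[a1]], a2); bond_order[[a1]] <- c(bond_order[[a1]], o)
      adj[[a2]] <- c(adj[[a2]], a1); bond_order[[a2]] <- c(bond_order[[a2]], o)
    }
  }
  hcount <- vapply(seq_len(n), function(i) {
    sum(symbol[adj[[i]]] == "H")
  }, integer(1))

  mol <- list(
    n_atoms = n, symbol = symbol, charge = charge, heavy = heavy,
    adj = adj, bond_order = bond_order, hcount = hcount
  )
  mol <- .perceive_rings(mol, sdf)
  mol <- .perceive_aromaticity(mol)
  mol
}

.perceive_rings <- function(mol, sdf) {
  rings <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf, upper = 12, type = "all",
                                      arom = FALSE, inner = FALSE)),
    error = function(e) list()
  )
  ring_idx <- lapply(rings, function(r) {
    as.integer(sub("^.*_", "", r))
  })
  ring_idx <- ring_idx[vapply(ring_idx, length, integer(1)) <= 8L]
  mol$rings <- unname(ring_idx)
  mol$ring_sizes_of <- lapply(seq_len(mol$n_atoms), function(i) {
    sizes <- vapply(mol$rings, function(r) {
      if (i %in% r) length(r) else NA_integer_
    }, integer(1))
    sizes[!is.na(sizes)]
  })
  mol
}

.bond_order_between <- function(mol, i, j) {
  k <- match(j, mol$adj[[i]])
  if (is.na(k)) NA_integer_ else as.integer(mol$bond_order[[i]][k])
}

# pi-electron contribution of one ring atom given a kekulized connection
# table; `anion_at` treats that atom as a carbanion (2 electrons, p-orbital).
# Returns the electron count, or NA when the atom cannot contribute a
# p-orbital (which blocks aromaticity of the ring).
.pi_contribution <- function(mol, i, ring, anion_at = NA_integer_) {
  if (!is.na(anion_at) && i == anion_at) return(2L)
  nb <- mol$adj[[i]]
  ord <- mol$bond_order[[i]]
  multiple <- ord >= 2L
  if (any(multiple)) {
    in_ring_multiple <- any(multiple & nb %in% ring)
    if (in_ring_multiple) return(1L)
    partners <- nb[multiple]
    # exocyclic C=O / C=S: carbonyl-type, empty aligned p-orbital.
    # Exocyclic C=C / C=N (e.g. a fused aromatic ring under either
    # kekulization) keeps one electron in the shared pi system, which also
    # makes the count independent of where the fusion double bond landed.
    if (all(mol$symbol[partners] %in% c("O", "S"))) return(0L)
    return(1L)
  }
  sym <- mol$symbol[i]
  chg <- mol$charge[i]
  if (sym == "C") {
    if (chg == -1L) return(2L)
    if (chg == 1L) return(0L)
    return(NA_integer_)  # saturated neutral carbon: sp3, blocks the ring
  }
  if (sym %in% c("N", "P")) {
    heavy_deg <- sum(mol$symbol[nb] != "H")
    if (chg == 1L && (heavy_deg + mol$hcount[i]) >= 4L) return(NA_integer_)
    return(2L)
  }
  if (sym %in% c("O", "S", "Se")) return(2L)
  NA_integer_
}

.ring_is_aromatic <- function(mol, ring, anion_at = NA_integer_) {
  if (length(ring) < 5L || length(ring) > 6L) return(FALSE)
  total <- 0L
  for (i in ring) {
    e <- .pi_contribution(mol, i, ring, anion_at)
    if (is.na(e)) return(FALSE)
    total <- total + e
  }
  total %% 4L == 2L
}

.perceive_aromaticity <- function(mol) {
  arom_ring <- vapply(mol$rings, function(r) .ring_is_aromatic(mol, r),
                      logical(1))
  mol$ring_aromatic <- arom_ring
  aromatic_atom <- rep(FALSE, mol$n_atoms)
  for (k in seq_along(mol$rings)) {
    if (arom_ring[k]) aromatic_atom[mol$rings[[k]]] <- TRUE
  }
  mol$aromatic_atom <- aromatic_atom
  # a bond is aromatic when both ends sit in one common aromatic ring
  arom_bond <- new.env(parent = emptyenv())
  for (k in seq_along(mol$rings)) {
    if (!arom_ring[k]) next
    r <- mol$rings[[k]]
    m <- length(r)
    for (p in seq_len(m)) {
      i <- r[p]; j <- r[if (p == m) 1L else p + 1L]
      assign(paste(min(i, j), max(i, j)), TRUE, envir = arom_bond)
    }
  }
  mol$.aromatic_bonds <- arom_bond
  mol
}

.bond_is_aromatic <- function(mol, i, j) {
  isTRUE(get0(paste(min(i, j), max(i, j)), envir = mol$.aromatic_bonds,
              ifnotfound = FALSE))
}

.heavy_neighbors <- function(mol, i) {
  nb <- mol$adj[[i]]
  sort(nb[mol$symbol[nb] != "H"])
}

.check_parsed <- function(mol) {
  if (!inherits(mol, "racemol")) stop("expected a 'racemol' object")
  if (!identical(mol$parse_status, "ok")) {
    stop("molecule '", mol$identifier, "' failed to parse (invalid SMILES: ",
         mol$smiles, ")")
  }
  invisible(mol)
}
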