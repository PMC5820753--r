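# Anchored substructure matching on the racemol connection table.
#
# Substituent-classification rules are written in a documented subset of the
# SMARTS language and matched with the first pattern atom pinned to a given
# molecule atom (the substituent atom as seen from the stereogenic center).
# Supported syntax:
#   atoms    C N O S P B F I Cl Br  (aliphatic), c n o s p (aromatic), *
#   brackets [..;..] with primitives joined by ';' or '&' (logical AND),
#            each optionally negated with '!':
#            #<n>  element by atomic number (any aromaticity)
#            El / el  element symbol, aliphatic / aromatic
#            A / a    any aliphatic / any aromatic atom
#            H<n>     total hydrogen count (H alone means H1)
#            X<n>     total connectivity (heavy neighbors + hydrogens)
#            R / R0   in / not in a ring;  r<n>  in a ring of size n
#            + - +<n> -<n>  formal charge
#   bonds    default (single or aromatic), - = # : ~
#   branches ( ... ), ring closures with digits 1-9
# This subset covers local substituent environments; it has no stereo, no
# recursive patterns and no 'OR' lists. Rules needing an exclusion use a
# separate veto pattern (see `classify_substituent`).

.ELEMENT_NUMBERS <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15,
                      S = 16, Cl = 17, Br = 35, I = 53, Se = 34)

compile_pattern <- function(smarts) {
  stopifnot(is.character(smarts), length(smarts) == 1L, nzchar(smarts))
  s <- smarts
  pos <- 1L
  nmax <- nchar(s)
  atoms <- list()          # per-atom constraint list
  bonds <- list()          # list(from, to, type)
  prev <- 0L               # pattern index of the previous atom
  stack <- integer(0)      # branch points
  pending_bond <- "default"
  ring_open <- list()      # digit -> list(atom, bond)

  peek <- function(k = 0L) {
    if (pos + k > nmax) "" else substr(s, pos + k, pos + k)
  }

  add_atom <- function(constraints) {
    atoms[[length(atoms) + 1L]] <<- constraints
    idx <- length(atoms)
    if (prev > 0L) {
      bonds[[length(bonds) + 1L]] <<- list(from = prev, to = idx,
                                           type = pending_bond)
    }
    pending_bond <<- "default"
    prev <<- idx
    idx
  }

  parse_bracket <- function() {
    close_at <- regexpr("]", substr(s, pos, nmax), fixed = TRUE)
    if (close_at < 0) stop("unclosed '[' in pattern: ", smarts)
    body <- substr(s, pos + 1L, pos + close_at - 2L)
    pos <<- pos + close_at
    chunks <- strsplit(body, "[;&]")[[1]]
    cons <- list()
    for (chunk in chunks) {
      for (tok in .tokenize_primitives(chunk, smarts)) {
        cons[[length(cons) + 1L]] <- .parse_primitive(tok$text, smarts,
                                                      tok$neg)
      }
    }
    cons
  }

  while (pos <= nmax) {
    ch <- peek()
    if (ch == "[") {
      add_atom(parse_bracket())
    } else if (ch %in% c("-", "=", "#", ":", "~")) {
      # '#' is a bond only when not part of [#n]; outside brackets it is a bond
      pending_bond <- switch(ch, "-" = "single", "=" = "double",
                             "#" = "triple", ":" = "aromatic", "~" = "any")
      pos <- pos + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); pos <- pos + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in pattern: ", smarts)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      pos <- pos + 1L
    } else if (grepl("[0-9]", ch)) {
      key <- ch
      if (!is.null(ring_open[[key]])) {
        bonds[[length(bonds) + 1L]] <- list(from = ring_open[[key]]$atom,
                                            to = prev,
                                            type = ring_open[[key]]$bond)
        ring_open[[key]] <- NULL
      } else {
        ring_open[[key]] <- list(atom = prev, bond = pending_bond)
      }
      pending_bond <- "default"
      pos <- pos + 1L
    } else if (ch == "*") {
      add_atom(list(list(kind = "any", neg = FALSE))); pos <- pos + 1L
    } else {
      two <- paste0(ch, peek(1L))
      if (two %in% c("Cl", "Br")) {
        add_atom(list(.parse_primitive(two, smarts, FALSE))); pos <- pos + 2L
      } else if (grepl("[A-Za-z]", ch)) {
        add_atom(list(.parse_primitive(ch, smarts, FALSE))); pos <- pos + 1L
      } else {
        stop("unsupported character '", ch, "' in pattern: ", smarts)
      }
    }
  }
  if (length(ring_open)) stop("unmatched ring closure in pattern: ", smarts)
  if (!length(atoms)) stop("pattern has no atoms: ", smarts)
  structure(list(atoms = atoms, bonds = bonds, smarts = smarts),
            class = "racemizr_pattern")
}

# Split a bracket chunk into juxtaposed primitives (implicit AND), e.g.
# "CX3H1" -> C, X3, H1. Inside brackets a leading 'H' token is always read
# as a hydrogen-count primitive, never as the element hydrogen.
.tokenize_primitives <- function(chunk, smarts) {
  pats <- c("#[0-9]+", "Cl", "Br", "Se", "H[0-9]*", "X[0-9]+", "R0", "R",
            "r[0-9]+", "\\+[0-9]*", "-[0-9]*", "\\*",
            "[BCNOFPSI]", "[cnops]", "[Aa]")
  out <- list()
  rest <- chunk
  while (nzchar(rest)) {
    neg <- FALSE
    while (startsWith(rest, "!")) { neg <- !neg; rest <- substring(rest, 2) }
    if (!nzchar(rest)) stop("dangling '!' in pattern: ", smarts)
    hit <- NULL
    for (p in pats) {
      m <- regmatches(rest, regexpr(paste0("^(", p, ")"), rest))
      if (length(m) && nzchar(m)) { hit <- m; break }
    }
    if (is.null(hit)) {
      stop("unsupported primitive near '", rest, "' in pattern: ", smarts)
    }
    out[[length(out) + 1L]] <- list(text = hit, neg = neg)
    rest <- substring(rest, nchar(hit) + 1L)
  }
  out
}

.parse_primitive <- function(p, smarts, neg) {
  if (grepl("^#[0-9]+$", p)) {
    return(list(kind = "number", value = as.integer(substring(p, 2)),
                neg = neg))
  }
  if (p == "A") return(list(kind = "aliphatic", neg = neg))
  if (p == "a") return(list(kind = "aromatic", neg = neg))
  if (p == "*") return(list(kind = "any", neg = neg))
  if (grepl("^H[0-9]*$", p)) {
    n <- if (nchar(p) == 1L) 1L else as.integer(substring(p, 2))
    return(list(kind = "hcount", value = n, neg = neg))
  }
  if (grepl("^X[0-9]+$", p)) {
    return(list(kind = "connectivity", value = as.integer(substring(p, 2)),
                neg = neg))
  }
  if (p == "R") return(list(kind = "in_ring", neg = neg))
  if (p == "R0") return(list(kind = "in_ring", neg = !neg))
  if (grepl("^r[0-9]+$", p)) {
    return(list(kind = "ring_size", value = as.integer(substring(p, 2)),
                neg = neg))
  }
  if (grepl("^\\+[0-9]*$", p)) {
    n <- if (nchar(p) == 1L) 1L else as.integer(substring(p, 2))
    return(list(kind = "charge", value = n, neg = neg))
  }
  if (grepl("^-[0-9]*$", p)) {
    n <- if (nchar(p) == 1L) 1L else as.integer(substring(p, 2))
    return(list(kind = "charge", value = -n, neg = neg))
  }
  if (p %in% names(.ELEMENT_NUMBERS)) {
    return(list(kind = "element", symbol = p, aromatic = FALSE, neg = neg))
  }
  low <- c(c = "C", n = "N", o = "O", s = "S", p = "P")
  if (p %in% names(low)) {
    return(list(kind = "element", symbol = low[[p]], aromatic = TRUE,
                neg = neg))
  }
  stop("unsupported primitive '", p, "' in pattern: ", smarts)
}

.atom_matches <- function(mol, i, constraints) {
  for (con in constraints) {
    ok <- switch(con$kind,
      any = TRUE,
      number = .ELEMENT_NUMBERS[[mol$symbol[i]]] == con$value,
      element = mol$symbol[i] == con$symbol &&
        mol$aromatic_atom[i] == con$aromatic,
      aromatic = mol$aromatic_atom[i],
      aliphatic = !mol$aromatic_atom[i],
      hcount = mol$hcount[i] == con$value,
      connectivity = (length(.heavy_neighbors(mol, i)) + mol$hcount[i]) ==
        con$value,
      in_ring = length(mol$ring_sizes_of[[i]]) > 0L,
      ring_size = con$value %in% mol$ring_sizes_of[[i]],
      charge = mol$charge[i] == con$value,
      stop("unknown constraint kind: ", con$kind)
    )
    if (isTRUE(con$neg)) ok <- !ok
    if (!ok) return(FALSE)
  }
  TRUE
}

.bond_matches <- function(mol, i, j, type) {
  o <- .bond_order_between(mol, i, j)
  if (is.na(o)) return(FALSE)
  arom <- .bond_is_aromatic(mol, i, j)
  switch(type,
    any = TRUE,
    default = arom || (o == 1L && !arom),
    single = o == 1L && !arom,
    double = o == 2L && !arom,
    triple = o == 3L,
    aromatic = arom,
    stop("unknown bond type: ", type)
  )
}

# Match `pattern` with pattern atom 1 mapped onto molecule atom `anchor`.
# Pattern atoms map injectively onto heavy atoms; returns TRUE/FALSE.
match_anchored <- function(mol, pattern, anchor) {
  if (is.character(pattern)) pattern <- compile_pattern(pattern)
  stopifnot(inherits(pattern, "racemizr_pattern"))
  np <- length(pattern$atoms)
  if (!.atom_matches(mol, anchor, pattern$atoms[[1]])) return(FALSE)
  if (np == 1L) return(TRUE)

  # bonds grouped by the later-placed pattern atom
  attach_bonds <- vector("list", np)
  cross_bonds <- vector("list", np)
  for (b in pattern$bonds) {
    hi <- max(b$from, b$to); lo <- min(b$from, b$to)
    if (is.null(attach_bonds[[hi]])) {
      attach_bonds[[hi]] <- list(other = lo, type = b$type)
    } else {
      cross_bonds[[hi]] <- c(cross_bonds[[hi]],
                             list(list(other = lo, type = b$type)))
    }
  }

  assignment <- rep(NA_integer_, np)
  assignment[1] <- anchor

  try_place <- function(k) {
    if (k > np) return(TRUE)
    ab <- attach_bonds[[k]]
    if (is.null(ab)) stop("disconnected pattern: ", pattern$smarts)
    base <- assignment[ab$other]
    for (cand in mol$adj[[base]]) {
      if (mol$symbol[cand] == "H") next
      if (cand %in% assignment) next
      if (!.bond_matches(mol, base, cand, ab$type)) next
      if (!.atom_matches(mol, cand, pattern$atoms[[k]])) next
      extra_ok <- TRUE
      for (cb in cross_bonds[[k]]) {
        if (!.bond_matches(mol, assignment[cb$other], cand, cb$type)) {
          extra_ok <- FALSE; break
        }
      }
      if (!extra_ok) next
      assignment[k] <<- cand
      if (try_place(k + 1L)) return(TRUE)
      assignment[k] <<- NA_integer_
    }
    FALSE
  }
  try_place(2L)
}
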