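# Substituent classification: a rule table applied in fixed order, each rule
# an anchored pattern (see R/pattern.R) evaluated at the substituent atom as
# seen from the stereogenic center. The first matching rule wins; an
# unmatched substituent is labelled "other" with matched_rule_id "fallback".

#' Controlled vocabulary of substituent type labels
#' @return character vector of the recognised `type_label` values.
#' @export
substituent_vocabulary <- function() {
  c("alkyl", "phenyl", "ester", "reversed_secondary_amide",
    "acidic_secondary_amide", "primary_amide", "five_membered_aromatic",
    "ketone", "carboxylic_acid", "thioether", "imide",
    "dialkyl_tertiary_amine", "primary_amine",
    "reversed_secondary_thioamide", "aminothiooxo_imide", "other")
}

# Stereogenic center types: multisets of three substituent labels.
CENTER_TYPES <- list(
  A = c("phenyl", "reversed_secondary_amide", "ester"),
  B = c("phenyl", "reversed_secondary_amide", "primary_amide"),
  C = c("five_membered_aromatic", "reversed_secondary_amide", "ester"),
  D = c("alkyl", "reversed_secondary_amide", "acidic_secondary_amide"),
  E = c("phenyl", "reversed_secondary_amide", "acidic_secondary_amide"),
  F = c("alkyl", "aminothiooxo_imide", "acidic_secondary_amide"),
  G = c("alkyl", "reversed_secondary_thioamide", "acidic_secondary_amide"),
  H = c("ketone", "dialkyl_tertiary_amine", "alkyl"),
  I = c("ketone", "primary_amine", "alkyl"),
  J = c("carboxylic_acid", "five_membered_aromatic", "alkyl"),
  K = c("thioether", "alkyl", "acidic_secondary_amide"),
  L = c("imide", "alkyl", "acidic_secondary_amide"),
  M = c("phenyl", "phenyl", "five_membered_aromatic"),
  N = c("ester", "dialkyl_tertiary_amine", "phenyl")
)

#' Table of stereogenic center types
#'
#' The fourteen recognised combinations of three substituent labels, keyed by
#' letter code. Matching ignores substituent order.
#'
#' @return a data.frame with columns `center_type_code` and `substituents`
#'   (pipe-separated labels).
#' @export
center_type_table <- function() {
  data.frame(
    center_type_code = names(CENTER_TYPES),
    substituents = vapply(CENTER_TYPES, paste, character(1), collapse = "|"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Built-in substituent classification rules
#'
#' Loads the shipped rule file (`inst/extdata/substituent_rules.json`), a
#' JSON array applied in file order of
#' `{rule_id, smarts, type_label, delocalizing}` entries (plus an optional
#' `veto_smarts` that suppresses a match). The shipped order puts more
#' specific patterns first: the acyl rules (acidic secondary amide, primary
#' amide, carboxylic acid, ester) before ketone, the imide-type nitrogens
#' before the plain amide nitrogens, aromatic attachments before alkyl.
#'
#' @return a `substituent_rules` object (list of compiled rules).
#' @export
default_rules <- function() {
  path <- system.file("extdata", "substituent_rules.json",
                      package = "racemizr", mustWork = TRUE)
  read_rule_file(path)
}

#' Read a substituent-rule pattern file
#'
#' @param path JSON file holding an ordered array of objects with fields
#'   `rule_id`, `smarts`, `type_label`, `delocalizing` and optionally
#'   `veto_smarts`. Rules are applied in file order; user files can extend
#'   the classification to further substituent types.
#' @return a `substituent_rules` object.
#' @export
read_rule_file <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!length(raw)) stop("rule file is empty: ", path)
  rules <- lapply(raw, function(r) {
    for (f in c("rule_id", "smarts", "type_label", "delocalizing")) {
      if (is.null(r[[f]])) stop("rule missing field '", f, "' in ", path)
    }
    list(
      rule_id = as.character(r$rule_id),
      smarts = as.character(r$smarts),
      type_label = as.character(r$type_label),
      delocalizing = isTRUE(r$delocalizing),
      pattern = compile_pattern(as.character(r$smarts)),
      veto = if (!is.null(r$veto_smarts)) {
        compile_pattern(as.character(r$veto_smarts))
      }
    )
  })
  structure(rules, class = "substituent_rules")
}

#' @export
print.substituent_rules <- function(x, ...) {
  cat("<substituent_rules> ", length(x), " rules, applied in order:\n",
      sep = "")
  for (r in x) {
    cat(sprintf("  %-30s %-28s %s\n", r$rule_id, r$type_label, r$smarts))
  }
  invisible(x)
}

#' Classify one substituent of a stereogenic center
#'
#' Applies the rule table in order with each rule's pattern anchored at
#' `neighbor` (the substituent atom as seen from `center`). Ring bonds make
#' both ring neighbors of the center separate substituents. A substituent
#' matching no rule is labelled `other` with `matched_rule_id = "fallback"`.
#'
#' @param mol a parsed `racemol`.
#' @param center atom index of the stereogenic center.
#' @param neighbor atom index of a heavy atom bonded to `center`.
#' @param rules a `substituent_rules` object; defaults to the shipped set.
#' @return a list of class `substituent_assignment` with fields
#'   `neighbor_atom_index`, `type_label`, `matched_rule_id`, `delocalizing`.
#' @examples
#' mol <- parse_smiles("CC(=O)NC(c1ccccc1)C(=O)OC")
#' ctr <- find_stereocenters(mol)
#' classify_substituent(mol, ctr, neighbor = mol$adj[[ctr]][1])
#' @export
classify_substituent <- function(mol, center, neighbor,
                                 rules = default_rules()) {
  .check_parsed(mol)
  if (!(neighbor %in% mol$adj[[center]])) {
    stop("atom ", neighbor, " is not bonded to center ", center,
         " in molecule '", mol$identifier, "'")
  }
  for (r in rules) {
    if (match_anchored(mol, r$pattern, neighbor)) {
      if (!is.null(r$veto) && match_anchored(mol, r$veto, neighbor)) next
      return(structure(
        list(neighbor_atom_index = neighbor, type_label = r$type_label,
             matched_rule_id = r$rule_id, delocalizing = r$delocalizing),
        class = "substituent_assignment"
      ))
    }
  }
  structure(
    list(neighbor_atom_index = neighbor, type_label = "other",
         matched_rule_id = "fallback", delocalizing = FALSE),
    class = "substituent_assignment"
  )
}

#' Assign the stereogenic-center type code from three substituent labels
#'
#' Compares the multiset of the three labels (order ignored) against the
#' fourteen recognised center types and returns the letter code, or
#' `"unclassified"` when no row matches.
#'
#' @param labels character vector of exactly three `type_label` values.
#' @return a single character: `"A"` to `"N"` or `"unclassified"`.
#' @examples
#' assign_center_type(c("ester", "phenyl", "reversed_secondary_amide"))  # "A"
#' @export
assign_center_type <- function(labels) {
  if (!is.character(labels) || length(labels) != 3L) {
    stop("exactly three substituent labels are required, got ",
         length(labels))
  }
  key <- paste(sort(labels), collapse = "|")
  for (code in names(CENTER_TYPES)) {
    if (identical(paste(sort(CENTER_TYPES[[code]]), collapse = "|"), key)) {
      return(code)
    }
  }
  "unclassified"
}

#' Full per-center structural report for a molecule
#'
#' Runs stereocenter perception, substituent classification, center typing
#' and the aromatic-anion assessment for every candidate center.
#'
#' @param mol a parsed `racemol`.
#' @inheritParams classify_substituent
#' @inheritParams assess_aromatic_anion
#' @return a list of `stereocenter_report` objects, each with fields
#'   `atom_index`, `h_count`, `substituents` (three
#'   `substituent_assignment`s, ascending neighbor index),
#'   `center_type_code` and `aromatic_anion`.
#' @export
analyze_molecule <- function(mol, rules = default_rules(),
                             overrides = default_aromatic_overrides()) {
  .check_parsed(mol)
  centers <- find_stereocenters(mol)
  lapply(centers, function(ctr) {
    subs <- lapply(.heavy_neighbors(mol, ctr), function(nb) {
      classify_substituent(mol, ctr, nb, rules)
    })
    labels <- vapply(subs, `[[`, character(1), "type_label")
    code <- assign_center_type(labels)
    structure(
      list(atom_index = ctr, h_count = 1L, substituents = subs,
           center_type_code = code,
           aromatic_anion = assess_aromatic_anion(mol, ctr, code, overrides)),
      class = "stereocenter_report"
    )
  })
}

#' @export
print.stereocenter_report <- function(x, ...) {
  labels <- vapply(x$substituents, `[[`, character(1), "type_label")
  cat("<stereocenter_report> atom ", x$atom_index,
      " [type ", x$center_type_code,
      if (x$aromatic_anion) ", aromatic anion" else "", "]\n", sep = "")
  cat("  substituents: ", paste(labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Flatten stereocenter reports to a data frame
#'
#' @param mol a parsed `racemol`.
#' @param reports output of [analyze_molecule()]; recomputed when missing.
#' @param ... passed on to [analyze_molecule()].
#' @return a data.frame with columns `identifier`, `atom_index`,
#'   `type_labels` (pipe-separated), `center_type_code`, `aromatic_anion`.
#' @export
center_report_table <- function(mol, reports = NULL, ...) {
  if (is.null(reports)) reports <- analyze_molecule(mol, ...)
  if (!length(reports)) {
    return(data.frame(identifier = character(0), atom_index = integer(0),
                      type_labels = character(0),
                      center_type_code = character(0),
                      aromatic_anion = logical(0), stringsAsFactors = FALSE))
  }
  data.frame(
    identifier = mol$identifier,
    atom_index = vapply(reports, `[[`, integer(1), "atom_index"),
    type_labels = vapply(reports, function(r) {
      paste(vapply(r$substituents, `[[`, character(1), "type_label"),
            collapse = "|")
    }, character(1)),
    center_type_code = vapply(reports, `[[`, character(1),
                              "center_type_code"),
    aromatic_anion = vapply(reports, `[[`, logical(1), "aromatic_anion"),
    stringsAsFactors = FALSE
  )
}
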