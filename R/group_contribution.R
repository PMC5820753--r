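# Group-contribution scoring: Sigma-DDG = sum of per-substituent
# carbanion-stabilization energies DDG(R,H,H) in kcal/mol, with a
# cross-conjugation correction down-weighting every charge-delocalizing
# group after the most stabilizing one.

#' Cross-conjugation correction policy
#'
#' When two or three substituents stabilize the carbanion through charge
#' delocalization, the second (and third) delocalizing group stabilizes less
#' than it would alone: the most stabilizing delocalizing group counts in
#' full and every other delocalizing group's contribution is multiplied by
#' `factor`. Non-delocalizing groups always count in full.
#'
#' @param factor scale in `[0, 1]` applied to delocalizing groups after the
#'   strongest; default 0.5.
#' @param mode `"scale_all_but_strongest"` (default) or `"none"` (no
#'   correction ever).
#' @return a `xconj_policy` object.
#' @export
xconj_policy <- function(factor = 0.5,
                         mode = c("scale_all_but_strongest", "none")) {
  mode <- match.arg(mode)
  if (!is.numeric(factor) || length(factor) != 1L || is.na(factor) ||
      factor < 0 || factor > 1) {
    stop("'factor' must be a single number in [0, 1]")
  }
  structure(list(factor = factor, mode = mode), class = "xconj_policy")
}

#' Read a group-contribution table
#'
#' Accepts CSV (header `type_label,ddg_kcal_mol,delocalizing,provenance`) or
#' a JSON array of objects with the same fields.
#'
#' @param path path to a CSV or JSON file.
#' @return a `group_table` data.frame.
#' @export
read_group_table <- function(path) {
  if (!file.exists(path)) stop("group table not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path)
    df <- as.data.frame(raw, stringsAsFactors = FALSE)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  as_group_table(df)
}

#' Validate a data frame as a group-contribution table
#'
#' @param df data.frame with columns `type_label`, `ddg_kcal_mol`,
#'   `delocalizing` and optionally `provenance`.
#' @return a `group_table` object.
#' @export
as_group_table <- function(df) {
  need <- c("type_label", "ddg_kcal_mol", "delocalizing")
  if (!all(need %in% names(df))) {
    stop("group table must have columns: ", paste(need, collapse = ", "))
  }
  df$type_label <- as.character(df$type_label)
  df$ddg_kcal_mol <- as.numeric(df$ddg_kcal_mol)
  df$delocalizing <- as.logical(df$delocalizing)
  if (is.null(df$provenance)) df$provenance <- "user"
  if (anyDuplicated(df$type_label)) {
    stop("duplicated type_label in group table")
  }
  if (any(!is.finite(df$ddg_kcal_mol))) {
    stop("non-finite ddg_kcal_mol in group table")
  }
  class(df) <- c("group_table", "data.frame")
  df
}

#' Write a group-contribution table
#'
#' @param table a `group_table`.
#' @param path output path; `.json` writes JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_group_table <- function(table, path) {
  df <- as.data.frame(table)[, c("type_label", "ddg_kcal_mol",
                                 "delocalizing", "provenance")]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                         auto_unbox = FALSE)
  } else {
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Shipped (provisional) group-contribution table
#'
#' One DDG(R,H,H) entry per built-in substituent type. The shipped numbers
#' are provisional placeholders (`provenance = "provisional"`): they have
#' plausible signs and ordering but are not the published quantum-chemical
#' values, which users should supply through [read_group_table()] for
#' production screening.
#'
#' @return a `group_table`.
#' @export
default_group_table <- function() {
  path <- system.file("extdata", "group_contributions.csv",
                      package = "racemizr", mustWork = TRUE)
  read_group_table(path)
}

#' Sum per-substituent stabilization energies into Sigma-DDG
#'
#' With at most one delocalizing group the result is the plain sum of the
#' three DDG(R,H,H) values. With two or more delocalizing groups and
#' `policy$mode != "none"`, the most stabilizing (most negative DDG)
#' delocalizing group counts in full and every other delocalizing group is
#' scaled by `policy$factor`; ties between equally stabilizing delocalizing
#' groups are broken deterministically (lexicographically smallest
#' `type_label`, then first position).
#'
#' @param labels character vector of exactly three substituent type labels.
#' @param table a `group_table` supplying DDG values and delocalizing flags.
#' @param policy a [xconj_policy()].
#' @param strict when `TRUE` (default) a label absent from the table is an
#'   error; when `FALSE` it contributes 0 kcal/mol with a warning.
#' @param delocalizing optional logical vector of length 3 overriding the
#'   table's delocalizing flags (used when flags come from the
#'   classification rule file).
#' @return a `sigma_ddg` object with fields `value_kcal_mol`, `corrected`
#'   and a `contributions` data.frame
#'   (`type_label`, `raw_ddg`, `applied_ddg`).
#' @examples
#' tab <- as_group_table(data.frame(
#'   type_label = c("a", "b", "c"),
#'   ddg_kcal_mol = c(-20, -15, -5),
#'   delocalizing = c(TRUE, TRUE, FALSE)))
#' sum_ddg(c("a", "b", "c"), tab)$value_kcal_mol  # -20 + 0.5*(-15) - 5
#' @export
sum_ddg <- function(labels, table, policy = xconj_policy(), strict = TRUE,
                    delocalizing = NULL) {
  if (!is.character(labels) || length(labels) != 3L) {
    stop("exactly three substituent labels are required, got ",
         length(labels))
  }
  stopifnot(inherits(policy, "xconj_policy"))
  table <- as_group_table(as.data.frame(table))
  idx <- match(labels, table$type_label)
  raw <- numeric(3)
  deloc <- logical(3)
  for (k in 1:3) {
    if (is.na(idx[k])) {
      if (strict) {
        stop("no group-contribution entry for label '", labels[k], "'")
      }
      warning("label '", labels[k],
              "' missing from group table; contributing 0 kcal/mol")
      raw[k] <- 0
      deloc[k] <- FALSE
    } else {
      raw[k] <- table$ddg_kcal_mol[idx[k]]
      deloc[k] <- table$delocalizing[idx[k]]
    }
  }
  if (!is.null(delocalizing)) {
    stopifnot(is.logical(delocalizing), length(delocalizing) == 3L)
    deloc <- delocalizing
  }

  applied <- raw
  corrected <- FALSE
  if (policy$mode != "none" && sum(deloc) >= 2L) {
    corrected <- TRUE
    dn <- which(deloc)
    ord <- dn[order(raw[dn], labels[dn], dn)]  # most negative first
    scale_these <- ord[-1]
    applied[scale_these] <- raw[scale_these] * policy$factor
  }
  structure(
    list(
      value_kcal_mol = sum(applied),
      corrected = corrected,
      contributions = data.frame(type_label = labels, raw_ddg = raw,
                                 applied_ddg = applied,
                                 delocalizing = deloc,
                                 stringsAsFactors = FALSE)
    ),
    class = "sigma_ddg"
  )
}

#' @export
print.sigma_ddg <- function(x, ...) {
  cat("<sigma_ddg> ", format(x$value_kcal_mol), " kcal/mol",
      if (x$corrected) " (cross-conjugation corrected)", "\n", sep = "")
  print(x$contributions, row.names = FALSE)
  invisible(x)
}

#' Sigma-DDG for every candidate stereocenter of a molecule
#'
#' Combines structure analysis with the group-contribution sum; each
#' substituent's delocalizing flag is taken from the classification rule
#' that matched it (the pattern file), its DDG value from `table`.
#' Classification or lookup failures at one center are reported as a
#' warning and skipped; other centers are still returned.
#'
#' @param mol a parsed `racemol`.
#' @param table a `group_table`.
#' @param policy a [xconj_policy()].
#' @param rules a `substituent_rules` object.
#' @param strict passed to [sum_ddg()].
#' @param overrides passed to [analyze_molecule()].
#' @return a list of `list(report = stereocenter_report, sigma =
#'   sigma_ddg)`, one per surviving center; empty list when the molecule has
#'   no candidate centers.
#' @export
sigma_ddg_for_molecule <- function(mol, table = default_group_table(),
                                   policy = xconj_policy(),
                                   rules = default_rules(), strict = TRUE,
                                   overrides = default_aromatic_overrides()) {
  .check_parsed(mol)
  reports <- analyze_molecule(mol, rules, overrides)
  out <- list()
  for (rep in reports) {
    labels <- vapply(rep$substituents, `[[`, character(1), "type_label")
    deloc <- vapply(rep$substituents, `[[`, logical(1), "delocalizing")
    sig <- tryCatch(
      sum_ddg(labels, table, policy, strict = strict, delocalizing = deloc),
      error = function(e) {
        warning("center ", rep$atom_index, " of '", mol$identifier,
                "' skipped: ", conditionMessage(e))
        NULL
      }
    )
    if (!is.null(sig)) {
      out[[length(out) + 1L]] <- list(report = rep, sigma = sig)
    }
  }
  out
}
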