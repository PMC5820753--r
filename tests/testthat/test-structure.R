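# Stereocenter perception and substituent classification.

test_that("candidate stereocenters are one-H tetrahedral carbons with four distinct branches", {
  expect_identical(find_stereocenters(parse_smiles("C")), integer(0))

  thal <- parse_smiles(CENTER_TYPE_REPRESENTATIVES$L, "thalidomide")
  expect_length(find_stereocenters(thal), 1L)

  hyd <- parse_smiles(CENTER_TYPE_REPRESENTATIVES$D, "5-methylhydantoin")
  expect_length(find_stereocenters(hyd), 1L)

  # two identical ethyl branches: not a stereocenter
  expect_identical(find_stereocenters(parse_smiles("CCC(O)CC")), integer(0))
  # symmetric diol: prochiral center rejected on branch invariants
  expect_identical(find_stereocenters(parse_smiles("OCC(O)CO")), integer(0))
  # centers are reported without drawn stereochemistry and sorted ascending
  two <- parse_smiles("CC(N)C(=O)NC(C)C(=O)O")
  ctrs <- find_stereocenters(two)
  expect_identical(ctrs, sort(ctrs))
  expect_length(ctrs, 2L)
})

test_that("parse failures are structured, not crashes", {
  bad <- parse_smiles("C1CC", "broken")
  expect_identical(bad$parse_status, "failed")
  expect_error(find_stereocenters(bad), "broken")
  mols <- read_smiles_file(
    withr::local_tempfile(lines = c("CCO\tok_mol", "C1CC\tbad_mol")))
  expect_identical(vapply(mols, `[[`, character(1), "parse_status"),
                   c("ok", "failed"))
})

test_that("substituent classification matches the named examples", {
  mol <- parse_smiles(CENTER_TYPE_REPRESENTATIVES$A)
  ctr <- find_stereocenters(mol)
  labels <- center_label_multisets(CENTER_TYPE_REPRESENTATIVES$A)[[1]]
  expect_setequal(labels,
                  c("phenyl", "reversed_secondary_amide", "ester"))

  labels_d <- center_label_multisets(CENTER_TYPE_REPRESENTATIVES$D)[[1]]
  expect_setequal(labels_d, c("alkyl", "reversed_secondary_amide",
                              "acidic_secondary_amide"))

  # CF3 has no shipped rule: falls back to "other"
  cf3 <- parse_smiles("FC(F)(F)C(N)C(=O)OC")
  ctr3 <- find_stereocenters(cf3)
  expect_length(ctr3, 1L)
  cf3_carbon <- which(vapply(seq_len(cf3$n_atoms), function(i) {
    cf3$symbol[i] == "C" && sum(cf3$symbol[cf3$adj[[i]]] == "F") == 3L
  }, logical(1)))
  asg <- classify_substituent(cf3, ctr3, cf3_carbon)
  expect_identical(asg$type_label, "other")
  expect_identical(asg$matched_rule_id, "fallback")

  # contract violation: neighbor not bonded to center
  expect_error(classify_substituent(mol, ctr, ctr), "not bonded")
})

test_that("assign_center_type matches Table rows irrespective of order", {
  expect_identical(
    assign_center_type(c("phenyl", "reversed_secondary_amide", "ester")),
    "A")
  expect_identical(
    assign_center_type(c("ester", "phenyl", "reversed_secondary_amide")),
    "A")
  expect_identical(
    assign_center_type(c("alkyl", "reversed_secondary_thioamide",
                         "acidic_secondary_amide")),
    "G")
  expect_identical(assign_center_type(c("alkyl", "alkyl", "alkyl")),
                   "unclassified")
  expect_error(assign_center_type(c("alkyl", "alkyl")), "three")
})

test_that("every center-type representative round-trips to its letter code", {
  for (code in names(CENTER_TYPE_REPRESENTATIVES)) {
    mol <- parse_smiles(CENTER_TYPE_REPRESENTATIVES[[code]], code)
    reports <- analyze_molecule(mol)
    codes <- vapply(reports, `[[`, character(1), "center_type_code")
    expect_true(code %in% codes,
                label = sprintf("type %s found in %s (got: %s)", code,
                                mol$smiles, paste(codes, collapse = ",")))
  }
})

test_that("center reports always carry three substituents and one hydrogen", {
  for (smi in unlist(CENTER_TYPE_REPRESENTATIVES, use.names = FALSE)) {
    for (rep in analyze_molecule(parse_smiles(smi))) {
      expect_length(rep$substituents, 3L)
      expect_identical(rep$h_count, 1L)
      expect_true(all(vapply(rep$substituents, `[[`, character(1),
                             "type_label") %in% substituent_vocabulary()))
    }
  }
})

test_that("classification is stable under atom renumbering", {
  for (variants in SMILES_VARIANTS) {
    ref <- center_label_multisets(variants[[1]])
    for (alt in variants[-1]) {
      expect_identical(center_label_multisets(alt), ref,
                       label = paste("variant", alt))
    }
  }
})

test_that("aromatic-anion assessment follows Hueckel counting with overrides", {
  # acyclic center: never aromatic
  mol <- parse_smiles(CENTER_TYPE_REPRESENTATIVES$A)
  ctr <- find_stereocenters(mol)
  expect_false(assess_aromatic_anion(mol, ctr))

  # cyclopentadiene CH2 as a harness center: 6 pi electrons on deprotonation
  cp <- parse_smiles("C1C=CC=C1")
  ch2 <- which(cp$symbol == "C" & cp$hcount == 2L)[1]
  expect_true(assess_aromatic_anion(cp, ch2))

  # cyclohexene CH2: not conjugatable all round
  ch <- parse_smiles("C1CC=CCC1")
  expect_false(assess_aromatic_anion(ch, which(ch$hcount == 2L)[1]))

  # hydantoin center: Hueckel says potentially aromatic, but the default
  # per-type override routes classified type D as non-aromatic
  hyd <- parse_smiles(CENTER_TYPE_REPRESENTATIVES$D)
  hctr <- find_stereocenters(hyd)
  expect_true(assess_aromatic_anion(hyd, hctr, center_type = NULL,
                                    overrides = NULL))
  expect_false(assess_aromatic_anion(hyd, hctr, center_type = "D"))
  rep <- analyze_molecule(hyd)[[1]]
  expect_false(rep$aromatic_anion)
  # an explicit override wins
  expect_true(assess_aromatic_anion(hyd, hctr, center_type = "D",
                                    overrides = c(D = TRUE)))
})

test_that("user rule files extend and reorder classification", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    list(rule_id = "any_carbon", smarts = "[#6]", type_label = "alkyl",
         delocalizing = FALSE)
  ), path, auto_unbox = TRUE)
  rules <- read_rule_file(path)
  mol <- parse_smiles(CENTER_TYPE_REPRESENTATIVES$A)
  ctr <- find_stereocenters(mol)
  phenyl_c <- intersect(mol$adj[[ctr]], which(mol$aromatic_atom))[1]
  expect_identical(classify_substituent(mol, ctr, phenyl_c, rules)$type_label,
                   "alkyl")
  expect_identical(
    classify_substituent(mol, ctr, phenyl_c, rules)$matched_rule_id,
    "any_carbon")
})
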