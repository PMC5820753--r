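# Shared fixtures: reference structures (one per stereogenic-center type)
# and pre-generated alternative atom-ordering SMILES spellings used for
# permutation-stability checks. The alternative spellings are synthetic
# re-writes of the same molecules with shuffled atom numbering.

CENTER_TYPE_REPRESENTATIVES <- list(
  A = "CC(=O)NC(c1ccccc1)C(=O)OC",          # N-acetyl phenylglycine ester
  B = "CC(=O)NC(c1ccccc1)C(N)=O",
  C = "CC(=O)NC(c1ccco1)C(=O)OC",
  D = "CC1NC(=O)NC1=O",                     # 5-methylhydantoin
  E = "c1ccccc1C2NC(=O)NC2=O",              # 5-phenylhydantoin
  F = "CC1N(C)C(=S)NC1=O",                  # 1-methyl-2-thiohydantoin
  G = "CC1NC(=S)NC1=O",                     # 2-thiohydantoin
  H = "CC(=O)C(C)N(C)C",
  I = "CC(=O)C(C)N",
  J = "CC(c1ccco1)C(=O)O",
  K = "CSC(C)C(=O)NC",
  L = "O=C1CCC(N2C(=O)c3ccccc3C2=O)C(=O)N1",  # thalidomide
  M = "C(c1ccccc1)(c1ccc(C)cc1)c1ccco1",
  N = "COC(=O)C(c1ccccc1)N(C)C"
)

SMILES_VARIANTS <- list(
  thalidomide = c(
    "O=C1CCC(N2C(=O)c3ccccc3C2=O)C(=O)N1",
    "C1C(N2C(=O)c3ccccc3C2=O)C(=O)NC(=O)C1",
    "N1(C2CCC(=O)NC2=O)C(=O)c2ccccc2C1=O",
    "O=C1N(C2C(=O)NC(=O)CC2)C(=O)c2c1cccc2",
    "O=C1N(C2CCC(=O)NC2=O)C(=O)c2ccccc21",
    "c1cc2c(cc1)C(=O)N(C1C(=O)NC(=O)CC1)C2=O",
    "c1cccc2c1C(=O)N(C1CCC(=O)NC1=O)C2=O"
  ),
  methylhydantoin = c(
    "CC1NC(=O)NC1=O",
    "C1(C)C(=O)NC(=O)N1",
    "C1(C)NC(=O)NC1=O",
    "N1C(=O)C(C)NC1=O",
    "N1C(=O)NC(=O)C1C",
    "O=C1NC(=O)NC1C",
    "O=C1NC(C)C(=O)N1"
  ),
  acetylphenylglycine_ester = c(
    "CC(=O)NC(c1ccccc1)C(=O)OC",
    "C(C(OC)=O)(c1ccccc1)NC(=O)C",
    "c1c(C(NC(=O)C)C(=O)OC)cccc1",
    "c1ccc(C(NC(=O)C)C(=O)OC)cc1",
    "c1cccc(C(NC(=O)C)C(OC)=O)c1",
    "c1cccc(C(NC(C)=O)C(=O)OC)c1"
  ),
  thiohydantoin = c(
    "CC1NC(=S)NC1=O",
    "C1(=O)NC(=S)NC1C",
    "C1(=S)NC(=O)C(C)N1",
    "C1(=S)NC(C)C(=O)N1",
    "N1C(=S)NC(=O)C1C",
    "O=C1C(C)NC(=S)N1",
    "S=C1NC(=O)C(C)N1"
  ),
  aminoketone = c(
    "CC(=O)C(C)N(C)C",
    "C(C(N(C)C)C)(=O)C",
    "CC(C(N(C)C)C)=O",
    "CN(C(C)C(=O)C)C",
    "CN(C)C(C(=O)C)C",
    "CN(C)C(C(C)=O)C"
  ),
  amino_ester = c(
    "COC(=O)C(c1ccccc1)N(C)C",
    "C(c1ccccc1)(C(OC)=O)N(C)C",
    "CN(C(C(=O)OC)c1ccccc1)C",
    "CN(C(c1ccccc1)C(OC)=O)C",
    "N(C)(C)C(C(=O)OC)c1ccccc1",
    "O(C(=O)C(N(C)C)c1ccccc1)C"
  )
)

# sorted multiset of substituent labels for every center of a molecule
center_label_multisets <- function(smiles, rules = default_rules()) {
  mol <- parse_smiles(smiles)
  reports <- analyze_molecule(mol, rules)
  sets <- lapply(reports, function(r) {
    sort(vapply(r$substituents, `[[`, character(1), "type_label"))
  })
  sets[order(vapply(sets, paste, character(1), collapse = "|"))]
}

make_group_table <- function(...) {
  entries <- list(...)
  as_group_table(data.frame(
    type_label = names(entries),
    ddg_kcal_mol = vapply(entries, function(e) e$ddg, numeric(1)),
    delocalizing = vapply(entries, function(e) e$deloc, logical(1)),
    stringsAsFactors = FALSE
  ))
}
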