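# Monomer -> repeat unit -> trimer construction

test_that("condensation forms the expected repeat unit and trimer", {
  eg <- monomer_spec("Ethylene glycol", "OCCO", "diol")
  dms <- monomer_spec("Dimethyl succinate", "COC(=O)CCC(=O)OC", "dimethyl_ester")
  ru <- condense(eg, dms)
  expect_equal(mol_n_atoms(ru$graph), 10)  # hand atom count of -OCC-O-C(=O)CCC(=O)-
  expect_equal(ru$eliminated, "methanol")
  expect_equal(lengths(regmatches(repeat_unit_smiles(ru),
                                  gregexpr("*", repeat_unit_smiles(ru), fixed = TRUE))), 2)

  tri <- build_nmer(ru, 3)
  expect_equal(tri$heavy_atoms, 3 * 10 + 1)
  g <- mol_parse(tri$smiles)
  expect_equal(mol_count_cooh(g), 1)
  expect_gte(mol_count_free_oh(g), 1)

  mono <- build_nmer(ru, 1)
  g1 <- mol_parse(mono$smiles)
  expect_equal(mol_count_cooh(g1), 1)
  expect_equal(mol_count_free_oh(g1), 1)
})

test_that("n-mer heavy-atom count is affine in n", {
  eg <- monomer_spec("Ethylene glycol", "OCCO", "diol")
  sa <- monomer_spec("Succinic acid", "OC(=O)CCC(=O)O", "diacid")
  ru <- condense(eg, sa)
  counts <- vapply(1:4, function(n) build_nmer(ru, n)$heavy_atoms, integer(1))
  expect_equal(length(unique(diff(counts))), 1)
})

test_that("branched polyols react through primary hydroxyls, pendant OH kept", {
  gly <- monomer_spec("Glycerol", "OCC(O)CO", "polyol")
  dms <- monomer_spec("Dimethyl succinate", "COC(=O)CCC(=O)OC", "dimethyl_ester")
  ru <- condense(gly, dms)
  tri <- build_nmer(ru, 3)
  g <- mol_parse(tri$smiles)
  # 3 pendant secondary OH + 1 terminal OH, exactly one COOH
  expect_equal(mol_count_free_oh(g), 4)
  expect_equal(mol_count_cooh(g), 1)
})

test_that("role mismatches are contract/structure errors", {
  eg <- monomer_spec("Ethylene glycol", "OCCO", "diol")
  pd <- monomer_spec("1,3-Propanediol", "OCCCO", "diol")
  expect_error(condense(eg, pd), class = "polybiodeg_contract_error")
  dma <- monomer_spec("Dimethyl adipate", "COC(=O)CCCCC(=O)OC", "dimethyl_ester")
  expect_error(ring_open(dma), class = "polybiodeg_structure_error")
  expect_error(monomer_spec("bogus", "not-a-smiles", "diol"),
               class = "polybiodeg_structure_error")
})

test_that("ring opening conserves heavy atoms and gives the two-unit lactide repeat", {
  vl <- monomer_spec("delta-Valerolactone", "O=C1CCCCO1", "lactone")
  rv <- ring_open(vl)
  expect_equal(mol_n_atoms(rv$graph), 7)
  cl <- monomer_spec("epsilon-Caprolactone", "O=C1CCCCCO1", "lactone")
  expect_equal(mol_n_atoms(ring_open(cl)$graph), 8)
  lac <- monomer_spec("Lactide", "CC1OC(=O)C(C)OC1=O", "lactone")
  rl <- ring_open(lac)
  expect_equal(mol_n_atoms(rl$graph), 10)  # two lactic units
  tri <- build_nmer(rl, 3)
  g <- mol_parse(tri$smiles)
  expect_equal(mol_count_cooh(g), 1)
  expect_gte(mol_count_free_oh(g), 1)
})

test_that("canonical trimer SMILES is invariant to monomer atom ordering", {
  ru1 <- condense(monomer_spec("eg", "OCCO", "diol"),
                  monomer_spec("dms", "COC(=O)CCC(=O)OC", "dimethyl_ester"))
  ru2 <- condense(monomer_spec("eg", "C(O)CO", "diol"),
                  monomer_spec("dms", "O(C)C(=O)CCC(=O)OC", "dimethyl_ester"))
  expect_identical(build_nmer(ru1, 3)$smiles, build_nmer(ru2, 3)$smiles)
})

test_that("the full study dataset builds with correct bookkeeping", {
  tbl <- fixture_table1()
  tr <- fixture_trimers()
  expect_equal(nrow(tr), 48)
  expect_true(all(nzchar(tr$trimer_smiles)))
  # duplicate monomer pair gives identical canonical SMILES
  expect_identical(tr$trimer_smiles[34], tr$trimer_smiles[36])
  # heavy-atom bookkeeping for every condensation polymer:
  # 3 * (m1 + m2 - 2 * e_bond) + 1, e_bond = 2 heavy atoms for methanol,
  # 1 for water
  reg <- load_monomer_registry()
  for (i in which(!is.na(tbl$monomer2) & tbl$id < 45)) {
    h1 <- mol_n_atoms(mol_parse(reg$smiles[reg$name == tbl$monomer1[i]]))
    h2 <- mol_n_atoms(mol_parse(reg$smiles[reg$name == tbl$monomer2[i]]))
    e <- if (reg$role[reg$name == tbl$monomer2[i]] == "dimethyl_ester") 4 else 2
    expect_equal(tr$heavy_atoms[i], 3 * (h1 + h2 - e) + 1)
  }
  # every trimer has one acid and at least one alcohol end group
  for (i in seq_len(48)) {
    g <- mol_parse(tr$trimer_smiles[i])
    expect_equal(mol_count_cooh(g), 1)
    expect_gte(mol_count_free_oh(g), 1)
  }
})

test_that("dataset building is deterministic and handles edge cases", {
  tr2 <- build_dataset_trimers(fixture_table1())
  expect_identical(tr2$trimer_smiles, fixture_trimers()$trimer_smiles)
  empty <- build_dataset_trimers(fixture_table1()[0, ])
  expect_equal(nrow(empty), 0)
  bad <- fixture_table1()[1, ]
  bad$monomer1 <- "Unobtainium diol"
  expect_error(build_dataset_trimers(bad), class = "polybiodeg_lookup_error")
})
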