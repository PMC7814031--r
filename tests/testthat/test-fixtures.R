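test_that("series generation hits hand-written target structures", {
  ser <- generate_series(pfas_series_spec("PFCAs", 4:8))
  expect_equal(nrow(ser), 5)
  # the n = 7 member is perfluorooctanoic acid
  pfoa <- "OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F"
  expect_equal(
    canonicalize_smiles(ser$smiles[ser$n == 7]),
    canonicalize_smiles(pfoa)
  )
  ftoh <- generate_series(pfas_series_spec("FTOHs", c(6L, 8L)))
  expect_equal(
    canonicalize_smiles(ftoh$smiles),
    canonicalize_smiles(c(
      "OCCC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F",
      "OCCC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F"
    ))
  )
  expect_error(pfas_series_spec("PFCAs", integer(0)), "invalid_spec")
  expect_error(pfas_series_spec("nope", 4:6), "invalid_spec")
})

test_that("all generated SMILES parse and survive standardization unchanged in atoms", {
  corpus <- generate_corpus(seed = 0)
  std <- pfas_standardize(corpus[, c("id", "smiles")])
  expect_true(all(std$valid))
  before <- pfas_element_counts(canonicalize_smiles(corpus$smiles))
  after <- pfas_element_counts(std$canonical_smiles)
  expect_equal(after$C, before$C)
  expect_equal(after$F, before$F)
  expect_equal(after$H, before$H)
})

test_that("the corpus is deterministic, sized, and covers the whole catalog", {
  c1 <- generate_corpus(seed = 0)
  c2 <- generate_corpus(seed = 0)
  expect_identical(c1, c2)
  c3 <- generate_corpus(seed = 1)
  expect_false(identical(c1$id, c3$id))
  expect_setequal(c1$id, c3$id)
  expect_gte(nrow(c1), 200)
  # every category
  expect_setequal(unique(c1$category), c(
    "aliphatic_pfas", "silicon_pfas", "side_chain_fluorinated_aromatic",
    "pfas_derivative", "not_pfas"
  ))
  # every subclass of the rule catalog, plus every derivative subclass
  expect_true(all(pfas_ruleset()$subclass %in% c1$subclass))
  expect_true(all(c(
    "halogen_substituted", "fluorinated_unsaturated_carbon",
    "fluorinated_aromatic_carbon"
  ) %in% c1$subclass))
  # at least two carbocyclic PFAS and some decoys
  expect_gte(sum(c1$ring_opened), 2)
  expect_gte(sum(c1$category == "not_pfas"), 5)
})

test_that("the curated named-compound table is internally consistent", {
  named <- pfas_named_compounds()
  expect_equal(nrow(named), 23)
  expect_false(any(duplicated(named$abbrev)))
  std <- pfas_standardize(named$smiles)
  expect_true(all(std$valid))
  # chain lengths follow the nomenclature (e.g. the octanoic acid is n = 7,
  # the octanesulfonic acid n = 8)
  expect_equal(named$n[named$abbrev == "PFOA"], 7L)
  expect_equal(named$n[named$abbrev == "PFOS"], 8L)
  expect_equal(named$n[named$abbrev == "FTOH (8:2)"], 8L)
})

test_that("corpus files can be written for external tools", {
  tmp <- withr::local_tempdir()
  corpus <- generate_corpus(seed = 0)[1:10, ]
  write_corpus(corpus, file.path(tmp, "c.smi"), file.path(tmp, "truth.csv"))
  back <- read_smi(file.path(tmp, "c.smi"))
  expect_equal(back$id, corpus$id)
  expect_equal(back$smiles, corpus$smiles)
  truth <- utils::read.csv(file.path(tmp, "truth.csv"))
  expect_equal(truth$subclass, corpus$subclass)
  expect_equal(truth$n, corpus$n)
})
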