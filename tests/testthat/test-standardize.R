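test_that("well-formed SMILES parse and malformed ones are rejected, never fatally", {
  res <- pfas_standardize(c(
    "CCO", "C(F)(F", "", "not a smiles!!",
    "OS(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F"
  ))
  expect_equal(res$valid, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(res$reject_reason[!res$valid], rep("invalid_smiles", 3))
  # the accepted sulfonate is C8F17SO3H
  counts <- pfas_element_counts(res$canonical_smiles[5])
  expect_equal(counts$C, 8)
  expect_equal(counts$F, 17)
  expect_equal(counts$S, 1)
})

test_that("the three printed PFOS variants standardize to one identical structure", {
  res <- pfas_standardize(unname(pfos_variants()))
  expect_true(all(res$valid))
  expect_length(unique(res$canonical_smiles), 1)
  dedup <- pfas_deduplicate(res)
  expect_equal(nrow(dedup), 1)
  expect_equal(dedup$n_sources, 3)
  expect_setequal(dedup$source_ids[[1]], res$id)
})

test_that("salt stripping, isotope removal and neutralization set their flags", {
  res <- pfas_standardize(c(
    salt = "[O-]C(=O)C(F)(F)F.[Na+]",
    plain = "CCO",
    isotope = "[13CH3]C([2H])O",
    quat = "C[N+](C)(C)C"
  ))
  expect_equal(res$canonical_smiles[1], canonicalize_smiles("OC(=O)C(F)(F)F"))
  expect_true(res$salt_stripped[1])
  expect_true(res$neutralized[1])
  expect_false(res$uncorrectable_charge[1])
  expect_false(any(unlist(res[2, c("salt_stripped", "isotopes_removed", "neutralized")])))
  expect_true(res$isotopes_removed[3])
  expect_equal(res$canonical_smiles[3], canonicalize_smiles("CCO"))
  # permanent charge is kept and flagged, not dropped
  expect_true(res$uncorrectable_charge[4])
  expect_match(res$canonical_smiles[4], "N\\+", fixed = FALSE)
})

test_that("standardization is idempotent and dedup-after-standardize is a fixpoint", {
  corpus <- generate_corpus(seed = 3)
  smis <- corpus$smiles[seq(1, nrow(corpus), by = 7)]
  first <- pfas_standardize(smis)
  expect_true(all(first$valid))
  second <- pfas_standardize(first$canonical_smiles)
  expect_equal(second$canonical_smiles, first$canonical_smiles)
  d1 <- pfas_deduplicate(first)
  redo <- pfas_standardize(d1$canonical_smiles)
  d2 <- pfas_deduplicate(redo)
  expect_equal(d2$canonical_smiles, d1$canonical_smiles)
})

test_that("standardization preserves the carbon count of the largest fragment", {
  cases <- c(
    "[O-]C(=O)C(F)(F)C(F)(F)F.[Na+]",
    "OC(=O)C(F)(F)C(F)(F)C(F)(F)F",
    "[13CH3]CO",
    "c1ccccc1CC(F)(F)F"
  )
  largest_c <- c(3, 4, 2, 8)
  res <- pfas_standardize(cases)
  got <- pfas_element_counts(res$canonical_smiles)$C
  expect_equal(got, largest_c)
})

test_that("deduplicate keeps first-occurrence order and merges ids", {
  res <- pfas_standardize(c(a = "CCO", b = "OC", c = "OCC", d = "CO"))
  d <- pfas_deduplicate(res)
  expect_equal(nrow(d), 2)
  expect_equal(d$canonical_smiles[1], canonicalize_smiles("CCO"))
  expect_equal(d$source_ids[[1]], c("S1", "S3"))
  expect_equal(d$source_ids[[2]], c("S2", "S4"))
})

test_that("smi/csv io round-trips records and reports rejects", {
  tmp <- withr::local_tempdir()
  smi <- file.path(tmp, "in.smi")
  writeLines(c("CCO eth", "C(F)(F broken", "OC(=O)C(F)(F)F tfa"), smi)
  dat <- read_smi(smi)
  expect_equal(dat$id, c("eth", "broken", "tfa"))
  std <- pfas_standardize(dat)
  out <- file.path(tmp, "std.csv")
  rej <- file.path(tmp, "rej.csv")
  write_standardized(std, out, rejects_path = rej)
  expect_equal(nrow(utils::read.csv(out)), 2)
  rejects <- utils::read.csv(rej)
  expect_equal(rejects$id, "broken")
  expect_equal(rejects$reason, "invalid_smiles")
})
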