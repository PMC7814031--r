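test_that("simple counts match hand counts and the formula oracle", {
  counts <- pfas_element_counts(c(
    "CCO",
    canonicalize_smiles(pfos_variants()[["rdkit"]]),
    "Fc1c(F)c(F)c(F)c(F)c1F"
  ))
  expect_equal(unlist(counts[1, c("C", "H", "O", "F", "aromatic_atom_count")]),
    c(C = 2, H = 6, O = 1, F = 0, aromatic_atom_count = 0))
  expect_equal(unlist(counts[2, c("C", "F", "S", "O", "H")]),
    c(C = 8, F = 17, S = 1, O = 3, H = 1))
  expect_equal(unlist(counts[3, c("C", "F", "aromatic_atom_count")]),
    c(C = 6, F = 6, aromatic_atom_count = 6))

  # independent oracle: the toolkit's printed molecular formula
  for (smi in c("CCO", "OC(=O)C(F)(F)F", "c1ccccc1CC(F)(F)F", "NS(=O)(=O)C(F)(F)F")) {
    oracle <- formula_counts(canonicalize_smiles(smi))
    got <- pfas_element_counts(smi)
    for (el in intersect(names(oracle), c("C", "H", "O", "N", "P", "S", "F"))) {
      expect_equal(got[[el]], unname(oracle[el]), info = paste(smi, el))
    }
  }
})

test_that("descriptor vectors are deterministic and chemically sensible", {
  pfoa <- canonicalize_smiles(paste0("OC(=O)", strrep("C(F)(F)", 6), "C(F)(F)F"))
  pfna <- canonicalize_smiles(paste0("OC(=O)", strrep("C(F)(F)", 7), "C(F)(F)F"))
  d1 <- pfas_descriptors(c(pfoa, pfna))
  d2 <- pfas_descriptors(c(pfoa, pfna))
  expect_identical(d1, d2)
  # one CF2 apart: fluorine-sensitive features differ
  expect_equal(d1$n_F[2] - d1$n_F[1], 2)
  expect_gt(d1$perfluoro_chain_n[2], d1$perfluoro_chain_n[1])
  # fingerprint bits are binary and highly similar for homologues
  bits <- as.matrix(d1[, grep("^fp_", names(d1))])
  expect_true(all(bits %in% c(0, 1)))
  tanimoto <- sum(bits[1, ] & bits[2, ]) / sum(bits[1, ] | bits[2, ])
  expect_gt(tanimoto, 0.8)
})

test_that("methane has all fluorine-related features zero", {
  d <- pfas_descriptors("C")
  expect_equal(d$n_F, 0)
  expect_equal(d$n_CF3, 0)
  expect_equal(d$n_chain_CF2, 0)
  expect_equal(d$perfluoro_chain_n, 0)
  expect_equal(d$frac_fluorinated_carbon, 0)
})

test_that("fingerprint bits are invariant to the input SMILES variant", {
  std <- pfas_standardize(unname(pfos_variants()))
  d <- pfas_descriptors(std[, "canonical_smiles"])
  bits <- as.matrix(d[, grep("^fp_", names(d))])
  expect_equal(bits[2, ], bits[1, ])
  expect_equal(bits[3, ], bits[1, ])
})

test_that("pruning drops over-threshold columns and median-imputes the rest", {
  desc <- tibble::tibble(
    canonical_smiles = paste0("s", 1:10),
    all_bad = NA_real_,
    all_good = 1:10,
    one_bad = c(NA, 2:10)
  )
  pruned_strict <- prune_descriptors(desc, invalid_fraction_threshold = 0.05)
  expect_setequal(pruned_strict$features, "all_good")
  pruned_loose <- prune_descriptors(desc, invalid_fraction_threshold = 0.2)
  expect_setequal(pruned_loose$features, c("all_good", "one_bad"))
  expect_equal(pruned_loose$data$one_bad[1], stats::median(2:10))
  expect_equal(pruned_loose$raw_n_features, 3)
  expect_equal(pruned_loose$retained_n_features, 2)
  expect_error(
    prune_descriptors(desc[, c("canonical_smiles", "all_bad")], 0.1),
    "empty_matrix"
  )
})

test_that("row order does not affect pruning decisions", {
  smis <- canonicalize_smiles(c(
    "CCO", "C", "OC(=O)C(F)(F)F", "c1ccccc1", "FC(F)(F)C(F)(F)F"
  ))
  d <- pfas_descriptors(smis)
  p1 <- prune_descriptors(d, 0.1)
  perm <- c(3, 1, 5, 2, 4)
  p2 <- prune_descriptors(d[perm, ], 0.1)
  expect_equal(p2$features, p1$features)
  expect_equal(p2$data, p1$data[perm, ])
})
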