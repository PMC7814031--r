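test_that("the definition filter recognizes CF3/CF2 and rejects near-misses", {
  expect_false(contains_perfluorinated_carbon("CCO"))
  expect_true(contains_perfluorinated_carbon(pfos_variants()[["comptox"]]))
  # Cl on otherwise perfluorinated carbons: neither CF3 nor chain-CF2
  expect_false(contains_perfluorinated_carbon("ClC(F)(F)C(F)(F)Cl"))
  # CHF2/CHF carbons carry hydrogen, so they are not fully fluorinated
  expect_false(contains_perfluorinated_carbon("FCF"))
  expect_true(contains_perfluorinated_carbon("FC(F)(F)CO"))
})

test_that("derivative subclassing tests its three patterns in order", {
  expect_equal(classify_derivative("ClC(F)(F)C(F)(F)Cl"), "halogen_substituted")
  expect_equal(classify_derivative("O=C(F)F"), "fluorinated_unsaturated_carbon")
  expect_equal(classify_derivative("FC(F)=C(F)F"), "fluorinated_unsaturated_carbon")
  expect_equal(classify_derivative("Fc1ccccc1"), "fluorinated_aromatic_carbon")
  expect_equal(classify_derivative("CCO"), "not_pfas")
  # not applicable once the definition filter passes
  expect_true(is.na(classify_derivative("FC(F)(F)CO")))
})

test_that("silicon and side-chain aromatic filters fire in cascade order", {
  expect_true(contains_silicon("C[Si](C)(C)CC(F)(F)F"))
  expect_false(contains_silicon(pfos_variants()[["rdkit"]]))
  expect_true(is_side_chain_fluorinated_aromatic("c1ccccc1CC(F)(F)F"))
  # aromatic F only: fails the definition filter, so module 3 never applies
  expect_false(is_side_chain_fluorinated_aromatic("Fc1ccccc1"))
  cls <- pfas_classify(c("C[Si](C)(C)CC(F)(F)F", "c1ccccc1CC(F)(F)F", "Fc1ccccc1"))
  expect_equal(
    cls$category,
    c("silicon_pfas", "side_chain_fluorinated_aromatic", "pfas_derivative")
  )
})

test_that("core module classifies the canonical examples with chain metadata", {
  cls <- pfas_classify(c(
    pfos = pfos_variants()[["rdkit"]],
    ftoh82 = "OCCC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F",
    pfhx = "FC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F",
    fosa = paste0("NS(=O)(=O)", strrep("C(F)(F)", 7), "C(F)(F)F")
  ))
  expect_equal(cls$category, rep("aliphatic_pfas", 4))
  expect_equal(cls$class, c(
    "PFAAs", "fluorotelomer_based_PFAA_precursors",
    "non_PFAA_perfluoroalkyls", "FASA_based_PFAA_precursors"
  ))
  expect_equal(cls$subclass, c("PFSAs", "FTOHs", "perfluoroalkanes", "FASAs"))
  expect_equal(cls$n, c(8L, 8L, 6L, 8L))
  expect_equal(cls$m, c(0L, 0L, 0L, 0L))
})

test_that("every named compound classifies to its name-implied class/subclass", {
  named <- pfas_named_compounds()
  cls <- pfas_classify(named$smiles)
  expect_equal(cls$category, named$category)
  expect_equal(cls$class, named$class)
  expect_equal(cls$subclass, named$subclass)
  expect_equal(cls$n, named$n)
  expect_equal(cls$m, named$m)
})

test_that("classification is total and single-valued on arbitrary molecules", {
  odd <- c(
    "C", "O", "[Na+]", "C1CC1", "c1ccncc1", "CC(F)(F)CC(F)(F)C",
    "FC(F)(F)OC(F)(F)F", "CC(=O)NC1CCCCC1", "N#CC(F)(F)F",
    "OC(=O)c1ccccc1C(F)(F)F"
  )
  cls <- pfas_classify(odd)
  expect_equal(nrow(cls), length(odd))
  expect_true(all(!is.na(cls$category)))
  expect_true(all(cls$category %in% c(
    "not_pfas", "pfas_derivative", "silicon_pfas",
    "side_chain_fluorinated_aromatic", "aliphatic_pfas"
  )))
  # aliphatic PFAS always carry a positive chain length
  expect_true(all(cls$n[cls$category == "aliphatic_pfas"] >= 1))
  # derivative subclasses only appear on the derivative category
  expect_true(all(is.na(cls$subclass) | cls$category != "not_pfas"))
})

test_that("classification is invariant to the input SMILES representation", {
  variants <- list(
    pfos = unname(pfos_variants()),
    ftoh = c(
      "OCCC(F)(F)C(F)(F)C(F)(F)C(F)(F)F",
      "C(CO)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F",
      "FC(F)(C(F)(F)F)C(F)(F)C(F)(F)CCO"
    ),
    tfa = c("OC(=O)C(F)(F)F", "C(=O)(O)C(F)(F)F", "FC(F)(F)C(O)=O")
  )
  for (v in variants) {
    std <- pfas_standardize(v)
    cls <- pfas_classify(std[, "canonical_smiles"])
    expect_equal(nrow(unique(cls[, c("category", "class", "subclass", "n", "m")])), 1)
  }
})

test_that("homologous series members all receive the generator's label and n", {
  for (sub in c("PFCAs", "PFSAs", "FTOHs", "FASAs", "FTIs", "perfluoroalkanes")) {
    ser <- generate_series(pfas_series_spec(sub, 4:12))
    std <- pfas_standardize(ser[, c("id", "smiles")])
    cls <- pfas_classify(std[, c("id", "canonical_smiles")])
    expect_equal(cls$subclass, ser$subclass, info = sub)
    expect_equal(cls$class, ser$class, info = sub)
    expect_equal(cls$n, ser$n, info = sub)
  }
})

test_that("the shipped rule table is ordered, complete and drives precedence", {
  rt <- pfas_ruleset()
  expect_equal(rt$order, sort(rt$order))
  expect_false(any(duplicated(rt$subclass)))
  # FTSA carries a sulfonic head but must not match PFSAs (ethyl spacer)
  ftsa <- "OS(=O)(=O)CCC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F"
  expect_equal(pfas_classify(ftsa)$subclass, "FTSAs")
  # restricting the table changes the outcome deterministically
  no_telomer <- rt[rt$class != "fluorotelomer_based_PFAA_precursors", ]
  cls <- pfas_classify(pfas_standardize(ftsa)[, "canonical_smiles"], ruleset = no_telomer)
  expect_equal(cls$class, "unclassified_aliphatic")
})
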