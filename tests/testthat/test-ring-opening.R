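test_that("the cyclohexanesulfonic worked example opens to perfluorohexanesulfonic acid", {
  o <- open_rings(cyclo_pfhxs_smiles())
  expect_equal(o$rings_opened, 1L)
  expect_false(o$ring_opening_failed)
  expect_equal(o$opened_smiles, canonicalize_smiles(pfhxs_smiles()))
  cls <- pfas_classify(cyclo_pfhxs_smiles())
  expect_equal(cls$class, "PFAAs")
  expect_equal(cls$subclass, "PFSAs")
  expect_equal(cls$n, 6L)
  expect_true(cls$ring_opened)
})

test_that("acyclic structures pass through unchanged", {
  pfoa <- canonicalize_smiles("OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F")
  o <- open_rings(pfoa)
  expect_equal(o$rings_opened, 0L)
  expect_equal(o$opened_smiles, pfoa)
})

test_that("ring opening preserves carbons and adds exactly 2 F per ring", {
  cyclics <- c(
    "FC1(F)C(F)(F)C(F)(F)C(F)(F)C1(F)F",                 # perfluorocyclopentane
    "FC1(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C1(F)F",          # perfluorocyclohexane
    cyclo_pfhxs_smiles(),
    "OC(=O)C1(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C1(F)F"      # cyclic carboxylic
  )
  before <- pfas_element_counts(canonicalize_smiles(cyclics))
  o <- open_rings(cyclics)
  after <- pfas_element_counts(o$opened_smiles)
  expect_equal(after$C, before$C)
  expect_equal(after$F, before$F + 2L * o$rings_opened)
  # outputs are acyclic
  reopened <- open_rings(o$opened_smiles)
  expect_equal(reopened$rings_opened, rep(0L, length(cyclics)))
})

test_that("perfluorocyclopentane opens to perfluoropentane", {
  o <- open_rings("FC1(F)C(F)(F)C(F)(F)C(F)(F)C1(F)F")
  expect_equal(
    o$opened_smiles,
    canonicalize_smiles("FC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F")
  )
  counts <- pfas_element_counts(o$opened_smiles)
  expect_equal(counts$F, 12L)
})

test_that("heteroatom rings are not opened and are flagged", {
  # perfluorinated cyclic ether ring
  ether_ring <- "FC1(F)OC(F)(F)C(F)(F)C(F)(F)C1(F)F"
  o <- open_rings(ether_ring)
  expect_equal(o$rings_opened, 0L)
  expect_true(o$ring_opening_failed)
  expect_equal(o$opened_smiles, canonicalize_smiles(ether_ring))
})

test_that("fused carbocycles are opened iteratively until acyclic", {
  # perfluorodecalin (two fused rings)
  decalin <- "FC1(F)C(F)(F)C(F)(F)C2(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C12F"
  o <- open_rings(decalin)
  expect_equal(o$rings_opened, 2L)
  before <- pfas_element_counts(canonicalize_smiles(decalin))
  after <- pfas_element_counts(o$opened_smiles)
  expect_equal(after$C, before$C)
  expect_equal(after$F, before$F + 4L)
  expect_equal(open_rings(o$opened_smiles)$rings_opened, 0L)
})
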