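# Shared fixtures and independent oracles.

# NA-tolerant elementwise equality
eq_na <- function(a, b) {
  (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
}

# the three printed canonical-SMILES variants of perfluorooctanesulfonic acid
pfos_variants <- function() {
  c(
    pubchem = "C(C(C(C(C(F)(F)S(=O)(=O)O)(F)F)(F)F)(F)F)(C(C(C(F)(F)F)(F)F)(F)F)(F)F",
    comptox = "OS(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F",
    rdkit = "O=S(=O)(O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F"
  )
}

# undecafluorocyclohexanesulfonic acid and its acyclic ring-opening product
cyclo_pfhxs_smiles <- function() "O=S(=O)(O)C1(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C1(F)F"
pfhxs_smiles <- function() "O=S(=O)(O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F"

# independent element-count oracle: parse the molecular formula string the
# toolkit's property engine prints (a different code path than the package's
# graph walk)
formula_counts <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  suppressWarnings(ChemmineR::cid(sdf) <- "m1")
  f <- as.character(suppressWarnings(ChemmineR::propOB(sdf))$formula[1])
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
  counts <- integer(0)
  for (t in toks) {
    el <- gsub("[0-9]", "", t)
    nn <- gsub("[^0-9]", "", t)
    counts[el] <- (if (is.na(counts[el])) 0L else counts[el]) +
      (if (nzchar(nn)) as.integer(nn) else 1L)
  }
  counts
}

# brute-force PCA oracle: eigendecomposition of the covariance of the
# standardized matrix
pca_eigen_oracle <- function(X, variance_target) {
  sds <- apply(X, 2, stats::sd)
  Z <- scale(X[, sds > 0, drop = FALSE])
  ev <- eigen(stats::cov(Z), symmetric = TRUE)$values
  ev[ev < 0] <- 0
  ratios <- ev / sum(ev)
  list(ratios = ratios, k = which(cumsum(ratios) >= variance_target - 1e-12)[1])
}

# nearest-neighbor label purity in an embedding
nn_purity <- function(Y, labels) {
  D <- as.matrix(stats::dist(Y))
  diag(D) <- Inf
  mean(labels == labels[apply(D, 1, which.min)])
}

# memoised expensive fixtures (shared across test files)
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# chain lengths used by the small reference; 6 and 10 are held out so
# placement can be tested on in-range homologues the fit never saw
small_ref_n <- function() c(4L, 5L, 7L, 8L, 9L, 11L, 12L)
held_out_n <- function() c(6L, 10L)

# a small but full reference build used by pipeline/map tests
small_reference <- function() {
  fixture("small_reference", function() {
    corpus <- dplyr::bind_rows(
      generate_series(pfas_series_spec("PFCAs", small_ref_n())),
      generate_series(pfas_series_spec("PFSAs", small_ref_n())),
      generate_series(pfas_series_spec("FTOHs", small_ref_n())),
      generate_series(pfas_series_spec("FASAs", small_ref_n(), 0:1)),
      generate_series(pfas_series_spec("FTIs", small_ref_n()))
    )
    build_reference(corpus[, c("id", "smiles")],
      perplexity = 15, steps = 300, seed = 7)
  })
}
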