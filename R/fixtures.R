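# Synthetic SMILES corpora with known ground-truth classifications.
#
# The generator writes homologous CnF2n+1 series for every subclass in the
# catalog from structural templates, so the classifier can be regression-
# tested against construction-time truth without any external compound list.
# The chain-length convention throughout is the number of fully fluorinated
# carbons (so perfluorooctanoic acid is the n = 7 carboxylic acid and
# perfluorooctanesulfonic acid the n = 8 sulfonate).

# CnF2n+1 written as explicit CF2 units with a terminal CF3
.chain_smiles <- function(n) {
  stopifnot(n >= 1)
  paste0(strrep("C(F)(F)", n - 1), "C(F)(F)F")
}

.alkyl_smiles <- function(m) strrep("C", m)

# subclass -> (template over n[, m], class); truth n equals the template's n
.series_templates <- function() {
  ch <- .chain_smiles
  alk <- .alkyl_smiles
  n_amide <- function(m, arm) {
    # sulfonamide N with optional N-alkyl and a functional arm
    if (m == 0) paste0(arm, "NS(=O)(=O)") else paste0(arm, "N(", alk(m), ")S(=O)(=O)")
  }
  list(
    PFCAs = list(class = "PFAAs", f = function(n, m) paste0("OC(=O)", ch(n))),
    PFSAs = list(class = "PFAAs", f = function(n, m) paste0("OS(=O)(=O)", ch(n))),
    PFPAs = list(class = "PFAAs", f = function(n, m) paste0("OP(=O)(O)", ch(n))),
    PFPiAs = list(class = "PFAAs", f = function(n, m) paste0("OP(=O)(", ch(n), ")", ch(n))),
    PFECAs = list(class = "PFAAs", f = function(n, m) paste0("OC(=O)C(F)(F)O", ch(n))),
    PFESAs = list(class = "PFAAs", f = function(n, m) paste0("OS(=O)(=O)C(F)(F)O", ch(n))),
    FASAs = list(
      class = "FASA_based_PFAA_precursors",
      f = function(n, m) paste0(if (m == 0) "NS(=O)(=O)" else paste0(alk(m), "NS(=O)(=O)"), ch(n))
    ),
    FASEs = list(
      class = "FASA_based_PFAA_precursors",
      f = function(n, m) paste0(n_amide(m, "OCC"), ch(n))
    ),
    FASAAs = list(
      class = "FASA_based_PFAA_precursors",
      f = function(n, m) paste0(n_amide(m, "OC(=O)C"), ch(n))
    ),
    FASACs = list(
      class = "FASA_based_PFAA_precursors",
      f = function(n, m) paste0(n_amide(m, "C=CC(=O)OCC"), ch(n))
    ),
    FASMACs = list(
      class = "FASA_based_PFAA_precursors",
      f = function(n, m) paste0(n_amide(m, "CC(=C)C(=O)OCC"), ch(n))
    ),
    FTOHs = list(class = "fluorotelomer_based_PFAA_precursors", f = function(n, m) paste0("OCC", ch(n))),
    FTACs = list(class = "fluorotelomer_based_PFAA_precursors", f = function(n, m) paste0("C=CC(=O)OCC", ch(n))),
    FTMACs = list(class = "fluorotelomer_based_PFAA_precursors", f = function(n, m) paste0("CC(=C)C(=O)OCC", ch(n))),
    FTIs = list(class = "fluorotelomer_based_PFAA_precursors", f = function(n, m) paste0("ICC", ch(n))),
    FTOs = list(class = "fluorotelomer_based_PFAA_precursors", f = function(n, m) paste0("C=C", ch(n))),
    FTSAs = list(class = "fluorotelomer_based_PFAA_precursors", f = function(n, m) paste0("OS(=O)(=O)CC", ch(n))),
    monoPAPs = list(class = "fluorotelomer_based_PFAA_precursors", f = function(n, m) paste0("OP(=O)(O)OCC", ch(n))),
    diPAPs = list(
      class = "fluorotelomer_based_PFAA_precursors",
      f = function(n, m) paste0("OP(=O)(OCC", ch(n), ")OCC", ch(n))
    ),
    FTALs = list(class = "fluorotelomer_based_PFAA_precursors", f = function(n, m) paste0("O=CC", ch(n))),
    FTCAs = list(class = "fluorotelomer_based_PFAA_precursors", f = function(n, m) paste0("OC(=O)C", ch(n))),
    FTUALs = list(class = "fluorotelomer_based_PFAA_precursors", f = function(n, m) paste0("O=CC=C(F)", ch(n))),
    FTUCAs = list(class = "fluorotelomer_based_PFAA_precursors", f = function(n, m) paste0("OC(=O)C=C(F)", ch(n))),
    PASFs = list(class = "perfluoroalkyl_PFAA_precursors", f = function(n, m) paste0("FS(=O)(=O)", ch(n))),
    PAFs = list(class = "perfluoroalkyl_PFAA_precursors", f = function(n, m) paste0("O=C(F)", ch(n))),
    PFAIs = list(class = "perfluoroalkyl_PFAA_precursors", f = function(n, m) paste0("I", ch(n))),
    perfluoroalkanes = list(class = "non_PFAA_perfluoroalkyls", f = function(n, m) paste0("F", ch(n))),
    perfluoroalkenes = list(class = "non_PFAA_perfluoroalkyls", f = function(n, m) paste0("FC(F)=C(F)", ch(n))),
    perfluoroalcohols = list(class = "non_PFAA_perfluoroalkyls", f = function(n, m) paste0("O", ch(n))),
    perfluoroketones = list(
      class = "non_PFAA_perfluoroalkyls",
      f = function(n, m) paste0("O=C(C(F)(F)F)", ch(n))
    )
  )
}

#' Specify a homologous series
#'
#' @param subclass Subclass label from the rule catalog (see
#'   [pfas_ruleset()]).
#' @param n_range Integer vector of perfluoroalkyl chain lengths.
#' @param m_range Integer vector of N-alkyl spacer lengths (FASA-based
#'   subclasses only; default 0).
#' @return A `pfas_series_spec` list.
#' @export
pfas_series_spec <- function(subclass, n_range, m_range = 0L) {
  tpl <- .series_templates()
  if (!subclass %in% names(tpl)) {
    stop("invalid_spec: unknown subclass '", subclass, "'")
  }
  if (length(n_range) == 0) stop("invalid_spec: empty n_range")
  structure(
    list(
      subclass = subclass, class = tpl[[subclass]]$class,
      n_range = as.integer(n_range), m_range = as.integer(m_range)
    ),
    class = "pfas_series_spec"
  )
}

#' Generate a homologous series with ground truth
#'
#' One record per chain length (and, for FASA-based subclasses, per N-alkyl
#' length), built from the subclass's structural template. The attached
#' ground truth is the construction-time classification, which the rule
#' cascade must reproduce.
#'
#' @param spec A `pfas_series_spec`.
#' @return A tibble: `id`, `smiles`, `category`, `class`, `subclass`, `n`,
#'   `m`, `ring_opened`.
#' @examples
#' generate_series(pfas_series_spec("PFCAs", 4:8))
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "pfas_series_spec"))
  tpl <- .series_templates()[[spec$subclass]]
  grid <- expand.grid(n = spec$n_range, m = spec$m_range)
  tibble::tibble(
    id = sprintf("%s_n%d_m%d", spec$subclass, grid$n, grid$m),
    smiles = vapply(seq_len(nrow(grid)), function(i) tpl$f(grid$n[i], grid$m[i]), character(1)),
    category = "aliphatic_pfas",
    class = spec$class,
    subclass = spec$subclass,
    n = as.integer(grid$n),
    m = as.integer(grid$m),
    ring_opened = FALSE
  )
}

# fixed non-series corpus members with ground truth
.corpus_extras <- function() {
  row <- function(id, smiles, category, class = NA_character_,
                  subclass = NA_character_, n = 0L, m = 0L, ring_opened = FALSE) {
    tibble::tibble(
      id = id, smiles = smiles, category = category, class = class,
      subclass = subclass, n = as.integer(n), m = as.integer(m),
      ring_opened = ring_opened
    )
  }
  dplyr::bind_rows(
    # silicon PFASs
    row("silicon_1", "C[Si](C)(C)CC(F)(F)F", "silicon_pfas", n = 1),
    row("silicon_2", paste0("C[Si](C)(C)CC", .chain_smiles(6)), "silicon_pfas", n = 6),
    row("silicon_3", paste0("O[Si](C)(C)CC", .chain_smiles(4)), "silicon_pfas", n = 4),
    # side-chain fluorinated aromatics
    row("arom_side_1", "c1ccccc1CC(F)(F)F", "side_chain_fluorinated_aromatic", n = 1),
    row("arom_side_2", paste0("c1ccc(CC", .chain_smiles(6), ")cc1"),
      "side_chain_fluorinated_aromatic", n = 6),
    row("arom_side_3", paste0("Oc1ccc(CC", .chain_smiles(4), ")cc1"),
      "side_chain_fluorinated_aromatic", n = 4),
    # carbocyclic PFASs (classified after ring opening)
    row("cyclo_pfhxs", "O=S(=O)(O)C1(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C1(F)F",
      "aliphatic_pfas", "PFAAs", "PFSAs", n = 6, ring_opened = TRUE),
    row("cyclo_pfhpa", "OC(=O)C1(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C1(F)F",
      "aliphatic_pfas", "PFAAs", "PFCAs", n = 6, ring_opened = TRUE),
    row("cyclo_c5", "FC1(F)C(F)(F)C(F)(F)C(F)(F)C1(F)F",
      "aliphatic_pfas", "non_PFAA_perfluoroalkyls", "perfluoroalkanes",
      n = 5, ring_opened = TRUE),
    row("cyclo_c6", "FC1(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C1(F)F",
      "aliphatic_pfas", "non_PFAA_perfluoroalkyls", "perfluoroalkanes",
      n = 6, ring_opened = TRUE),
    # PFAS derivatives
    row("deriv_hal_1", "ClC(F)(F)Cl", "pfas_derivative", subclass = "halogen_substituted"),
    row("deriv_hal_2", "ClC(F)(F)C(F)(F)Cl", "pfas_derivative", subclass = "halogen_substituted"),
    row("deriv_hal_3", "BrC(F)(F)Br", "pfas_derivative", subclass = "halogen_substituted"),
    row("deriv_unsat_1", "FC(F)=C(F)F", "pfas_derivative", subclass = "fluorinated_unsaturated_carbon"),
    row("deriv_unsat_2", "O=C(F)F", "pfas_derivative", subclass = "fluorinated_unsaturated_carbon"),
    row("deriv_unsat_3", "FC=CF", "pfas_derivative", subclass = "fluorinated_unsaturated_carbon"),
    row("deriv_arom_1", "Fc1ccccc1", "pfas_derivative", subclass = "fluorinated_aromatic_carbon"),
    row("deriv_arom_2", "Fc1ccc(F)cc1", "pfas_derivative", subclass = "fluorinated_aromatic_carbon"),
    row("deriv_arom_3", "Fc1c(F)c(F)c(F)c(F)c1F", "pfas_derivative", subclass = "fluorinated_aromatic_carbon"),
    # not-PFAS decoys
    row("decoy_ethanol", "CCO", "not_pfas"),
    row("decoy_acetic", "CC(=O)O", "not_pfas"),
    row("decoy_benzene", "c1ccccc1", "not_pfas"),
    row("decoy_octane", "CCCCCCCC", "not_pfas"),
    row("decoy_isopropanol", "CC(C)O", "not_pfas"),
    row("decoy_ethylamine", "CCN", "not_pfas"),
    row("decoy_methane", "C", "not_pfas"),
    row("decoy_mef", "CF", "not_pfas"),
    row("decoy_dfm", "FCF", "not_pfas"),
    row("decoy_2fp", "CC(F)C", "not_pfas"),
    row("decoy_glycerol", "OCC(O)CO", "not_pfas")
  )
}

#' Generate the synthetic test corpus
#'
#' A deterministic, seeded corpus of 200+ structures spanning every
#' category, class, and subclass of the catalog: homologous series (chain
#' lengths 4-10, with N-alkyl variants for the sulfonamide family), silicon
#' PFASs, side-chain fluorinated aromatics, carbocyclic PFASs, the three
#' derivative subclasses, and non-PFAS decoys — each with construction-time
#' ground truth attached. The seed controls only the row order.
#'
#' @param seed Integer seed.
#' @param n_range Chain lengths of the homologous series (default 4:10).
#' @return A tibble: `id`, `smiles`, `category`, `class`, `subclass`, `n`,
#'   `m`, `ring_opened`.
#' @export
generate_corpus <- function(seed = 0L, n_range = 4:10) {
  tpl <- .series_templates()
  m_ranges <- list(FASAs = 0:2, FASEs = 0:2, FASAAs = 1L, FASACs = 1L, FASMACs = 1L)
  series <- dplyr::bind_rows(lapply(names(tpl), function(sub) {
    m_range <- m_ranges[[sub]] %||% 0L
    generate_series(pfas_series_spec(sub, n_range, m_range))
  }))
  corpus <- dplyr::bind_rows(series, .corpus_extras())
  ord <- withr::with_seed(as.integer(seed), sample.int(nrow(corpus)))
  corpus[ord, , drop = FALSE]
}

#' Curated named-compound truth table
#'
#' Well-known PFAS from the T4-TTR binding and ToxCast activity compound
#' lists, hand-encoded from their names, with the class/subclass each name
#' implies. This is the frozen reference table used to validate the rule
#' cascade against real nomenclature.
#'
#' @return A tibble: `name`, `abbrev`, `smiles`, `category`, `class`,
#'   `subclass`, `n`, `m`.
#' @export
pfas_named_compounds <- function() {
  ch <- .chain_smiles
  pfca <- function(n) paste0("OC(=O)", ch(n))
  pfsa <- function(n) paste0("OS(=O)(=O)", ch(n))
  row <- function(name, abbrev, smiles, class, subclass, n, m = 0L) {
    tibble::tibble(
      name = name, abbrev = abbrev, smiles = smiles,
      category = "aliphatic_pfas", class = class, subclass = subclass,
      n = as.integer(n), m = as.integer(m)
    )
  }
  dplyr::bind_rows(
    row("perfluorobutanoic acid", "PFBA", pfca(3), "PFAAs", "PFCAs", 3),
    row("perfluorobutane sulfonic acid", "PFBS", pfsa(4), "PFAAs", "PFSAs", 4),
    row("perfluorohexanoic acid", "PFHxA", pfca(5), "PFAAs", "PFCAs", 5),
    row("perfluoroheptanoic acid", "PFHpA", pfca(6), "PFAAs", "PFCAs", 6),
    row("perfluorohexane sulfonic acid", "PFHxS", pfsa(6), "PFAAs", "PFSAs", 6),
    row("perfluorooctanoic acid", "PFOA", pfca(7), "PFAAs", "PFCAs", 7),
    row("perfluorononanoic acid", "PFNA", pfca(8), "PFAAs", "PFCAs", 8),
    row("perfluorooctanesulfonamide", "FOSA", paste0("NS(=O)(=O)", ch(8)),
      "FASA_based_PFAA_precursors", "FASAs", 8),
    row("perfluorooctanesulfonic acid", "PFOS", pfsa(8), "PFAAs", "PFSAs", 8),
    row("perfluorodecanoic acid", "PFDcA", pfca(9), "PFAAs", "PFCAs", 9),
    row("perfluoroundecanoic acid", "PFUnA", pfca(10), "PFAAs", "PFCAs", 10),
    row("perfluorodecane sulfonic acid", "PFDS", pfsa(10), "PFAAs", "PFSAs", 10),
    row("perfluorododecanoic acid", "PFDoA", pfca(11), "PFAAs", "PFCAs", 11),
    row("perfluorotetradecanoic acid", "PFTdA", pfca(13), "PFAAs", "PFCAs", 13),
    row("6:2 fluorotelomer alcohol", "FTOH (6:2)", paste0("OCC", ch(6)),
      "fluorotelomer_based_PFAA_precursors", "FTOHs", 6),
    row("8:2 fluorotelomer alcohol", "FTOH (8:2)", paste0("OCC", ch(8)),
      "fluorotelomer_based_PFAA_precursors", "FTOHs", 8),
    row("2H-perfluoro-2-octenoic acid", "FTUA (6:2)",
      paste0("OC(=O)C=C(F)", ch(5)),
      "fluorotelomer_based_PFAA_precursors", "FTUCAs", 5),
    row("N-methylperfluorooctanesulfonamide", "N-MeFOSA",
      paste0("CNS(=O)(=O)", ch(8)), "FASA_based_PFAA_precursors", "FASAs", 8, 1),
    row("N-ethylperfluorooctanesulfonamide", "N-EtFOSA",
      paste0("CCNS(=O)(=O)", ch(8)), "FASA_based_PFAA_precursors", "FASAs", 8, 2),
    row("N-methyl-N-(2-hydroxyethyl)perfluorooctanesulfonamide", "N-MeFOSE",
      paste0("OCCN(C)S(=O)(=O)", ch(8)), "FASA_based_PFAA_precursors", "FASEs", 8, 1),
    row("N-ethyl-N-(2-hydroxyethyl)perfluorooctanesulfonamide", "N-EtFOSE",
      paste0("OCCN(CC)S(=O)(=O)", ch(8)), "FASA_based_PFAA_precursors", "FASEs", 8, 2),
    row("6:2 fluorotelomer methacrylate", "6:2 FTMAC",
      paste0("CC(=C)C(=O)OCC", ch(6)),
      "fluorotelomer_based_PFAA_precursors", "FTMACs", 6),
    row("1H,1H,2H,2H-perfluorooctyl iodide", "6:2 FTI", paste0("ICC", ch(6)),
      "fluorotelomer_based_PFAA_precursors", "FTIs", 6)
  )
}

#' Write a corpus as SMI + ground-truth CSV
#'
#' @param corpus A tibble from [generate_corpus()] or [generate_series()].
#' @param smi_path Output `.smi` file (smiles, id).
#' @param truth_path Optional ground-truth CSV.
#' @return `corpus`, invisibly.
#' @export
write_corpus <- function(corpus, smi_path, truth_path = NULL) {
  writeLines(paste(corpus$smiles, corpus$id), smi_path)
  if (!is.null(truth_path)) {
    utils::write.csv(
      corpus[, c("id", "smiles", "category", "class", "subclass", "n", "m", "ring_opened")],
      truth_path,
      row.names = FALSE
    )
  }
  invisible(corpus)
}
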