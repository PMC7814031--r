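# Carbocycle ring opening.
#
# Cyclic aliphatic PFAS are transformed to acyclic analogues before the core
# class/subclass rules run: one ring C-C bond is deleted and a fluorine is
# added to each of the two carbons of the broken bond, so carbon count is
# preserved and the fluorine count grows by exactly two per opened ring.
# Rings containing heteroatoms (and aromatic rings) are never opened.

# Ranking of the exocyclic substituents a ring carbon carries, used to pick
# the bond to break: the carbon holding the highest-ranked substituent keeps
# it at a chain terminus. acid anchor > other heteroatom > carbon > F only.
.ring_carbon_priority <- function(mol, i, ring) {
  ex <- setdiff(mol_neighbors(mol, i), ring)
  if (length(ex) == 0) return(1L)
  p <- 1L
  for (j in ex) {
    sym <- mol$atoms$symbol[j]
    if (sym == "F") next
    pj <- if (sym %in% c("S", "P")) {
      4L
    } else if (sym == "C") {
      nbj <- mol_neighbors(mol, j)
      dbl_o <- any(vapply(nbj, function(k) {
        mol$atoms$symbol[k] == "O" && mol_bond_order(mol, j, k) == 2L
      }, logical(1)))
      if (dbl_o) 4L else 2L
    } else {
      3L
    }
    p <- max(p, pj)
  }
  p
}

# Open all carbocycles of one molecule graph. Returns
# list(mol, rings_opened, failed). `failed` is TRUE when cycles remain that
# the rule cannot open (heteroatom rings, non-single ring bonds).
open_rings_mol <- function(mol) {
  rings_opened <- 0L
  failed <- FALSE
  for (iter in 1:50) {
    if (length(mol$rings) == 0) break
    is_carbo <- vapply(seq_along(mol$rings), function(k) {
      r <- mol$rings[[k]]
      all(mol$atoms$symbol[r] == "C") && !mol$ring_aromatic[k]
    }, logical(1))
    if (!any(is_carbo)) {
      failed <- TRUE
      break
    }
    cand <- which(is_carbo)
    sizes <- lengths(mol$rings[cand])
    cand <- cand[sizes == min(sizes)]
    ring <- mol$rings[[cand[order(vapply(mol$rings[cand], min, integer(1)))[1]]]]

    prio <- vapply(ring, .ring_carbon_priority, integer(1), mol = mol, ring = ring)
    a <- ring[order(-prio, ring)][1]
    ring_nb <- intersect(mol_neighbors(mol, a), ring)
    ring_nb <- ring_nb[vapply(ring_nb, function(b) mol_bond_order(mol, a, b) == 1L, logical(1))]
    if (length(ring_nb) == 0) {
      failed <- TRUE
      break
    }
    nb_prio <- vapply(ring_nb, function(b) .ring_carbon_priority(mol, b, ring), integer(1))
    b <- ring_nb[order(nb_prio, ring_nb)][1]

    # delete the a-b bond, cap both carbons with F
    drop <- which((mol$bonds$a1 == min(a, b)) & (mol$bonds$a2 == max(a, b)))
    mol$bonds <- mol$bonds[-drop[1], , drop = FALSE]
    nf <- nrow(mol$atoms) + c(1L, 2L)
    mol$atoms <- dplyr::bind_rows(
      mol$atoms,
      tibble::tibble(
        idx = nf, symbol = "F", charge = 0L, nH = 0L, aromatic = FALSE
      )
    )
    mol$bonds <- dplyr::bind_rows(
      mol$bonds,
      tibble::tibble(a1 = c(a, b), a2 = nf, order = 1L)
    )
    rings_opened <- rings_opened + 1L

    # reparse for fresh ring perception (fused systems open iteratively)
    can <- mol_canonical(mol)
    if (is.na(can)) {
      failed <- TRUE
      break
    }
    mol2 <- mol_from_smiles(can)
    if (is.null(mol2)) {
      failed <- TRUE
      break
    }
    mol <- mol2
  }
  list(mol = mol, rings_opened = rings_opened, failed = failed)
}

#' Open carbocycles of cyclic aliphatic structures
#'
#' For each structure, every all-carbon non-aromatic ring is opened by
#' deleting one ring C--C bond and adding a fluorine atom to each of the two
#' carbons of the broken bond; the result is re-canonicalized. The bond chosen
#' is the one that leaves the highest-priority substituent (acid group, then
#' other heteroatom, then carbon, then fluorine-only) at a chain terminus.
#' Heteroatom-containing and aromatic rings are left intact and flagged.
#'
#' @param data A data frame with a `canonical_smiles` column (e.g. from
#'   [pfas_standardize()]), or a character vector of SMILES.
#' @return A tibble with `canonical_smiles` (input), `opened_smiles`
#'   (canonical form after opening), `rings_opened` (integer count) and
#'   `ring_opening_failed` (cycles remained that the rule does not cover).
#' @examples
#' open_rings("FC1(F)C(F)(F)C(F)(F)C(F)(F)C1(F)F")
#' @export
open_rings <- function(data) {
  if (is.character(data)) data <- tibble::tibble(canonical_smiles = canonicalize_smiles(data))
  stopifnot("canonical_smiles" %in% names(data))
  rows <- purrr::map(data$canonical_smiles, function(s) {
    mol <- mol_from_smiles(s)
    if (is.null(mol)) {
      return(tibble::tibble(
        canonical_smiles = s, opened_smiles = NA_character_,
        rings_opened = NA_integer_, ring_opening_failed = TRUE
      ))
    }
    res <- open_rings_mol(mol)
    tibble::tibble(
      canonical_smiles = s,
      opened_smiles = if (res$rings_opened > 0) mol_canonical(res$mol) else s,
      rings_opened = res$rings_opened,
      ring_opening_failed = res$failed
    )
  })
  dplyr::bind_rows(rows)
}
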