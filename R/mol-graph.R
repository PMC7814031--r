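# Internal molecular-graph layer.
#
# All SMILES parsing and canonicalization goes through ChemmineR/ChemmineOB
# (OpenBabel). A molecule is held as a pair of tibbles (atoms, bonds) derived
# from the V2000 blocks, which is what the standardizer and the classification
# cascade operate on. Graph edits are written back as V2000 text and
# re-canonicalized, because canonical SMILES strings are the package's single
# comparison dialect (see `canonicalize_smiles()`).

# Default valences used to derive implicit hydrogen counts from a kekulized
# V2000 connection table.
.default_valence <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

.atomic_mass <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.99, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Br = 79.904, I = 126.904
)

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the package's single canonical dialect (OpenBabel
#' canonical SMILES). Every string comparison between structures in this
#' package goes through this routine.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES; `NA` where conversion failed.
#' @export
canonicalize_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles) & vapply(smiles, smiles_syntax_ok, logical(1))
  if (any(ok)) {
    res <- vapply(smiles[ok], function(s) {
      r <- tryCatch(
        ChemmineOB::convertFormat("SMI", "CAN", source = s),
        error = function(e) ""
      )
      r <- sub("[\t\n].*$", "", r)
      if (!nzchar(r)) NA_character_ else r
    }, character(1), USE.NAMES = FALSE)
    out[ok] <- res
  }
  out
}

# Syntactic pre-validation. OpenBabel silently repairs some malformed SMILES
# (unbalanced parentheses, dangling ring bonds), so structural bookkeeping is
# checked here before any string reaches the parser.
smiles_syntax_ok <- function(smi) {
  if (is.na(smi) || !nzchar(smi)) return(FALSE)
  if (grepl("[^A-Za-z0-9@+\\-\\[\\]()=#$/\\\\%.:*]", smi)) return(FALSE)
  chars <- strsplit(smi, "")[[1]]
  # bracket atoms must not nest and must close
  depth_b <- 0L
  depth_p <- 0L
  outside <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      if (depth_b > 0L) return(FALSE)
      depth_b <- depth_b + 1L
    } else if (ch == "]") {
      depth_b <- depth_b - 1L
      if (depth_b < 0L) return(FALSE)
    } else if (depth_b == 0L) {
      if (ch == "(") depth_p <- depth_p + 1L
      if (ch == ")") {
        depth_p <- depth_p - 1L
        if (depth_p < 0L) return(FALSE)
      }
      if (ch == "%") {
        if (i + 2L > n || !grepl("^[0-9][0-9]$", paste0(chars[i + 1L], chars[i + 2L]))) {
          return(FALSE)
        }
        outside <- c(outside, paste0("%", chars[i + 1L], chars[i + 2L]))
        i <- i + 2L
      } else if (grepl("[0-9]", ch)) {
        outside <- c(outside, ch)
      }
    }
    i <- i + 1L
  }
  if (depth_b != 0L || depth_p != 0L) return(FALSE)
  # ring-closure labels must appear an even number of times
  if (length(outside) > 0 && any(table(outside) %% 2L != 0L)) return(FALSE)
  TRUE
}

# Strip isotope labels ([13C] -> [C], [2H] -> [H]) at string level; the bare
# [H] atoms fold back into implicit hydrogens on canonicalization.
strip_isotopes <- function(smi) {
  gsub("\\[([0-9]+)", "[", smi)
}

has_isotopes <- function(smi) {
  grepl("\\[[0-9]", smi)
}

# Parse one SMILES into the internal graph. Returns NULL on failure.
# atoms: idx, symbol, charge, nH (implicit + collapsed explicit), aromatic
# bonds: a1, a2, order   (kekulized orders from the V2000 block)
# rings: list of integer vectors (atom idx); ring_aromatic: logical per ring
mol_from_smiles <- function(smi) {
  if (!smiles_syntax_ok(smi)) return(NULL)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smi)),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) == 0) return(NULL)
  mol_from_sdf(sdf[[1]])
}

mol_from_sdf <- function(sdf) {
  ab <- tryCatch(ChemmineR::atomblock(sdf), error = function(e) NULL)
  if (is.null(ab) || nrow(ab) == 0) return(NULL)
  symbols <- sub("_.*$", "", rownames(ab))
  n_atoms <- length(symbols)

  bb <- tryCatch(ChemmineR::bondblock(sdf), error = function(e) NULL)
  if (!is.null(bb) && !is.matrix(bb)) bb <- matrix(bb, nrow = length(bb) > 0)
  if (is.null(bb) || length(bb) == 0 || nrow(bb) == 0 || ncol(bb) < 3) {
    bonds <- tibble::tibble(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    bb <- matrix(as.integer(bb[, 1:3]), ncol = 3)
    bonds <- tibble::tibble(
      a1 = pmin(bb[, 1], bb[, 2]),
      a2 = pmax(bb[, 1], bb[, 2]),
      order = bb[, 3]
    )
  }

  charge <- integer(n_atoms)
  binfo <- tryCatch(ChemmineR::bonds(sdf, type = "bonds"), error = function(e) NULL)
  if (!is.null(binfo) && nrow(binfo) == n_atoms) {
    charge <- as.integer(binfo$charge)
  }

  # ring perception + aromaticity (ChemmineR exhaustive ring search)
  ringlist <- list()
  ring_aromatic <- logical(0)
  if (nrow(bonds) >= n_atoms) {  # a cycle can only exist if #bonds >= #atoms (per component; cheap guard)
    rr <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, upper = 20, type = "all", arom = TRUE)),
      error = function(e) NULL
    )
    if (!is.null(rr) && length(rr$RINGS) > 0) {
      ringlist <- lapply(rr$RINGS, function(v) as.integer(sub("^.*_", "", v)))
      ring_aromatic <- as.logical(rr$AROMATIC)
    }
  }
  aromatic <- logical(n_atoms)
  if (length(ringlist) > 0) {
    arom_atoms <- unique(unlist(ringlist[ring_aromatic]))
    aromatic[arom_atoms] <- TRUE
  }

  mol <- list(
    atoms = tibble::tibble(
      idx = seq_len(n_atoms), symbol = symbols,
      charge = charge, nH = 0L, aromatic = aromatic
    ),
    bonds = bonds,
    rings = ringlist,
    ring_aromatic = ring_aromatic
  )
  mol <- .collapse_explicit_h(mol)
  mol$atoms$nH <- mol$atoms$nH + .implicit_h(mol)
  mol
}

# Fold explicit hydrogen atoms into the nH count of their heavy neighbor.
.collapse_explicit_h <- function(mol) {
  hs <- which(mol$atoms$symbol == "H")
  if (length(hs) == 0) return(mol)
  extra <- integer(nrow(mol$atoms))
  for (h in hs) {
    nb <- c(
      mol$bonds$a2[mol$bonds$a1 == h],
      mol$bonds$a1[mol$bonds$a2 == h]
    )
    if (length(nb) == 1 && !(mol$atoms$symbol[nb] == "H")) extra[nb] <- extra[nb] + 1L
  }
  keep <- setdiff(seq_len(nrow(mol$atoms)), hs)
  remap <- integer(nrow(mol$atoms))
  remap[keep] <- seq_along(keep)
  bonds <- mol$bonds[!(mol$bonds$a1 %in% hs | mol$bonds$a2 %in% hs), , drop = FALSE]
  bonds$a1 <- remap[bonds$a1]
  bonds$a2 <- remap[bonds$a2]
  atoms <- mol$atoms[keep, , drop = FALSE]
  atoms$idx <- seq_len(nrow(atoms))
  atoms$nH <- atoms$nH + extra[keep]
  rings <- lapply(mol$rings, function(r) remap[r])
  list(atoms = atoms, bonds = bonds, rings = rings, ring_aromatic = mol$ring_aromatic)
}

.bond_order_sum <- function(mol) {
  n <- nrow(mol$atoms)
  s <- numeric(n)
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds$order[k]
      s[mol$bonds$a1[k]] <- s[mol$bonds$a1[k]] + o
      s[mol$bonds$a2[k]] <- s[mol$bonds$a2[k]] + o
    }
  }
  s
}

.implicit_h <- function(mol) {
  sym <- mol$atoms$symbol
  chg <- mol$atoms$charge
  dv <- unname(.default_valence[sym])
  dv[is.na(dv)] <- 0
  adj <- ifelse(sym %in% c("N", "P", "O", "S"), chg,
    ifelse(sym == "C", -abs(chg), 0)
  )
  bs <- .bond_order_sum(mol)
  pmax(0L, as.integer(round(dv + adj - bs)))
}

# Neighbor indices of atom i.
mol_neighbors <- function(mol, i) {
  c(mol$bonds$a2[mol$bonds$a1 == i], mol$bonds$a1[mol$bonds$a2 == i])
}

mol_bond_order <- function(mol, i, j) {
  a <- pmin(i, j); b <- pmax(i, j)
  k <- which(mol$bonds$a1 == a & mol$bonds$a2 == b)
  if (length(k) == 0) 0L else mol$bonds$order[k[1]]
}

mol_degree <- function(mol) {
  n <- nrow(mol$atoms)
  tabulate(c(mol$bonds$a1, mol$bonds$a2), nbins = n)
}

# Connected components over the bond graph (fragment detection).
mol_components <- function(mol) {
  n <- nrow(mol$atoms)
  comp <- seq_len(n)
  find <- function(x) {
    while (comp[x] != x) {
      comp[x] <<- comp[comp[x]]
      x <- comp[x]
    }
    x
  }
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      ra <- find(mol$bonds$a1[k]); rb <- find(mol$bonds$a2[k])
      if (ra != rb) comp[ra] <- rb
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Extract the sub-molecule induced by a set of atom indices.
mol_subset <- function(mol, keep) {
  keep <- sort(keep)
  remap <- integer(nrow(mol$atoms))
  remap[keep] <- seq_along(keep)
  bonds <- mol$bonds[mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep, , drop = FALSE]
  bonds$a1 <- remap[bonds$a1]
  bonds$a2 <- remap[bonds$a2]
  atoms <- mol$atoms[keep, , drop = FALSE]
  atoms$idx <- seq_len(nrow(atoms))
  keep_ring <- vapply(mol$rings, function(r) all(r %in% keep), logical(1))
  rings <- lapply(mol$rings[keep_ring], function(r) remap[r])
  list(
    atoms = atoms, bonds = bonds, rings = rings,
    ring_aromatic = mol$ring_aromatic[keep_ring]
  )
}

mol_weight <- function(mol) {
  m <- unname(.atomic_mass[mol$atoms$symbol])
  m[is.na(m)] <- 0
  sum(m) + sum(mol$atoms$nH) * .atomic_mass[["H"]]
}

# Serialize the graph as V2000 SDF text (kekulized orders, M CHG for formal
# charges). Implicit hydrogens are left for the reader to recompute, which is
# why charge edits alone are enough to (de)protonate.
mol_to_sdf <- function(mol) {
  n_at <- nrow(mol$atoms)
  n_bd <- nrow(mol$bonds)
  header <- c("mol", "  pfasmap", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_at, n_bd)
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, mol$atoms$symbol
  )
  bond_lines <- if (n_bd > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$a1, mol$bonds$a2, mol$bonds$order)
  } else {
    character(0)
  }
  chg <- which(mol$atoms$charge != 0)
  chg_lines <- character(0)
  if (length(chg) > 0) {
    groups <- split(chg, ceiling(seq_along(chg) / 8))
    chg_lines <- vapply(groups, function(g) {
      paste0(
        sprintf("M  CHG%3d", length(g)),
        paste0(sprintf("%4d%4d", g, mol$atoms$charge[g]), collapse = "")
      )
    }, character(1))
  }
  paste(c(header, counts, atom_lines, bond_lines, chg_lines, "M  END", "$$$$", ""),
    collapse = "\n"
  )
}

# Canonical SMILES of a graph (via SDF round trip so charges survive).
mol_canonical <- function(mol) {
  txt <- mol_to_sdf(mol)
  r <- tryCatch(
    ChemmineOB::convertFormat("SDF", "CAN", source = txt),
    error = function(e) ""
  )
  r <- sub("[\t\n].*$", "", r)
  if (!nzchar(r)) NA_character_ else r
}

# --- convenience element queries used across modules ---

mol_symbol_count <- function(mol, sym) {
  sum(mol$atoms$symbol == sym)
}

# F neighbors per atom
mol_f_count <- function(mol, i) {
  sum(mol$atoms$symbol[mol_neighbors(mol, i)] == "F")
}

# sp3 carbon: carbon, not aromatic, all incident bonds single
mol_is_sp3_carbon <- function(mol, i) {
  if (mol$atoms$symbol[i] != "C" || mol$atoms$aromatic[i]) return(FALSE)
  ords <- c(
    mol$bonds$order[mol$bonds$a1 == i],
    mol$bonds$order[mol$bonds$a2 == i]
  )
  length(ords) == 0 || all(ords == 1)
}
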