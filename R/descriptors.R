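# Descriptor engine: per-structure feature vectors and the pruned matrix
# that feeds PCA. The catalog is the package's own fixed set of 1D/2D
# descriptors (constitutional counts, graph-topological indices, OpenBabel
# property block) concatenated with a 1024-bit path-based substructure
# fingerprint (OpenBabel FP2). Features that cannot be computed for a
# structure are NA ("invalid"), never silently zeroed.

#' Simple element and aromaticity counts
#'
#' The counts used by the classification rules alongside SMILES: numbers of
#' C, H, O, N, P, S and F atoms (H includes implicit hydrogens) plus the
#' aromatic atom count.
#'
#' @param data A data frame with a `canonical_smiles` column, or a character
#'   vector of SMILES.
#' @return A tibble with `canonical_smiles` and columns `C`, `H`, `O`, `N`,
#'   `P`, `S`, `F`, `aromatic_atom_count`.
#' @examples
#' pfas_element_counts("CCO")
#' @export
pfas_element_counts <- function(data) {
  if (is.character(data)) data <- tibble::tibble(canonical_smiles = canonicalize_smiles(data))
  stopifnot("canonical_smiles" %in% names(data))
  dplyr::bind_rows(purrr::map(data$canonical_smiles, function(s) {
    mol <- if (is.na(s)) NULL else mol_from_smiles(s)
    if (is.null(mol)) {
      return(tibble::tibble(
        canonical_smiles = s, C = NA_integer_, H = NA_integer_, O = NA_integer_,
        N = NA_integer_, P = NA_integer_, S = NA_integer_, F = NA_integer_,
        aromatic_atom_count = NA_integer_
      ))
    }
    tibble::tibble(
      canonical_smiles = s,
      C = mol_symbol_count(mol, "C"),
      H = sum(mol$atoms$nH),
      O = mol_symbol_count(mol, "O"),
      N = mol_symbol_count(mol, "N"),
      P = mol_symbol_count(mol, "P"),
      S = mol_symbol_count(mol, "S"),
      F = mol_symbol_count(mol, "F"),
      aromatic_atom_count = sum(mol$atoms$aromatic)
    )
  }))
}

# graph-topological block for one molecule
.topo_descriptors <- function(mol) {
  n <- nrow(mol$atoms)
  deg <- mol_degree(mol)
  if (nrow(mol$bonds) > 0) {
    g <- igraph::graph_from_edgelist(
      cbind(mol$bonds$a1, mol$bonds$a2),
      directed = FALSE
    )
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    d <- igraph::distances(g)
    finite <- d[is.finite(d)]
    wiener <- sum(finite) / 2
    diam <- max(finite)
  } else {
    wiener <- 0
    diam <- 0
  }
  ring_bonds <- 0L
  if (length(mol$rings) > 0 && nrow(mol$bonds) > 0) {
    in_ring <- vapply(seq_len(nrow(mol$bonds)), function(k) {
      any(vapply(mol$rings, function(r) {
        mol$bonds$a1[k] %in% r && mol$bonds$a2[k] %in% r
      }, logical(1)))
    }, logical(1))
    ring_bonds <- sum(in_ring)
  } else {
    in_ring <- logical(nrow(mol$bonds))
  }
  rotatable <- 0L
  if (nrow(mol$bonds) > 0) {
    rotatable <- sum(
      mol$bonds$order == 1L & !in_ring &
        deg[mol$bonds$a1] > 1L & deg[mol$bonds$a2] > 1L
    )
  }
  c(
    wiener_index = wiener,
    graph_diameter = diam,
    zagreb_m1 = sum(deg^2),
    zagreb_m2 = if (nrow(mol$bonds) > 0) sum(deg[mol$bonds$a1] * deg[mol$bonds$a2]) else 0,
    n_branch_points = sum(deg >= 3L),
    n_terminal_atoms = sum(deg == 1L),
    n_rotatable_bonds = rotatable,
    n_ring_bonds = ring_bonds
  )
}

# constitutional block for one molecule
.count_descriptors <- function(mol) {
  cf3 <- sum(vapply(seq_len(nrow(mol$atoms)), .is_cf3, logical(1), mol = mol))
  cf2 <- sum(vapply(seq_len(nrow(mol$atoms)), .is_chain_cf2, logical(1), mol = mol))
  carbons <- which(mol$atoms$symbol == "C")
  fluorinated_c <- sum(vapply(carbons, function(i) mol_f_count(mol, i) > 0, logical(1)))
  c(
    n_C = mol_symbol_count(mol, "C"),
    n_H = sum(mol$atoms$nH),
    n_O = mol_symbol_count(mol, "O"),
    n_N = mol_symbol_count(mol, "N"),
    n_P = mol_symbol_count(mol, "P"),
    n_S = mol_symbol_count(mol, "S"),
    n_F = mol_symbol_count(mol, "F"),
    n_Cl = mol_symbol_count(mol, "Cl"),
    n_Br = mol_symbol_count(mol, "Br"),
    n_I = mol_symbol_count(mol, "I"),
    n_Si = mol_symbol_count(mol, "Si"),
    n_heavy_atoms = nrow(mol$atoms),
    n_aromatic_atoms = sum(mol$atoms$aromatic),
    n_rings = length(mol$rings),
    n_bonds = nrow(mol$bonds),
    n_double_bonds = sum(mol$bonds$order == 2L),
    n_triple_bonds = sum(mol$bonds$order == 3L),
    n_CF3 = cf3,
    n_chain_CF2 = cf2,
    perfluoro_chain_n = .perfluoro_chain_n(mol),
    frac_fluorinated_carbon = if (length(carbons) > 0) fluorinated_c / length(carbons) else 0,
    molecular_weight = mol_weight(mol)
  )
}

#' Compute descriptor vectors for a structure set
#'
#' Builds the package's fixed descriptor catalog for each structure:
#' constitutional counts, graph-topological indices, the OpenBabel property
#' block (logP, molar refractivity, TPSA, H-bond acceptor/donor counts), and
#' a 1024-bit FP2 path fingerprint. The feature ordering is fixed across a
#' batch; identical structures give identical vectors. Features that fail
#' for a structure are `NA`.
#'
#' @param data A data frame with a `canonical_smiles` column, or a character
#'   vector of SMILES.
#' @param fingerprint_bits Number of fingerprint bits appended (<= 1024;
#'   the leading bits of the FP2 fingerprint).
#' @return A tibble: `canonical_smiles` followed by named descriptor columns
#'   and fingerprint bit columns `fp_0001` ...
#' @export
pfas_descriptors <- function(data, fingerprint_bits = 1024L) {
  if (is.character(data)) data <- tibble::tibble(canonical_smiles = canonicalize_smiles(data))
  stopifnot("canonical_smiles" %in% names(data))
  stopifnot(fingerprint_bits >= 0, fingerprint_bits <= 1024)
  smis <- data$canonical_smiles

  mols <- purrr::map(smis, function(s) if (is.na(s)) NULL else mol_from_smiles(s))
  base_names <- c(
    names(.count_descriptors(mol_from_smiles("C"))),
    names(.topo_descriptors(mol_from_smiles("C")))
  )
  base <- t(vapply(mols, function(mol) {
    if (is.null(mol)) {
      return(stats::setNames(rep(NA_real_, length(base_names)), base_names))
    }
    c(.count_descriptors(mol), .topo_descriptors(mol))
  }, stats::setNames(numeric(length(base_names)), base_names)))

  # OpenBabel property block + fingerprint, computed in batch
  prop_names <- c("logP", "MR", "TPSA", "HBA1", "HBA2", "HBD")
  props <- matrix(NA_real_, nrow = length(smis), ncol = length(prop_names),
    dimnames = list(NULL, prop_names))
  fps <- matrix(NA_real_, nrow = length(smis), ncol = fingerprint_bits)
  if (fingerprint_bits > 0) {
    colnames(fps) <- sprintf("fp_%04d", seq_len(fingerprint_bits))
  }
  ok <- which(!vapply(mols, is.null, logical(1)))
  if (length(ok) > 0) {
    sdfs <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(smis[ok])),
      error = function(e) NULL
    )
    if (!is.null(sdfs)) {
      suppressWarnings(ChemmineR::cid(sdfs) <- paste0("m", ok))
      # bond-less (single-atom) structures yield SDF records the toolkit
      # flags invalid; their OB-derived features stay NA (masked)
      valid <- suppressWarnings(ChemmineR::validSDF(sdfs))
      ok <- ok[valid]
      sdfs <- sdfs[valid]
      pb <- tryCatch(
        suppressWarnings(ChemmineR::propOB(sdfs)),
        error = function(e) NULL
      )
      if (!is.null(pb)) {
        for (nm in prop_names) {
          if (nm %in% colnames(pb)) props[ok, nm] <- as.numeric(pb[[nm]])
        }
      }
      if (fingerprint_bits > 0) {
        fb <- tryCatch(
          suppressWarnings(
            methods::slot(ChemmineR::fingerprintOB(sdfs, "FP2"), "fpma")
          ),
          error = function(e) NULL
        )
        if (!is.null(fb)) fps[ok, ] <- fb[, seq_len(fingerprint_bits), drop = FALSE]
      }
    }
  }

  out <- tibble::as_tibble(cbind(base, props, if (fingerprint_bits > 0) fps))
  dplyr::bind_cols(tibble::tibble(canonical_smiles = smis), out)
}

#' Assemble and prune the descriptor matrix
#'
#' Drops features whose invalid (NA) fraction exceeds the threshold, imputes
#' the surviving scattered invalids with the column median, and records the
#' raw and retained dimensionality. Pruning decisions depend only on the set
#' of rows, not their order.
#'
#' @param descriptors A tibble from [pfas_descriptors()].
#' @param invalid_fraction_threshold Features invalid in more than this
#'   fraction of structures are removed (default 0.1).
#' @return A `pfas_descriptor_matrix`: list with `data` (tibble, no missing
#'   values), `features`, `medians` (training medians used for imputation),
#'   `raw_n_features`, `retained_n_features`, `invalid_fraction_threshold`.
#' @export
prune_descriptors <- function(descriptors, invalid_fraction_threshold = 0.1) {
  stopifnot(
    is.data.frame(descriptors),
    invalid_fraction_threshold >= 0, invalid_fraction_threshold <= 1
  )
  keys <- descriptors$canonical_smiles
  num <- descriptors[, setdiff(names(descriptors), "canonical_smiles"), drop = FALSE]
  raw_n <- ncol(num)
  invalid_frac <- vapply(num, function(col) mean(is.na(col)), numeric(1))
  keep <- names(invalid_frac)[invalid_frac <= invalid_fraction_threshold]
  if (length(keep) == 0) {
    stop("empty_matrix: every feature exceeded the invalid-fraction threshold")
  }
  num <- num[, keep, drop = FALSE]
  medians <- vapply(num, function(col) stats::median(col, na.rm = TRUE), numeric(1))
  for (j in seq_along(num)) {
    miss <- is.na(num[[j]])
    if (any(miss)) num[[j]][miss] <- medians[j]
  }
  structure(
    list(
      data = dplyr::bind_cols(tibble::tibble(canonical_smiles = keys), num),
      features = keep,
      medians = medians,
      raw_n_features = raw_n,
      retained_n_features = length(keep),
      invalid_fraction_threshold = invalid_fraction_threshold
    ),
    class = "pfas_descriptor_matrix"
  )
}

#' @export
print.pfas_descriptor_matrix <- function(x, ...) {
  cat(
    "<pfas_descriptor_matrix> ", nrow(x$data), " structures x ",
    x$retained_n_features, " features (", x$raw_n_features, " raw, threshold ",
    x$invalid_fraction_threshold, ")\n",
    sep = ""
  )
  invisible(x)
}

# Align a new descriptor tibble to the feature schema of a pruned training
# matrix: select its retained features and fill residual NAs with the
# training medians.
align_descriptors <- function(matrix_obj, descriptors) {
  stopifnot(inherits(matrix_obj, "pfas_descriptor_matrix"))
  missing <- setdiff(matrix_obj$features, names(descriptors))
  if (length(missing) > 0) {
    stop("schema_mismatch: descriptor columns absent: ", paste(utils::head(missing), collapse = ", "))
  }
  num <- descriptors[, matrix_obj$features, drop = FALSE]
  for (j in seq_along(num)) {
    miss <- is.na(num[[j]])
    if (any(miss)) num[[j]][miss] <- matrix_obj$medians[[j]]
  }
  dplyr::bind_cols(
    tibble::tibble(canonical_smiles = descriptors$canonical_smiles),
    num
  )
}

#' Write a descriptor matrix and its column manifest
#'
#' @param matrix_obj A `pfas_descriptor_matrix` from [prune_descriptors()].
#' @param path Output CSV (first column `canonical_smiles`).
#' @param manifest_path Optional text file listing retained feature names.
#' @return `matrix_obj`, invisibly.
#' @export
write_descriptor_matrix <- function(matrix_obj, path, manifest_path = NULL) {
  utils::write.csv(matrix_obj$data, path, row.names = FALSE)
  if (!is.null(manifest_path)) {
    writeLines(matrix_obj$features, manifest_path)
  }
  invisible(matrix_obj)
}
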