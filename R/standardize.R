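#' Standardize SMILES records into a single canonical dialect
#'
#' Runs each record through the preprocessing used to build the reference map:
#' largest-fragment salt stripping, isotope-label removal, charge
#' neutralization (protonate anionic O/N/S, deprotonate protonated amines),
#' and canonicalization into the package's declared canonical SMILES dialect.
#' Records whose SMILES cannot be parsed are reported, never fatal.
#'
#' @param data A data frame with an identifier column and a SMILES column, or
#'   a character vector of SMILES (identifiers are then generated).
#' @param smiles,id Column names (strings) holding the SMILES and the record
#'   identifier. Ignored when `data` is a character vector.
#' @return A tibble with one row per input record: `id`, `input_smiles`,
#'   `canonical_smiles`, the provenance flags `salt_stripped`,
#'   `isotopes_removed`, `neutralized`, `uncorrectable_charge`, plus `valid`
#'   and `reject_reason` (`NA` for accepted records, `"invalid_smiles"`
#'   otherwise).
#' @examples
#' pfas_standardize(c("CCO", "[O-]C(=O)C(F)(F)F.[Na+]"))
#' @export
pfas_standardize <- function(data, smiles = "smiles", id = "id") {
  if (is.character(data)) {
    data <- tibble::tibble(
      id = paste0("S", seq_along(data)),
      smiles = data
    )
    smiles <- "smiles"
    id <- "id"
  }
  stopifnot(is.data.frame(data), smiles %in% names(data))
  ids <- if (id %in% names(data)) as.character(data[[id]]) else paste0("S", seq_len(nrow(data)))
  if (anyDuplicated(ids)) stop("record identifiers must be unique within a batch")
  smi <- as.character(data[[smiles]])

  rows <- purrr::map2(ids, smi, function(i, s) {
    res <- .standardize_one(s)
    tibble::tibble(
      id = i, input_smiles = s,
      canonical_smiles = res$canonical,
      salt_stripped = res$salt_stripped,
      isotopes_removed = res$isotopes_removed,
      neutralized = res$neutralized,
      uncorrectable_charge = res$uncorrectable_charge,
      valid = res$valid,
      reject_reason = res$reason
    )
  })
  dplyr::bind_rows(rows)
}

.standardize_one <- function(smi) {
  reject <- list(
    canonical = NA_character_, salt_stripped = NA, isotopes_removed = NA,
    neutralized = NA, uncorrectable_charge = NA, valid = FALSE,
    reason = "invalid_smiles"
  )
  if (is.na(smi) || !nzchar(trimws(smi)) || !smiles_syntax_ok(trimws(smi))) {
    return(reject)
  }
  smi <- trimws(smi)
  iso <- has_isotopes(smi)
  mol <- mol_from_smiles(strip_isotopes(smi))
  if (is.null(mol) || nrow(mol$atoms) == 0) return(reject)

  # salt stripping: keep the fragment with the most heavy atoms; ties broken
  # by molecular weight, then by smallest canonical SMILES
  comp <- mol_components(mol)
  salt_stripped <- length(unique(comp)) > 1
  if (salt_stripped) {
    frags <- lapply(unique(comp), function(cc) mol_subset(mol, which(comp == cc)))
    heavy <- vapply(frags, function(m) sum(m$atoms$symbol != "H"), integer(1))
    cand <- which(heavy == max(heavy))
    if (length(cand) > 1) {
      mw <- vapply(frags[cand], mol_weight, numeric(1))
      cand <- cand[mw == max(mw)]
    }
    if (length(cand) > 1) {
      cans <- vapply(frags[cand], mol_canonical, character(1))
      cand <- cand[order(cans)][1]
    }
    mol <- frags[[cand[1]]]
  }

  # neutralization; charge-separated pairs (e.g. nitro) are left intact
  neutralized <- FALSE
  chg <- mol$atoms$charge
  if (any(chg != 0)) {
    bs <- .bond_order_sum(mol)
    for (i in which(chg != 0)) {
      nb <- mol_neighbors(mol, i)
      if (chg[i] < 0 && mol$atoms$symbol[i] %in% c("O", "N", "S") &&
        !any(mol$atoms$charge[nb] > 0)) {
        mol$atoms$charge[i] <- 0L
        neutralized <- TRUE
      } else if (chg[i] > 0 && mol$atoms$symbol[i] == "N" && bs[i] <= 3 &&
        !any(mol$atoms$charge[nb] < 0)) {
        mol$atoms$charge[i] <- 0L
        neutralized <- TRUE
      }
    }
  }
  uncorrectable <- sum(mol$atoms$charge) != 0

  canonical <- mol_canonical(mol)
  if (is.na(canonical)) return(reject)
  list(
    canonical = canonical, salt_stripped = salt_stripped,
    isotopes_removed = iso, neutralized = neutralized,
    uncorrectable_charge = uncorrectable, valid = TRUE, reason = NA_character_
  )
}

#' Collapse standardized records to distinct structures
#'
#' One row per distinct canonical SMILES; the identifiers of all records that
#' collapsed onto a structure are kept in the `source_ids` list-column. The
#' order of first occurrence is preserved. Invalid records are dropped.
#'
#' @param standardized A tibble from [pfas_standardize()].
#' @return A tibble with `canonical_smiles`, `source_ids` (list of character),
#'   `n_sources`, and the OR-combined provenance flags.
#' @export
pfas_deduplicate <- function(standardized) {
  stopifnot("canonical_smiles" %in% names(standardized))
  ok <- standardized[standardized$valid %||% TRUE, , drop = FALSE]
  ok <- ok[!is.na(ok$canonical_smiles), , drop = FALSE]
  ok |>
    dplyr::mutate(.first = dplyr::row_number()) |>
    dplyr::summarise(
      source_ids = list(.data$id),
      n_sources = dplyr::n(),
      salt_stripped = any(.data$salt_stripped),
      isotopes_removed = any(.data$isotopes_removed),
      neutralized = any(.data$neutralized),
      uncorrectable_charge = any(.data$uncorrectable_charge),
      .first = min(.data$.first),
      .by = "canonical_smiles"
    ) |>
    dplyr::arrange(.data$.first) |>
    dplyr::select(-".first")
}

#' Read a SMILES (.smi) file
#'
#' One record per line: a SMILES string optionally followed by
#' whitespace-separated identifier. Missing identifiers are generated.
#'
#' @param path Path to the file.
#' @return A tibble with columns `id` and `smiles`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  tibble::tibble(
    id = vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1) parts[[i]][2] else paste0("S", i)
    }, character(1)),
    smiles = vapply(parts, `[[`, character(1), 1)
  )
}

#' Write standardization results
#'
#' Writes accepted records as CSV
#' (`id,canonical_smiles,salt_stripped,isotopes_removed,neutralized`) and,
#' when a `rejects_path` is supplied, the rejected records as
#' `id,smiles,reason`.
#'
#' @param standardized A tibble from [pfas_standardize()].
#' @param path Output CSV for accepted records.
#' @param rejects_path Optional output CSV for rejected records.
#' @return `standardized`, invisibly.
#' @export
write_standardized <- function(standardized, path, rejects_path = NULL) {
  ok <- standardized[standardized$valid, c(
    "id", "canonical_smiles", "salt_stripped", "isotopes_removed", "neutralized"
  )]
  utils::write.csv(ok, path, row.names = FALSE)
  if (!is.null(rejects_path)) {
    bad <- standardized[!standardized$valid, c("id", "input_smiles", "reject_reason")]
    names(bad) <- c("id", "smiles", "reason")
    utils::write.csv(bad, rejects_path, row.names = FALSE)
  }
  invisible(standardized)
}
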