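# Reference/user two-path pipeline: the reference set is standardized,
# classified, featurized, PCA-reduced and t-SNE-embedded once; user
# compounds go through the identical standardization/classification/
# descriptor path but are projected with the *trained* PCA (never refit)
# and placed on the trained embedding by k-NN interpolation.

#' Build a reference structure-function map
#'
#' Runs the full reference path: standardize, deduplicate, classify, compute
#' and prune descriptors, fit PCA to the variance target, and embed with
#' seeded 3D t-SNE.
#'
#' @param data A data frame with `id` and `smiles` columns, or a character
#'   vector of SMILES.
#' @param variance_target Cumulative explained-variance target for PCA
#'   (default 0.70).
#' @param perplexity,steps,seed t-SNE hyperparameters (defaults 50, 1000, 0).
#' @param invalid_fraction_threshold Descriptor pruning threshold
#'   (default 0.1).
#' @param fingerprint_bits Fingerprint bits in the descriptor catalog.
#' @return A `pfas_reference` object bundling the standardization table, the
#'   deduplicated structures, classification results, the pruned descriptor
#'   matrix, the `pfas_pca` model, the `pfas_tsne` embedding, and the
#'   resolved configuration.
#' @export
build_reference <- function(data,
                            variance_target = 0.70,
                            perplexity = 50,
                            steps = 1000L,
                            seed = 0L,
                            invalid_fraction_threshold = 0.1,
                            fingerprint_bits = 1024L) {
  std <- pfas_standardize(data)
  structures <- pfas_deduplicate(std)
  classes <- pfas_classify(structures[, "canonical_smiles"])
  desc <- pfas_descriptors(structures[, "canonical_smiles"], fingerprint_bits = fingerprint_bits)
  dm <- prune_descriptors(desc, invalid_fraction_threshold = invalid_fraction_threshold)
  pca <- fit_pfas_pca(dm, variance_target = variance_target)
  tsne <- fit_pfas_tsne(pca, perplexity = perplexity, steps = steps, seed = seed)
  structure(
    list(
      standardized = std,
      structures = structures,
      classification = classes,
      descriptor_matrix = dm,
      pca = pca,
      tsne = tsne,
      config = list(
        variance_target = variance_target, perplexity = perplexity,
        steps = as.integer(steps), seed = as.integer(seed),
        invalid_fraction_threshold = invalid_fraction_threshold,
        fingerprint_bits = as.integer(fingerprint_bits),
        k_retained = pca$k,
        tsne_defaults = tsne$config,
        package_version = as.character(utils::packageVersion("pfasmap"))
      )
    ),
    class = "pfas_reference"
  )
}

#' @export
print.pfas_reference <- function(x, ...) {
  cat(
    "<pfas_reference> ", nrow(x$structures), " distinct structures (",
    sum(!x$standardized$valid), " rejected), ",
    x$descriptor_matrix$retained_n_features, " features -> ",
    x$pca$k, " components -> 3D embedding (seed ", x$config$seed, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Classify and place user compounds on a trained reference map
#'
#' User compounds are standardized and classified exactly as reference
#' compounds; their descriptors are aligned to the reference feature schema,
#' projected by the trained PCA model, and placed on the reference embedding
#' by inverse-distance-weighted k-nearest-neighbor interpolation.
#'
#' @param reference A `pfas_reference` from [build_reference()].
#' @param data A data frame with `id` and `smiles`, or a character vector.
#' @param k_neighbors Neighbors used for embedding placement (default 10).
#' @return A tibble with one row per valid user record: `id`,
#'   `canonical_smiles`, the classification columns, `tsne_pca_1..3`, and
#'   `provenance = "user_placed"`.
#' @export
place_compounds <- function(reference, data, k_neighbors = 10L) {
  stopifnot(inherits(reference, "pfas_reference"))
  std <- pfas_standardize(data)
  ok <- std[std$valid, , drop = FALSE]
  if (nrow(ok) == 0) stop("no valid user structures to place")
  classes <- pfas_classify(ok[, c("id", "canonical_smiles")])
  desc <- pfas_descriptors(ok[, "canonical_smiles"],
    fingerprint_bits = reference$config$fingerprint_bits)
  aligned <- align_descriptors(reference$descriptor_matrix, desc)
  scores <- stats::predict(reference$pca, aligned)
  placed <- place_user_points(
    reference$tsne,
    reference$pca$scores,
    scores[, setdiff(names(scores), "canonical_smiles"), drop = FALSE],
    k_neighbors = k_neighbors
  )
  dplyr::bind_cols(
    classes,
    placed[, grep("^tsne_pca_", names(placed), value = TRUE), drop = FALSE]
  ) |>
    dplyr::mutate(provenance = "user_placed")
}

#' Persist and restore a reference map
#'
#' Writes the trained PCA model (feature schema with hash, means, standard
#' deviations, loadings, variance ratios) as JSON plus the coordinates,
#' scores and classification tables as CSV, so user compounds can be placed
#' later without refitting.
#'
#' @param reference A `pfas_reference`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly (`write_reference`); a restored
#'   `pfas_reference` (`read_reference`).
#' @export
write_reference <- function(reference, dir) {
  stopifnot(inherits(reference, "pfas_reference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pca <- reference$pca
  model <- list(
    features = pca$features,
    schema_hash = .schema_hash(pca$features),
    means = as.list(stats::setNames(pca$means, pca$features)),
    sds = as.list(stats::setNames(pca$sds, pca$features)),
    loadings = unname(apply(pca$loadings, 2, as.numeric, simplify = FALSE)),
    ratios = pca$ratios,
    k = pca$k,
    variance_target = pca$variance_target
  )
  jsonlite::write_json(model, file.path(dir, "pca_model.json"),
    auto_unbox = TRUE, digits = NA)
  utils::write.csv(
    dplyr::bind_cols(
      tibble::tibble(canonical_smiles = pca$row_keys),
      tibble::as_tibble(pca$scores)
    ),
    file.path(dir, "scores.csv"),
    row.names = FALSE
  )
  utils::write.csv(reference$tsne$coordinates, file.path(dir, "coordinates.csv"),
    row.names = FALSE)
  utils::write.csv(reference$classification, file.path(dir, "classification.csv"),
    row.names = FALSE)
  utils::write.csv(reference$descriptor_matrix$data, file.path(dir, "descriptors.csv"),
    row.names = FALSE)
  writeLines(
    yaml::as.yaml(reference$config),
    file.path(dir, "run_config.yaml")
  )
  invisible(dir)
}

.schema_hash <- function(features) {
  # order-sensitive polynomial hash over the concatenated feature names
  h <- 0
  for (ch in utf8ToInt(paste(features, collapse = "|"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  sprintf("%08x", h)
}

#' @rdname write_reference
#' @export
read_reference <- function(dir) {
  model <- jsonlite::read_json(file.path(dir, "pca_model.json"), simplifyVector = TRUE)
  features <- model$features
  if (!identical(.schema_hash(features), model$schema_hash)) {
    stop("schema_mismatch: stored feature schema fails its hash check")
  }
  loadings <- if (is.list(model$loadings)) {
    do.call(cbind, lapply(model$loadings, as.numeric))
  } else {
    t(as.matrix(model$loadings))  # simplified to a k x p matrix on read
  }
  rownames(loadings) <- features
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  scores_df <- utils::read.csv(file.path(dir, "scores.csv"), check.names = FALSE)
  scores <- as.matrix(scores_df[, -1, drop = FALSE])
  pca <- structure(
    list(
      features = features,
      means = unlist(model$means)[features],
      sds = unlist(model$sds)[features],
      loadings = loadings,
      ratios = model$ratios,
      k = model$k,
      variance_target = model$variance_target,
      scores = scores,
      row_keys = scores_df[[1]]
    ),
    class = "pfas_pca"
  )
  coords <- tibble::as_tibble(utils::read.csv(file.path(dir, "coordinates.csv"),
    check.names = FALSE))
  classification <- tibble::as_tibble(utils::read.csv(file.path(dir, "classification.csv"),
    check.names = FALSE))
  desc <- tibble::as_tibble(utils::read.csv(file.path(dir, "descriptors.csv"),
    check.names = FALSE))
  config <- yaml::read_yaml(file.path(dir, "run_config.yaml"))
  dm <- structure(
    list(
      data = desc,
      features = features,
      medians = vapply(desc[, features, drop = FALSE], stats::median, numeric(1)),
      raw_n_features = length(features),
      retained_n_features = length(features),
      invalid_fraction_threshold = config$invalid_fraction_threshold
    ),
    class = "pfas_descriptor_matrix"
  )
  tsne <- structure(
    list(
      coordinates = coords,
      config = config$tsne_defaults,
      kl_divergence = NA_real_,
      n = nrow(coords)
    ),
    class = "pfas_tsne"
  )
  structure(
    list(
      standardized = NULL,
      structures = tibble::tibble(canonical_smiles = classification$canonical_smiles),
      classification = classification,
      descriptor_matrix = dm,
      pca = pca,
      tsne = tsne,
      config = config
    ),
    class = "pfas_reference"
  )
}
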