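# PCA on the descriptor matrix, retaining the smallest number of components
# whose cumulative explained-variance ratio reaches the target (default 70%).
# Features are standardized (zero mean, unit variance) first; zero-variance
# features carry no information and are dropped.

#' Fit a PCA model to a descriptor matrix
#'
#' @param x A `pfas_descriptor_matrix`, a data frame with a
#'   `canonical_smiles` column plus numeric features, or a numeric matrix.
#' @param variance_target Retain the smallest k whose cumulative explained
#'   variance ratio is at least this value (in (0, 1], default 0.70).
#' @return A `pfas_pca` object: feature names, means, standard deviations,
#'   orthonormal loading matrix (features x k), all explained-variance
#'   ratios, `k`, and the training scores.
#' @export
fit_pfas_pca <- function(x, variance_target = 0.70) {
  stopifnot(variance_target > 0, variance_target <= 1)
  parts <- .as_feature_matrix(x)
  X <- parts$X
  if (nrow(X) < 2) stop("PCA needs at least two structures")
  if (anyNA(X)) stop("descriptor matrix must not contain missing values; prune first")

  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("degenerate_matrix: no feature varies across structures")
  means <- colMeans(X[, keep, drop = FALSE])
  Z <- scale(X[, keep, drop = FALSE], center = means, scale = sds[keep])
  p <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  ratios <- p$sdev^2 / sum(p$sdev^2)
  cum <- cumsum(ratios)
  k <- which(cum >= variance_target - 1e-12)[1]

  structure(
    list(
      features = colnames(X)[keep],
      means = means,
      sds = sds[keep],
      loadings = p$rotation[, seq_len(k), drop = FALSE],
      ratios = ratios,
      k = k,
      variance_target = variance_target,
      scores = p$x[, seq_len(k), drop = FALSE],
      row_keys = parts$keys
    ),
    class = "pfas_pca"
  )
}

.as_feature_matrix <- function(x) {
  if (inherits(x, "pfas_descriptor_matrix")) x <- x$data
  if (is.data.frame(x)) {
    keys <- if ("canonical_smiles" %in% names(x)) x$canonical_smiles else NULL
    num <- x[, setdiff(names(x), "canonical_smiles"), drop = FALSE]
    X <- as.matrix(num)
  } else {
    keys <- rownames(x)
    X <- as.matrix(x)
  }
  storage.mode(X) <- "double"
  list(X = X, keys = keys)
}

#' Project structures into a trained PCA space
#'
#' Scores are computed as the standardized (training means/sds) feature
#' values multiplied by the training loadings; transforming the training data
#' reproduces the fit scores.
#'
#' @param object A `pfas_pca` model.
#' @param newdata Data with the model's feature columns (descriptor tibble,
#'   `pfas_descriptor_matrix`, or matrix).
#' @param ... Unused.
#' @return A tibble of scores `PC1` ... `PCk` (with `canonical_smiles` when
#'   available).
#' @export
predict.pfas_pca <- function(object, newdata, ...) {
  parts <- .as_feature_matrix(newdata)
  missing <- setdiff(object$features, colnames(parts$X))
  if (length(missing) > 0) {
    stop("schema_mismatch: features absent from new data: ",
      paste(utils::head(missing), collapse = ", "))
  }
  Z <- scale(parts$X[, object$features, drop = FALSE],
    center = object$means, scale = object$sds)
  S <- Z %*% object$loadings
  colnames(S) <- paste0("PC", seq_len(ncol(S)))
  out <- tibble::as_tibble(S)
  if (!is.null(parts$keys)) {
    out <- dplyr::bind_cols(tibble::tibble(canonical_smiles = parts$keys), out)
  }
  out
}

#' @export
print.pfas_pca <- function(x, ...) {
  cat(
    "<pfas_pca> ", length(x$features), " features -> ", x$k,
    " components (cumulative explained variance ",
    sprintf("%.3f", sum(x$ratios[seq_len(x$k)])),
    " >= target ", x$variance_target, ")\n",
    sep = ""
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-component summary of a PCA model
#'
#' @param x A `pfas_pca` object.
#' @param ... Unused.
#' @return A tibble with `component`, `variance_ratio`,
#'   `cumulative_variance`, and `retained`.
#' @method tidy pfas_pca
#' @export
tidy.pfas_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$ratios),
    variance_ratio = x$ratios,
    cumulative_variance = cumsum(x$ratios),
    retained = seq_along(x$ratios) <= x$k
  )
}

#' One-row summary of a PCA model
#'
#' @param x A `pfas_pca` object.
#' @param ... Unused.
#' @return A tibble with `n_features`, `k`, `variance_target`,
#'   `cumulative_variance`, `n_structures`.
#' @method glance pfas_pca
#' @export
glance.pfas_pca <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$features),
    k = x$k,
    variance_target = x$variance_target,
    cumulative_variance = sum(x$ratios[seq_len(x$k)]),
    n_structures = nrow(x$scores)
  )
}
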