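# Exact (dense) t-SNE in three dimensions.
#
# Standard formulation: pairwise affinities in the input space from a
# Gaussian kernel whose per-point bandwidth is tuned by bisection to a fixed
# perplexity; a Student-t kernel in the embedding; gradient descent on the
# KL divergence with early exaggeration, momentum, and per-parameter gains.
# O(n^2) memory/time, which is the intended regime for reference sets of a
# few hundred to a few thousand structures.

# bandwidth search: conditional affinities for one row at log-perplexity u
.cond_affinities <- function(d2, u, tol = 1e-5, max_iter = 50) {
  beta <- 1
  beta_min <- -Inf
  beta_max <- Inf
  for (it in seq_len(max_iter)) {
    p <- exp(-d2 * beta)
    sp <- sum(p)
    if (sp == 0) {
      h <- 0
      pr <- p
    } else {
      h <- log(sp) + beta * sum(d2 * p) / sp
      pr <- p / sp
    }
    diff <- h - u
    if (abs(diff) < tol) break
    if (diff > 0) {
      beta_min <- beta
      beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
    } else {
      beta_max <- beta
      beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
    }
  }
  pr
}

.tsne_p_matrix <- function(X, perplexity) {
  n <- nrow(X)
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  P <- matrix(0, n, n)
  u <- log(perplexity)
  for (i in seq_len(n)) {
    P[i, -i] <- .cond_affinities(D2[i, -i], u)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Embed PCA scores with seeded 3D t-SNE
#'
#' @param scores PCA scores: a matrix, a tibble from [predict.pfas_pca()], or
#'   a `pfas_pca` object (its training scores are used).
#' @param perplexity Neighborhood-entropy parameter (default 50); must be
#'   smaller than the number of points.
#' @param steps Number of gradient-descent iterations (default 1000,
#'   minimum 250).
#' @param seed Integer seed for the random initialization; identical seed,
#'   input and configuration give identical coordinates.
#' @param output_dims Embedding dimensionality (default 3).
#' @return A `pfas_tsne` object whose `coordinates` tibble holds
#'   `tsne_pca_1..3` (finite), `provenance = "reference"`, and
#'   `canonical_smiles` when the scores carried keys.
#' @export
fit_pfas_tsne <- function(scores, perplexity = 50, steps = 1000L, seed = 0L,
                          output_dims = 3L) {
  keys <- NULL
  if (inherits(scores, "pfas_pca")) {
    keys <- scores$row_keys
    scores <- scores$scores
  } else if (is.data.frame(scores)) {
    if ("canonical_smiles" %in% names(scores)) keys <- scores$canonical_smiles
    scores <- as.matrix(scores[, setdiff(names(scores), "canonical_smiles"), drop = FALSE])
  }
  X <- as.matrix(scores)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (perplexity <= 0) stop("perplexity must be positive")
  if (n <= perplexity) {
    stop("too_few_points: need more points than the perplexity (", n,
      " points, perplexity ", perplexity, ")")
  }
  if (steps < 250) stop("steps must be at least 250")

  P <- .tsne_p_matrix(X, perplexity)
  exag_iters <- min(250L, as.integer(steps) %/% 2L)
  eta <- 200
  Y <- withr::with_seed(seed, matrix(stats::rnorm(n * output_dims, sd = 1e-4), n, output_dims))
  inc <- matrix(0, n, output_dims)
  gains <- matrix(1, n, output_dims)
  Q <- NULL

  for (iter in seq_len(steps)) {
    sq <- rowSums(Y^2)
    num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    Pe <- if (iter <= exag_iters) 12 * P else P
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (iter <= 250) 0.5 else 0.8
    same <- sign(grad) == sign(inc)
    gains <- pmax((gains + 0.2) * !same + gains * 0.8 * same, 0.01)
    inc <- momentum * inc - eta * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  kl <- sum(P * log(P / Q))

  coords <- tibble::as_tibble(Y, .name_repair = ~ paste0("tsne_pca_", seq_len(output_dims)))
  coords$provenance <- "reference"
  if (!is.null(keys)) {
    coords <- dplyr::bind_cols(tibble::tibble(canonical_smiles = keys), coords)
  }
  structure(
    list(
      coordinates = coords,
      config = list(
        perplexity = perplexity, steps = as.integer(steps), seed = as.integer(seed),
        output_dims = as.integer(output_dims), learning_rate = eta,
        early_exaggeration = 12, exaggeration_iters = exag_iters
      ),
      kl_divergence = kl,
      n = n
    ),
    class = "pfas_tsne"
  )
}

#' @export
print.pfas_tsne <- function(x, ...) {
  cat(
    "<pfas_tsne> ", x$n, " points in ", x$config$output_dims,
    "D (perplexity ", x$config$perplexity, ", steps ", x$config$steps,
    ", seed ", x$config$seed, "); final KL ", sprintf("%.4f", x$kl_divergence),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Coordinates of a t-SNE embedding
#'
#' @param x A `pfas_tsne` object.
#' @param ... Unused.
#' @return The coordinate tibble (one row per structure).
#' @method tidy pfas_tsne
#' @export
tidy.pfas_tsne <- function(x, ...) {
  x$coordinates
}

#' One-row summary of a t-SNE embedding
#'
#' @param x A `pfas_tsne` object.
#' @param ... Unused.
#' @return A tibble with `n`, `perplexity`, `steps`, `seed`, `kl_divergence`.
#' @method glance pfas_tsne
#' @export
glance.pfas_tsne <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    perplexity = x$config$perplexity,
    steps = x$config$steps,
    seed = x$config$seed,
    kl_divergence = x$kl_divergence
  )
}

#' Place user compounds on a trained reference embedding
#'
#' Each user point is placed at the inverse-distance-weighted mean of the
#' t-SNE coordinates of its k nearest reference points, with distances
#' measured in the PCA score space. A user point whose scores coincide with
#' a reference point lands exactly on that point.
#'
#' @param reference Reference embedding: a `pfas_tsne` object or its
#'   coordinate tibble.
#' @param reference_scores PCA scores of the reference points (matrix or
#'   tibble, same row order as the embedding).
#' @param user_scores PCA scores of the compounds to place.
#' @param k_neighbors Number of reference neighbors to interpolate over
#'   (default 10).
#' @return A tibble of user coordinates with `provenance = "user_placed"`.
#' @export
place_user_points <- function(reference, reference_scores, user_scores,
                              k_neighbors = 10L) {
  coords <- if (inherits(reference, "pfas_tsne")) reference$coordinates else reference
  axis_cols <- grep("^tsne_pca_", names(coords), value = TRUE)
  R <- .as_feature_matrix(reference_scores)$X
  up <- .as_feature_matrix(user_scores)
  U <- up$X
  if (nrow(R) == 0) stop("empty_reference: no reference points to place against")
  if (ncol(U) != ncol(R)) {
    stop("schema_mismatch: user scores have ", ncol(U), " columns, reference ", ncol(R))
  }
  k <- min(k_neighbors, nrow(R))
  refY <- as.matrix(coords[, axis_cols, drop = FALSE])

  placed <- t(vapply(seq_len(nrow(U)), function(i) {
    d <- sqrt(rowSums(sweep(R, 2, U[i, ])^2))
    if (any(d == 0)) {
      return(refY[which(d == 0)[1], ])
    }
    nn <- order(d)[seq_len(k)]
    w <- 1 / d[nn]
    w <- w / sum(w)
    colSums(refY[nn, , drop = FALSE] * w)
  }, numeric(length(axis_cols))))

  out <- tibble::as_tibble(placed, .name_repair = ~axis_cols)
  out$provenance <- "user_placed"
  if (!is.null(up$keys)) {
    out <- dplyr::bind_cols(tibble::tibble(canonical_smiles = up$keys), out)
  }
  out
}
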