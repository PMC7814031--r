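test_that("seeded t-SNE is bit-reproducible and produces finite 3D coordinates", {
  set.seed(31)
  X <- matrix(rnorm(120 * 6), 120, 6)
  e1 <- fit_pfas_tsne(X, perplexity = 20, steps = 300, seed = 4)
  e2 <- fit_pfas_tsne(X, perplexity = 20, steps = 300, seed = 4)
  expect_identical(e1$coordinates, e2$coordinates)
  Y <- as.matrix(e1$coordinates[, paste0("tsne_pca_", 1:3)])
  expect_equal(dim(Y), c(120, 3))
  expect_true(all(is.finite(Y)))
  # a different seed gives a different (but equally valid) layout
  e3 <- fit_pfas_tsne(X, perplexity = 20, steps = 300, seed = 5)
  expect_false(identical(e1$coordinates, e3$coordinates))
})

test_that("well-separated blobs stay pure in the embedding", {
  set.seed(42)
  X <- rbind(
    matrix(rnorm(100 * 5), 100, 5),
    matrix(rnorm(100 * 5, mean = 8), 100, 5)
  )
  labels <- rep(c("a", "b"), each = 100)
  e <- fit_pfas_tsne(X, perplexity = 30, steps = 500, seed = 0)
  Y <- as.matrix(e$coordinates[, paste0("tsne_pca_", 1:3)])
  expect_gte(nn_purity(Y, labels), 0.9)
})

test_that("hyperparameter preconditions are enforced", {
  X <- matrix(rnorm(200 * 4), 200, 4)
  expect_error(fit_pfas_tsne(X, perplexity = 300, steps = 300), "too_few_points")
  expect_error(fit_pfas_tsne(X, perplexity = 10, steps = 100), "at least 250")
  expect_error(fit_pfas_tsne(X[1:10, ], perplexity = 0, steps = 300), "positive")
})

test_that("user placement interpolates by inverse distance in score space", {
  ref_scores <- rbind(
    c(0, 0), c(2, 0), c(0, 3), c(4, 4), c(6, 1)
  )
  ref_coords <- tibble::tibble(
    tsne_pca_1 = c(10, 20, 30, 40, 50),
    tsne_pca_2 = c(1, 2, 3, 4, 5),
    tsne_pca_3 = c(-1, -2, -3, -4, -5)
  )
  # a duplicate of a reference point lands exactly on it
  exact <- place_user_points(ref_coords, ref_scores, rbind(c(2, 0)), k_neighbors = 3)
  expect_equal(unlist(exact[1, paste0("tsne_pca_", 1:3)]),
    c(tsne_pca_1 = 20, tsne_pca_2 = 2, tsne_pca_3 = -2))
  expect_equal(exact$provenance, "user_placed")
  # equidistant between two references with k = 2: the midpoint
  mid <- place_user_points(ref_coords, ref_scores, rbind(c(1, 1)), k_neighbors = 2)
  expect_equal(unlist(mid[1, paste0("tsne_pca_", 1:3)]),
    c(tsne_pca_1 = 15, tsne_pca_2 = 1.5, tsne_pca_3 = -1.5))
  expect_error(
    place_user_points(ref_coords[0, ], ref_scores[0, , drop = FALSE], rbind(c(1, 1))),
    "empty_reference"
  )
})

test_that("held-out homologues are placed next to their own subclass", {
  ref <- small_reference()  # chain lengths 6 and 10 held out of the build
  cls <- ref$classification
  held <- dplyr::bind_rows(
    generate_series(pfas_series_spec("PFCAs", held_out_n())),
    generate_series(pfas_series_spec("PFSAs", held_out_n())),
    generate_series(pfas_series_spec("FTOHs", held_out_n())),
    generate_series(pfas_series_spec("FASAs", held_out_n())),
    generate_series(pfas_series_spec("FTIs", held_out_n()))
  )
  placed <- place_compounds(ref, held[, c("id", "smiles")], k_neighbors = 5)
  ref_coords <- ref$tsne$coordinates
  ref_Y <- as.matrix(ref_coords[, paste0("tsne_pca_", 1:3)])
  lab <- cls$subclass
  ok <- 0
  for (i in seq_len(nrow(placed))) {
    d <- sqrt(rowSums(sweep(ref_Y, 2, unlist(placed[i, paste0("tsne_pca_", 1:3)]))^2))
    nn_lab <- lab[which.min(d)]
    if (identical(nn_lab, placed$subclass[i])) ok <- ok + 1
  }
  expect_gte(ok / nrow(placed), 0.8)
})
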