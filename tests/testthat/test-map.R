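# map documents built from a tiny hand-made embedding + classification
tiny_map_inputs <- function() {
  coords <- tibble::tibble(
    id = c("a", "b", "c"),
    tsne_pca_1 = c(0, 1, 2),
    tsne_pca_2 = c(0, 1, 0),
    tsne_pca_3 = c(1, 0, 1),
    provenance = "reference"
  )
  classes <- tibble::tibble(
    id = c("a", "b", "c"),
    canonical_smiles = c("sa", "sb", "sc"),
    category = c("aliphatic_pfas", "aliphatic_pfas", "not_pfas"),
    class = c("PFAAs", "PFAAs", NA),
    subclass = c("PFCAs", "PFSAs", NA),
    n = c(7L, 8L, 0L),
    m = 0L,
    ring_opened = FALSE
  )
  list(coords = coords, classes = classes)
}

test_that("map documents assign deterministic colors and legends per level", {
  inp <- tiny_map_inputs()
  doc <- pfas_map(inp$coords, inp$classes, level = "class")
  expect_s3_class(doc, "pfas_map")
  expect_equal(nrow(doc$points), 3)
  # 2 legend entries at class level (PFAAs + not_pfas fallback)
  expect_length(doc$palette, 2)
  expect_equal(doc$points$color[1], doc$points$color[2])
  expect_false(doc$points$color[1] == doc$points$color[3])
  # byte-identical across runs
  doc2 <- pfas_map(inp$coords, inp$classes, level = "class")
  expect_identical(doc, doc2)
  # subclass level separates the two acids
  doc3 <- pfas_map(inp$coords, inp$classes, level = "subclass")
  expect_length(doc3$palette, 3)
  # hover text carries the id and the classification path
  expect_match(doc$points$hover[1], "a | aliphatic_pfas / PFAAs / PFCAs", fixed = TRUE)
})

test_that("mismatched keys are reported and dropped", {
  inp <- tiny_map_inputs()
  coords <- inp$coords
  coords$id[3] <- "zz"
  expect_warning(doc <- pfas_map(coords, inp$classes), "key_mismatch")
  expect_equal(nrow(doc$points), 2)
})

test_that("property overlay recolors only supplied points and keeps geometry", {
  inp <- tiny_map_inputs()
  doc <- pfas_map(inp$coords, inp$classes)
  # empty table: document geometry unchanged, property registered
  empty <- overlay_property(doc, tibble::tibble(id = character(), value = numeric()),
    "binding")
  expect_equal(empty$points[, 1:7], doc$points[, 1:7])
  expect_equal(empty$property$name, "binding")
  expect_equal(empty$color_mode, "categorical")
  # single-id overlay colors exactly one point
  one <- overlay_property(doc, tibble::tibble(id = "b", value = 5), "binding")
  expect_equal(one$color_mode, "continuous")
  expect_equal(sum(one$points$color != "#BDBDBD"), 1)
  expect_match(one$points$hover[2], "binding=5")
  # scale bounds span the supplied values
  multi <- overlay_property(
    doc,
    tibble::tibble(id = c("a", "c"), value = c(24.7, 91.2)),
    "hit_ratio"
  )
  expect_equal(multi$property$range, c(24.7, 91.2))
  # overlay never mutates coordinates or labels
  expect_equal(multi$points[, c("tsne_pca_1", "tsne_pca_2", "tsne_pca_3")],
    doc$points[, c("tsne_pca_1", "tsne_pca_2", "tsne_pca_3")])
  expect_equal(multi$points$subclass, doc$points$subclass)
})

test_that("fraction strings convert to one-decimal percentages", {
  expect_equal(fraction_to_percent("210/851"), 24.7)
  expect_equal(fraction_to_percent("0/10"), 0.0)
  expect_equal(fraction_to_percent("851/851"), 100.0)
  expect_equal(fraction_to_percent(c("1/3", "2/3")), c(33.3, 66.7))
  expect_error(fraction_to_percent("1/0"), "zero_denominator")
  expect_error(fraction_to_percent("x/y"), "malformed_fraction")
  expect_error(fraction_to_percent("1.5/2"), "malformed_fraction")
  # oracle sweep over a grid of rationals up to 1000
  a <- seq(0, 1000, by = 13)
  b <- seq(1, 1000, by = 17)
  grid <- expand.grid(a = a, b = b)
  got <- fraction_to_percent(paste0(grid$a, "/", grid$b))
  expect_equal(got, round(100 * grid$a / grid$b, 1))
})

test_that("2D projection picks stored axes without touching coordinates", {
  inp <- tiny_map_inputs()
  doc <- pfas_map(inp$coords, inp$classes)
  p23 <- project_2d(doc, c(2, 3))
  expect_equal(p23$view, "2d")
  expect_equal(p23$axes, c(2L, 3L))
  expect_equal(p23$points, doc$points)
  # round trip back to 3D rendering keeps the original coordinates intact
  expect_equal(p23$points[, paste0("tsne_pca_", 1:3)],
    doc$points[, paste0("tsne_pca_", 1:3)])
  expect_error(project_2d(doc, c(1, 1)), "invalid_axes")
  expect_error(project_2d(doc, c(2, 4)), "invalid_axes")
})

test_that("exports write csv, json document model, and standalone html", {
  tmp <- withr::local_tempdir()
  inp <- tiny_map_inputs()
  doc <- overlay_property(
    pfas_map(inp$coords, inp$classes),
    tibble::tibble(id = "a", value = 1), "p"
  )
  write_map_csv(doc, file.path(tmp, "m.csv"))
  write_map_json(doc, file.path(tmp, "m.json"))
  write_map_html(doc, file.path(tmp, "m.html"))
  expect_equal(nrow(utils::read.csv(file.path(tmp, "m.csv"))), 3)
  model <- jsonlite::read_json(file.path(tmp, "m.json"), simplifyVector = TRUE)
  expect_equal(model$level, "class")
  expect_equal(model$property$name, "p")
  expect_equal(length(model$points$id), 3)
  html <- readLines(file.path(tmp, "m.html"))
  expect_true(any(grepl("MODEL", html)))
  expect_true(any(grepl("tsne_pca_1", html)))
})

test_that("autoplot renders both color modes", {
  inp <- tiny_map_inputs()
  doc <- pfas_map(inp$coords, inp$classes)
  p1 <- ggplot2::autoplot(doc)
  expect_s3_class(p1, "ggplot")
  p2 <- ggplot2::autoplot(
    overlay_property(doc, tibble::tibble(id = "a", value = 1), "p")
  )
  expect_s3_class(p2, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p1))
  expect_no_error(ggplot2::ggplot_build(p2))
})
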