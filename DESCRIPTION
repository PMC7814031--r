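Package: pfasmap
Title: Rule-Based Classification and Structure-Function Mapping of PFAS Chemical Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Standardizes SMILES for per- and polyfluoroalkyl substances (PFAS),
    classifies each structure into the Buck/OECD class-subclass hierarchy through a
    deterministic rule cascade (definition filter, derivative subclassing, silicon
    filter, side-chain aromatic filter, carbocycle ring opening, and a core
    class-subclass module), computes molecular descriptor and fingerprint matrices,
    reduces them by principal component analysis to a target explained variance,
    embeds the reduced space with seeded 3D t-SNE, places user compounds on a trained
    reference map, and renders structure-function maps with class colours and
    per-compound property overlays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
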