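# pfasmap

Rule-based classification and structure–function mapping of per- and
polyfluoroalkyl substances (PFAS) in R.

PFAS are compounds carrying at least one fully fluorinated carbon (a terminal
–CF₃ or a chain –CF₂–). Thousands of structurally distinct PFAS are now
registered, but property and toxicity measurements exist for only a small
fraction of them, so environmental chemists lean on *structural taxonomy*
(the Buck classification and its OECD refinements) and on *chemical-space
maps* to transfer knowledge from measured to unmeasured compounds. `pfasmap`
implements that workflow end to end:

1. **SMILES standardization** — salts stripped (largest fragment kept),
   isotope labels removed, ionizable groups neutralized, everything
   canonicalized into one declared SMILES dialect and deduplicated.
2. **Classification** — a deterministic rule cascade: PFAS definition filter
   (≥1 fully fluorinated carbon, near-misses subclassed as PFAS derivatives),
   silicon filter, side-chain fluorinated aromatic filter, carbocycle
   ring opening (one ring C–C bond broken, one F added to each broken-bond
   carbon), then an ordered class–subclass rule table covering PFAAs
   (PFCAs, PFSAs, PFPAs, PFPiAs, PFECAs, PFESAs), FASA-based precursors
   (CₙF₂ₙ₊₁–SO₂N(CₘH₂ₘ₊₁)–R¹), n:2 fluorotelomer-based precursors
   (CₙF₂ₙ₊₁–C₂H₄–R¹), perfluoroalkyl PFAA precursors, and non-PFAA
   perfluoroalkyls. Each result carries the perfluoroalkyl chain length *n*
   (the longest run of fully fluorinated carbons) and the N-alkyl spacer *m*.
3. **Descriptors** — a fixed catalog of constitutional counts, topological
   indices, physicochemical estimates (logP, TPSA, MR, H-bond counts) and a
   1024-bit substructure fingerprint per structure, pruned of features that
   are invalid for more than a configurable fraction of structures.
4. **Embedding** — PCA retaining the smallest number of components reaching a
   cumulative explained-variance target (default 70%), followed by seeded,
   exact 3D t-SNE (default perplexity 50, 1000 steps). The three output axes
   (TSNE-PCA-1/2/3) are the map's coordinate system.
5. **Maps** — user compounds are standardized/classified through the same
   path, projected with the *trained* PCA (never refit) and placed by
   inverse-distance-weighted k-nearest-neighbor interpolation; maps are
   colored by category/class/subclass or by a numeric property overlay
   (e.g. assay hit ratios, binding percentages) and exported as CSV, a JSON
   document model, interactive standalone HTML, or ggplot2 figures.

## Worked example

```r
library(pfasmap)
library(dplyr)

c("OS(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F",
  "OCCC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F",
  "[O-]C(=O)C(F)(F)C(F)(F)C(F)(F)F.[Na+]",
  "O=S(=O)(O)C1(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C1(F)F") |>
  pfas_standardize() |>
  pfas_deduplicate() |>
  pfas_classify() |>
  select(category, class, subclass, n, ring_opened)
#> # A tibble: 4 × 5
#>   category       class                               subclass     n ring_opened
#>   <chr>          <chr>                               <chr>    <int> <lgl>
#> 1 aliphatic_pfas PFAAs                               PFSAs        8 FALSE
#> 2 aliphatic_pfas fluorotelomer_based_PFAA_precursors FTOHs        6 FALSE
#> 3 aliphatic_pfas PFAAs                               PFCAs        3 FALSE
#> 4 aliphatic_pfas PFAAs                               PFSAs        6 TRUE
```

Row 1 is perfluorooctanesulfonic acid (PFOS; chain length n = 8). Row 2 is
the 6:2 fluorotelomer alcohol. Row 3 arrived as a sodium carboxylate salt and
was stripped/neutralized to perfluorobutanoic acid. Row 4 is a cyclic
undecafluorocyclohexanesulfonate: the ring was opened (+2 F) and the acyclic
product classified as a perfluoroalkane sulfonic acid with n = 6.

Building a map from a reference set and overlaying an activity table:

```r
corpus <- generate_corpus(seed = 0)              # synthetic, ground-truthed
ref    <- build_reference(corpus[, c("id", "smiles")], seed = 0)
doc    <- pfas_map(ref$tsne, ref$classification, level = "class")
doc    <- overlay_property(doc,
            tibble::tibble(id = "PFCAs_n10_m0", value = fraction_to_percent("210/851")),
            property_name = "hit_ratio_percent")
autoplot(project_2d(doc, c(2, 3)))               # 2D projection, TSNE-PCA-2/3
write_map_html(doc, "pfas_map.html")             # interactive standalone page
```

`fraction_to_percent("210/851")` prints `24.7` — assay hit ratios supplied as
fractions are converted to one-decimal percentages before overlay.

A thin command-line wrapper over the same functions ships in
`inst/cli/pfasmap` (`standardize`, `classify`, `build-reference`, `place`,
`map` subcommands).

## Scope notes

The published EPA-list figures (7,866 master-list entries → 6,134 distinct
structures; 2,090 PaDEL descriptors → 74 components at 70% variance) depend
on a dated snapshot of the US EPA PFAS Master List and on the PaDEL
descriptor schema; they are documented in the methods vignette but are not
recomputed here. The packaged synthetic homologous-series corpus stands in
for the reference set so that everything builds and tests offline.
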