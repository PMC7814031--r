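---
title: "Methods: rule-based PFAS classification and structure-function maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based PFAS classification and structure-function maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfasmap)
```

## The problem

Per- and polyfluoroalkyl substances (PFAS) are molecules with at least one
fully fluorinated carbon — a terminal –CF₃ or a chain –CF₂– group. The family
has grown to thousands of registered structures while measured properties
(bioactivity, binding, bond strengths) exist for only a few dozen compounds.
Two tools let chemists reason about the unmeasured majority: a *structural
taxonomy* (Buck's class/subclass system and the OECD's refinements, which
group compounds by head group and perfluoroalkyl chain) and an *unsupervised
chemical-space map*, in which each structure is a point in a low-dimensional
embedding of a high-dimensional descriptor space and measured properties are
overlaid as colors. Compounds that sit together on such a map tend to share
structure, and — to the extent that the structure–function relationship is
smooth — function.

`pfasmap` implements both: a deterministic classification cascade and a
PCA + 3D t-SNE embedding pipeline, joined by a map-document layer for
rendering and property overlay.

## Standardization

One molecule has many valid SMILES; different databases print different
canonical forms of even so central a compound as perfluorooctanesulfonic
acid (PFOS). All comparisons in this package therefore go through a single
declared canonicalization routine — OpenBabel canonical SMILES, reached via
`canonicalize_smiles()` — and every pipeline input passes through
`pfas_standardize()` first:

* **Salt stripping.** Multi-fragment inputs keep the fragment with the most
  heavy atoms; ties break by molecular weight, then by lexicographically
  smallest canonical SMILES. Deterministic, and sufficient for the common
  Na⁺/K⁺/NH₄⁺ counter-ion cases.
* **Isotope removal.** Isotope labels are dropped before parsing; explicit
  deuterium folds back into implicit hydrogens.
* **Neutralization.** Anionic O/N/S centers are protonated and protonated
  amines deprotonated, *except* atoms adjacent to an oppositely charged
  neighbor (nitro and other charge-separated groups are left intact).
  Permanent cations (quaternary ammonium) cannot be neutralized by a
  protonation change; they are kept and flagged `uncorrectable_charge`.
* **Validation.** OpenBabel silently repairs some malformed SMILES, so a
  syntactic check (balanced brackets/parentheses, paired ring-closure
  digits, legal characters) runs first; bad records are reported with reason
  `invalid_smiles` and never abort a batch.

Standardization is idempotent (re-standardizing a canonical SMILES is a
no-op), and `pfas_deduplicate()` collapses records by canonical SMILES while
preserving first-occurrence order — both properties are asserted in the test
suite.

## The classification cascade

`pfas_classify()` applies five stages in a fixed order; every parseable
structure receives exactly one result.

1. **Definition filter.** A terminal CF₃ is an sp³, hydrogen-free carbon
   bearing ≥3 fluorines; a chain CF₂ is an sp³, hydrogen-free carbon bearing
   exactly 2 fluorines with both remaining bonds to carbon. Requiring the
   carbon to be H-free keeps "fully fluorinated" literal: CHF₂/CHF carbons
   never qualify, and (a deliberate edge ruling) neither does fluoroform.
   This guarantees every aliphatic PFAS has chain length n ≥ 1.
2. **Derivative subclassing.** Structures that miss the definition are
   tested, in order, for: F replaced by Cl/Br on an otherwise perfluorinated
   carbon; a fluorinated C=C or C=O carbon (aromatic bonds excluded — the
   connection table is kekulized, so aromatic atoms are checked separately);
   a fluorinated aromatic carbon. Matches are `pfas_derivative` with the
   matching subclass; otherwise `not_pfas`. Derivatives deliberately carry a
   subclass but no class label: the taxonomy's class level only applies to
   aliphatic PFAS.
3. **Silicon filter.** Any Si atom → `silicon_pfas`; no further subclassing
   (no published rule set exists for organosilicon PFAS).
4. **Side-chain aromatic filter.** A structure that passed the definition
   filter and contains an aromatic ring is a side-chain fluorinated
   aromatic: its fully fluorinated carbons are sp³, hence necessarily on an
   aliphatic side chain. This filter precedes ring opening, so aromatic
   rings are never opened.
5. **Ring opening.** Every all-carbon, non-aromatic ring is opened: one ring
   C–C single bond is deleted and one fluorine added to each of the two
   carbons of the broken bond, preserving carbons and adding exactly 2 F per
   ring. The bond broken is chosen so the highest-priority exocyclic
   substituent (acid anchor > other heteroatom > carbon > fluorine-only)
   ends at a chain terminus, with index order as the deterministic
   tie-break; fused systems are opened iteratively until acyclic.
   Heteroatom-containing rings (cyclic ethers) are left intact and flagged —
   the opening rule is defined for carbons only.
6. **Core class–subclass rules.** The acyclic aliphatic structure is matched
   against the ordered rule table shipped in
   `system.file("extdata", "pfas_ruleset.tsv", package = "pfasmap")` (see
   `pfas_ruleset()`); the first matching subclass wins. Matchers are
   whole-molecule: each recognizes a head-group motif and then requires the
   remainder to be a pure perfluoroalkyl skeleton, which keeps the patterns
   effectively mutually exclusive; precedence still matters and is fixed by
   the table (acid-bearing and ester-bearing telomer/sulfonamide subclasses
   before plain alcohols/amides; FASA-based before fluorotelomer-based;
   PFAAs before non-PFAA perfluoroalkyls). Ether acids (PFECAs/PFESAs) are
   housed under PFAAs, noted as such in the table. Anything unmatched is
   `unclassified_aliphatic` — the rules are total.

**Chain-length convention.** `n` is the number of fully fluorinated carbons
in the longest contiguous run (sp³, H-free, ≥2 F, at most two non-fluorine
neighbors). PFOS is n = 8; perfluorooctanoic acid is n = 7 (the acid carbon
is not fluorinated). This matches the CₙF₂ₙ₊₁ factor in the subclass
patterns and is the same number the synthetic generator records as ground
truth. `m` is the longest saturated N-alkyl substituent on the sulfonamide
nitrogen (0 for the bare amide).

## Descriptors

`pfas_descriptors()` computes a fixed, deterministic catalog per structure:
constitutional counts (element counts including implicit H, aromatic atoms,
rings, bond-order counts, CF₃/CF₂ counts, perfluoro chain length, fraction
of fluorinated carbons, molecular weight), graph-topological indices (Wiener
index, diameter, Zagreb indices, branch/terminal counts, rotatable bonds),
the OpenBabel property block (logP, molar refractivity, TPSA, H-bond
acceptor/donor counts), and a 1024-bit path-based substructure fingerprint
(OpenBabel FP2). The catalog is this package's own; it is *not* a clone of
any third-party descriptor engine — the pipeline needs a rich, deterministic
feature space, not schema parity. Features that cannot be computed for a
structure are `NA` (masked), never silently zeroed; single-atom molecules,
for example, get graph-derived features but no OpenBabel block.

`prune_descriptors()` drops features whose invalid fraction exceeds a
threshold (default 0.1 — the fraction is the tunable, the default is a
deliberately conservative reading of "invalid for a significant number of
structures") and imputes surviving scattered invalids with the column
median, which is robust and deterministic. Pruning decisions depend only on
the set of rows, not their order. The training medians are stored so user
compounds can be aligned to the same schema later.

## Embedding

`fit_pfas_pca()` standardizes features to zero mean/unit variance (their
scales differ by orders of magnitude; zero-variance columns are dropped) and
retains the smallest k whose cumulative explained-variance ratio reaches the
target (default 0.70, expressed as a ratio rather than a fixed component
count because the right k depends on the reference set). The test suite
checks the ratios and the minimal-k property against a brute-force
eigendecomposition of the covariance matrix to 1e-8.

`fit_pfas_tsne()` is an exact O(n²) t-SNE in three dimensions: per-point
Gaussian bandwidths tuned by bisection to the target perplexity (default
50), symmetrized affinities, Student-t kernel in the embedding, and gradient
descent with early exaggeration (factor 12 for the first 250 iterations),
momentum 0.5→0.8, learning rate 200, and van der Maaten-style adaptive
gains. Defaults are perplexity 50 and 1000 steps; the implementation
enforces n > perplexity and steps ≥ 250. Given a seed, input and
configuration, the embedding is bit-reproducible; the exact formulation is
the intended regime for reference sets of a few hundred to a few thousand
structures (cost grows quadratically beyond that).

**Out-of-sample placement.** How a published interactive map places new
compounds without refitting is an open design point; this package resolves
it explicitly: user compounds are projected by the trained PCA and placed at
the inverse-distance-weighted mean of the t-SNE coordinates of their k = 10
(default) nearest reference points, with distances measured in PCA space. A
user compound identical to a reference compound lands exactly on it (the
zero-distance limit), and placed points carry `provenance = "user_placed"`
so reference and user points are never conflated.

## Map documents

`pfas_map()` joins coordinates and classification into a document model:
points with coordinates, the full classification path in hover text, and a
categorical palette fixed by sorted label order (identical inputs give
byte-identical documents). `overlay_property()` switches supplied points to
a linear min–max continuous scale (sequential by default, blue–red diverging
by option — the palette is presentational and configurable), leaves points
without values neutral gray, and never mutates coordinates or labels.
`project_2d()` selects two of the three stored components without
recomputation. Renderers — `autoplot()`, CSV, JSON, and a self-contained
interactive HTML page with a small canvas renderer — are adapters over the
document model, which is what the tests assert on. `fraction_to_percent()`
converts hit-ratio fractions ("210/851") to one-decimal percentages for
overlay.

## The synthetic corpus: what it does and does not show

`generate_corpus()` builds a deterministic, ground-truthed corpus of 268
structures: homologous series (chain lengths 4–10) from structural templates
for all 30 subclasses in the rule catalog, N-alkyl variants for the
sulfonamide family, silicon PFAS, side-chain fluorinated aromatics, four
carbocyclic PFAS, the three derivative patterns, and eleven non-PFAS decoys.
The seed shuffles row order only; content is fixed. Because ground truth is
attached at construction time, the corpus is the classifier's principal
regression suite (`classify(generate(x))` must reproduce the truth exactly)
and the substrate for the embedding checks.

What the corpus emulates: homologous-series structure, head-group diversity,
the full category range, and the preprocessing hazards (salts, isotopes,
charges) via dedicated fixtures. What it does not emulate: the real
registry's composition — its long tail of polymers, complex mixtures,
isomer-level diversity and uneven class sizes. Consequently, passing tests
show the *rules and pipeline* are implemented correctly and that the
embedding separates clean structural families; they do not certify
classification accuracy on arbitrary registry entries, where exotic
structures can fall to `unclassified_aliphatic` by design. Similarly, the
published reference-scale figures (thousands of registry entries reduced to
~6,100 distinct structures; ~2,090 descriptors reduced to 74 components at
70% variance) are snapshot- and descriptor-schema-specific and are not
reproduced by this package's synthetic conditions; on the synthetic corpus
the same 70% target is met by a much smaller k, which the acceptance script
reports as its own quantity.

## Numerical choices and degenerate inputs

* Explained-variance comparisons use a 1e-12 slack when selecting k, so a
  target of exactly 1.0 is reachable despite floating-point summation.
* A descriptor matrix with no varying column is an error
  (`degenerate_matrix`), as is an all-invalid feature set (`empty_matrix`).
* t-SNE ties and symmetric configurations resolve by index order (k-NN
  neighbor selection is `order()`-stable).
* Ring opening breaks only single C–C bonds; a carbocycle with no single
  bond (fully unsaturated) is flagged rather than opened.
* The FASA spacer m and telomer C₂H₄ spacer are matched exactly; other
  spacer lengths fall through to `unclassified_aliphatic` rather than being
  force-fitted into the n:2 taxonomy.

## Known limitations

* The canonical dialect is OpenBabel's; canonical strings are not comparable
  across toolkits (that non-portability is precisely why one dialect is
  declared).
* Stereochemistry and tautomerism are not normalized beyond what
  canonicalization provides; stereoisomers collapse only if the
  canonicalizer collapses them.
* The subclass rule set is reconstructed from the taxonomy's published
  structural patterns; exotic structures (branched spacers, mixed heads,
  phosphonate esters) may receive `unclassified_aliphatic` where a curator
  would assign a subclass. The rule table is shipped as data so such
  refinements can be added without code changes.
* t-SNE geometry is seed-dependent; only neighborhood structure (purity,
  homologous trends), never absolute coordinates, should be interpreted.

## Problem sizes used in the checks

The shipped tests build references from 77-point (perplexity 15, 300 steps)
and 208-point (perplexity 50, 1000 steps) corpora, sizes chosen so the whole
suite exercises every stage — including two full pipeline builds — in about
two minutes on one core; the acceptance script's five-subclass corpus uses
the default perplexity 50 / 1000 steps at n = 208.
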