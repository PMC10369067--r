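---
title: "Building ad hoc disease maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building ad hoc disease maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapforge)
```

`mapforge` assembles a prototype molecular disease map for a rare disease
from file-backed knowledge sources: association tables, pathway diagram
collections and interaction tables. This vignette describes the procedure,
its assumptions, the parameters that matter, the numerical choices, and
what the synthetic test worlds do and do not demonstrate.

## The procedure

The pipeline runs in three stages.

**Stage 1 — disease context.** The disease is identified by Orphanet ids,
or by HPO phenotype terms resolved against a phenotype-annotation table.
Phenotype matching scores each annotated disease by the Jaccard similarity
between the query HPO set and the disease's annotation set. Jaccard was
chosen because it is symmetric, threshold-free and trivially checkable by
hand; diseases sharing no term are excluded rather than ranked last, and
ties break on ascending Orphanet id so results are reproducible.

Gene and variant associations are then consolidated per source:

* *Orphanet* gene–disease rows are authoritative and always kept.
* *DisGeNET*- and *OpenTargets*-style rows carry platform scores; rows at
  or above the per-source threshold are kept and each source is truncated
  to the configured maximum by descending score (ties on symbol).
  OpenTargets rows are reached through a required ORPHA→EFO mapping table;
  unmapped ids are skipped with a warning rather than failing the run.
* *ClinVar*-style rows contribute only pathogenic and likely-pathogenic
  variants. Separately, every variant another source supports but ClinVar
  classifies benign or likely benign is **flagged** in the discrepancy
  report rather than deleted — the evidence conflict is surfaced, and the
  decision is left to the curator.

Variants are filtered for rarity by population allele frequency: a variant
is removed when its *maximum* frequency over the configured populations
reaches the threshold (a conservative rarity claim — one common population
suffices for removal). Variants absent from the frequency panel are
**kept**: rare-disease variants are often missing from population panels,
and dropping them would defeat the workflow's purpose. Finally the gene
list is augmented with the genes carrying the surviving variants (appended
alphabetically after the association-derived genes, whose order is
preserved).

**Stage 2 — network of mechanisms.** Three component groups are collected.
Disease-map "areas" and pathway diagrams are modelled as gene sets with an
attached diagram file, a layout flag and optional parent links; enrichment
is hypergeometric over-representation (the input gene list is unranked, so
an ORA is the appropriate test; no permutation GSEA is attempted). The
universe defaults to all genes appearing in a collection's sets; query
genes outside it are dropped with a warning. Benjamini–Hochberg adjustment
is computed over all sets of the collection, but ranking and truncation use
the raw p-value with a deterministic set-id tie-break — the only stated
result control is a per-collection maximum count, so no p-value cutoff is
applied. Reactome results are narrowed to diagrams with stored layout, and
when both an ancestor and a descendant are enriched only the topmost
ancestor present is kept (the filtered results form an antichain in the
nesting order).

The text-mining component starts from a scored undirected edge table
(STRING 0–1000 convention). Candidate neighbors are non-seed genes linked
to at least one seed at or above the minimum combined score, ranked by
their best such score and truncated globally to the configured maximum —
a per-seed quota was rejected as less deterministic and harder to reason
about. Directionality comes from a curated directed/signed edge table; only
edges with *both* endpoints in the text-mining node set survive. Nodes left
without a surviving directed edge are kept as unconnected DataNodes: they
were selected by the evidence and their absence from the curated table is
itself informative.

**Stage 3 — assembly and overlays.** All diagrams are converted into one
glyph-and-arc model (coordinates in pixels, top-left origin, y downward —
the convention of the richest source dialect) and merged on a mesh grid:
components are placed row-major on a near-square grid
(`columns = ceiling(sqrt(m))`), each cell sized to its component plus a
margin, so internal layouts are preserved exactly and component bounding
boxes never overlap. No cross-component deduplication is performed: a gene
appearing in two source diagrams remains two glyphs, consistent with
preserving source layouts, and overlays highlight all copies. The merged
map is written as CellDesigner SBML and bundled with the gene, variant and
expression overlays into a ZIP archive.

## Format conversions and loss reporting

Supported dialects: GPML 2013a (WikiPathways), SBML Level 3 with the layout
(and optional render) packages (Reactome exports), and CellDesigner-extended
SBML Level 2 Version 4 as the harmonization target. Level 2 Version 4 is an
assumption — the target platform accepts several CellDesigner levels — and
is isolated in the writer.

Conversions are lossy by nature and never lose features silently: every
dropped feature lands in a `ConversionReport`. Specifically, GPML
interactions without a resolvable reactant/product endpoint, free labels,
shapes and embedded images are dropped and recorded; GPML `Group`s of
DataNodes become complex glyphs (one nesting level; deeper structures are
flattened with a warning); unmapped DataNode types map to `unknown` with a
warning. For SBML, species without a layout glyph are recorded as dropped,
and render styles are counted and ignored — the CellDesigner target carries
its own styling. SBML species map to glyph classes through their SBO term;
species without one become `unknown`.

The round-trip contract — GPML → model → CellDesigner SBML → model
preserves glyph and arc counts, labels, classes and coordinates within
0.5 px — is enforced on generated fixtures in the test suite.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `disgenet_min_score`, `opentargets_min_score` | 0.3 | per-source association score floor (0–1) |
| `disgenet_max_genes` | 100 | per-source cap on score-ranked genes |
| `vep_af_threshold` | 0.01 | max population AF before a variant is removed |
| `populations` | all in table | populations considered by the AF filter |
| `max_disease_map_diagrams` | 3 | disease-map areas retained |
| `max_pathways_per_collection` | 5 | pathway diagrams retained per database |
| `string_min_score` | 700 | minimum combined score (0–1000) |
| `string_max_new_neighbors` | 100 | neighbor expansion cap |
| `layout_iterations`, `layout_seed` | 100, 42 | force-layout schedule and seed |
| `margin` | 20 px | mesh-grid spacing |

The defaults for the retained-diagram counts and the neighbor cap (3, 5,
100) mirror a deliberately constrained map build: larger values quickly
produce overgrown, hard-to-read maps. One source configuration note: where
a source's description of the score parameter is ambiguous between a
minimum and a maximum, it is implemented as a **minimum** retained score,
matching STRING semantics.

## Numerical choices

* `ora_p_value` delegates to `stats::phyper` (upper tail); the test suite
  checks it against exhaustive enumeration of all draws for every universe
  up to size 12. `adjust_bh` delegates to `stats::p.adjust`.
* The Fruchterman–Reingold layout follows the classic 1991 formulation
  with C = 1: ideal length `k = sqrt(area/|V|)`, pairwise repulsion
  `k^2/d`, attraction `d^2/k` along edges, displacement capped by a
  temperature cooled linearly to zero, positions clamped to the area.
  Initial positions come from a seeded uniform stream and the caller's RNG
  state is restored, so identical inputs and seed give bitwise-identical
  coordinates. Degenerate distances are floored at 1e-9 to avoid division
  by zero; a single node feels no force and keeps its initial position.
* DEG filtering uses strict inequalities (`FDR < 0.05`,
  `2^|log2FC| > 2`): rows exactly at either boundary are excluded. The
  fold-change bound is interpreted on the linear scale; a documented
  `log_scale` toggle provides the strict-log reading. Log fold changes are
  normalized by the maximum absolute value (not clipped at ±1): clipping
  would erase relative magnitude among large effects, which is the signal
  the expression overlay is meant to show.
* The overlay bundle is written with a stored (uncompressed) ZIP encoder
  with a constant timestamp, so identical content yields identical bytes —
  this is what makes whole-pipeline determinism checkable by hashing.
* Ties are broken deterministically everywhere (score ties by symbol,
  p-value ties by set id, equal-score neighbors by symbol), so no result
  depends on input row order.

## The synthetic worlds

`fixture_spec()` / `gen_world()` generate every input the pipeline
consumes, with planted ground truth: disease genes whose scores clear the
default thresholds while decoys sit far below; rare, common and
benign-conflict variants with the matching allele-frequency rows; pathway
collections in which planted sets contain at least 80% disease genes and
decoy sets at most one, making enrichment recovery exact rather than
statistical; an interaction table in which the disease genes form a
high-score module with planted directed edges (distractor directed edges
touch symbols absent from the scored table, so the refined edge set is
predictable independent of neighbor selection); and a DEG table with known
survivors including exact-boundary rows. All randomness flows from a single
seed and the generator restores the caller's RNG state; the same spec
yields byte-identical files.

The worlds emulate schemas and separable signals, **not** biology: gene
symbols are synthetic, scores are uniform draws, diagrams are grid chains.
Passing the recovery tests demonstrates that the pipeline's filters,
thresholds, rankings and conversions behave exactly as specified under
separable conditions — it says nothing about recall on real databases,
where signal and noise overlap and association evidence is far messier.
Real-data results also depend on database versions, which is why published
headline counts for specific diseases are not reproduction targets.

The packaged table `inst/extdata/ORPHA791_DEGs_synthetic.tsv` is a
*synthetic stand-in* for a retinitis pigmentosa organoid
differential-expression export (the original accompanies its study's
repository): 800 edgeR-style rows constructed so that the standard filter
retains exactly 371, including boundary rows the strict inequalities must
exclude. It exercises the filter and the expression overlay end to end
without shipping third-party data.

## Test problem sizes

The suite runs the enumeration oracle over all universes up to N = 12
(~3,000 cases), twenty random diagrams through the format round trip, ten
seeded worlds through planted-signal recovery, and two full pipeline runs
for the determinism check; these sizes keep the whole suite under a minute
while covering every code path the properties constrain.

## Known limitations

* CellDesigner state variables, residues and tags are out of scope; SBGN-ML
  and image export are not supported.
* Complex nesting is capped at one level; deeper structures are flattened.
* The merged map is a patchwork of source styles by design — style
  harmonization is left to downstream editors.
* Live database clients are out of scope: all sources are file-backed
  behind documented TSV/GMT schemas, so adapters for web APIs can be added
  without touching the pipeline.
* "Unique elements" in map statistics counts post-merge glyphs
  (compartments excluded); since components are not deduplicated, a gene
  shared between two source diagrams counts twice.
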