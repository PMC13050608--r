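---
title: "Composable views of cell-type populations"
author: "scPopViz"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composable views of cell-type populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scPopViz)
```

## The problem

Cell population plots summarize how the cells of each biological sample
distribute over annotated cell types. The classical encoding is a stacked
bar chart — one bar per sample, one colored segment per cell type. That
encoding degrades quickly as atlases grow: only the bottom segment of each
bar shares a baseline, so most comparisons are length judgements between
shifted, separated segments; dozens of cell types exhaust any usable
qualitative color palette; and absent cell types (zero cells in a sample)
are simply invisible. Modern multi-sample atlases routinely annotate 30-50
cell types across hundreds of samples, which is exactly the regime where
stacked bars fail.

scPopViz implements an alternative, matrix-centered view as a scriptable
library: the central object is the sample-by-cell-type count matrix, the
display is a heatmap with aligned marginal panels, any row can be expanded
into a within-sample bar chart, and the traditional stacked bar chart
remains available as a one-call preset. Every view is a deterministic
function of (data, configuration), so figures are reproducible and
testable down to the byte.

## Data model

Let $c_{st}$ be the number of cells of type $t$ in sample $s$. The
`PopulationMatrix` stores the dense matrix $C = (c_{st})$ together with a
`valueKind` tag (counts, fractions, or their logs) and an orientation flag
(which axis currently holds samples). A `CellPopDataset` bundles the
matrix with per-sample and per-cell-type metadata tables (keyed
`DataFrame`s) and an optional `CellTypeHierarchy` — a forest mapping
fine-grained annotations to coarser ancestors (e.g. CD4+ T cell → T cell →
lymphocyte).

Two modelling choices are worth making explicit:

* **Label order is data, display order is view state.** Construction
  (`buildPopulationMatrix`) fixes first-appearance order; only `sortBy`
  changes order afterwards. This keeps object identity independent of how
  a figure happens to be sorted.
* **Absence is a zero, not a missing value.** The matrix holds a single
  number per (sample, type) pair; absence surfaces through
  `presenceStats()` and through a dedicated glyph in the rendered heatmap,
  not through a parallel missingness structure. Cells with an empty or
  missing type label are kept under the reserved label `"unknown"` (and
  counted in a load report) rather than silently dropped — real atlases
  publish "unknown" as a first-class annotation.

## The transform algebra

All views are compositions of seven transforms over a `CellPopDataset`:

| transform | effect |
|---|---|
| `filterBy` | keep/drop entities by categorical values or a numeric range |
| `groupBy` | sum counts over a categorical metadata field |
| `collapseToDepth` | replace each cell type by its ontology ancestor at a depth |
| `normalize` | counts → within-sample or within-cell-type fractions |
| `logTransform` | $v \mapsto \log_b(v + \varepsilon)$ |
| `sortBy` | stable multi-key reorder of rows/columns |
| `transposeView` | swap the sample and cell-type axes |

`applyView()` composes them in a *fixed* order — filter → group/collapse →
normalize → log → sort → transpose. The order is not negotiable at the
configuration level because some compositions are statistically wrong:
summing within-sample fractions across samples does not yield the fraction
of the pooled counts, so aggregation (grouping, hierarchy collapse) must
precede normalization. `groupBy` and `collapseToDepth` therefore refuse
non-count input, and `normalize` refuses to re-normalize. Integer count
aggregation is exact, so both aggregations conserve the grand total
exactly, which the test suite asserts without tolerance.

Normalization offers two denominators because they answer different
questions: within-sample fractions $f_{st} = c_{st} / \sum_{t'} c_{st'}$
(the quantity classical stacked bars show; what is this sample made of?)
and within-cell-type fractions $g_{st} = c_{st} / \sum_{s'} c_{s't}$
(which samples contribute this cell type?). Samples or types with zero
total stay all-zero rather than producing NaNs.

The log transform defaults to base 10 with pseudocount 1, so a zero count
maps to exactly 0 and stays at the floor of the color scale. A
pseudocount other than 1 shifts that floor; the renderer's absent-cell
test (`value == 0`) is calibrated to the default and is documented as such
below.

Sorting details that matter for reproducibility: keys are applied as one
stable lexicographic multi-key sort per axis with the original order as
final tiebreaker; entities with missing metadata sort last regardless of
direction (so a descending age sort does not promote unknown ages); the
`hierarchy` sort kind orders cell types by a depth-first traversal of the
ontology with roots and siblings alphabetical in C-locale collation
(locale-independent output). The `total_count` kind sorts by the current
matrix's row/column sums; after normalization those sums are degenerate
(all 1), in which case the stable sort leaves the order unchanged — sort
before normalizing if count totals are the intended key (the default
pipeline order does exactly this for the default view's use case of raw
counts).

`groupBy` needed one decision the interface leaves open: which axis a
configured `group_field` refers to. The package defaults to the sample
axis (`groupAxis = "rows"`), since grouping samples by disease or organ is
the canonical use, but the column axis works symmetrically. Entities with
missing values in the grouping field form an explicit `"(missing)"`
category rather than disappearing. Grouping the cell-type axis detaches
the hierarchy (categories are not ontology nodes); collapsing via the
hierarchy keeps it.

## The figure model

`layoutFigure()` maps a view-applied dataset to a `FigureModel`: a list of
panels (column sidebar, column axis, heatmap, expanded rows, row axis, row
sidebar, legend), each with a rectangle in abstract coordinates (origin
top-left, y downward, one heatmap cell = 18 units) and a data.frame of
marks. The model, not the file, is the tested artifact: mark completeness
(one mark per matrix cell), expanded-bar/column-center alignment, and
stacked-segment conservation are all asserted on coordinates and values in
the model, and exporters are thin, deterministic serializers.

Numerical/encoding choices:

* **Heatmap color** is a linear map from the (possibly log-transformed)
  value range onto a 256-step continuous palette
  (`grDevices::hcl.colors`, default Viridis), making color a monotone step
  function of value. Zero cells are drawn as a distinct hollow glyph
  instead of the lowest ramp color, so absence reads as absence rather
  than as "very small".
* **Categorical colors** for bars and stacked segments come from a
  qualitative palette (`grDevices::palette.colors`, default Okabe-Ito)
  cycled in label order; user overrides always win.
* **Violins** use a kernel density with Scott's-rule bandwidth
  (`bw.nrd`, falling back to `bw.nrd0` when Scott's rule degenerates),
  evaluated on 48 points and clipped to the observed data range. Inputs
  with fewer than two distinct values draw a flat sliver. Each violin
  mark also carries the min/median/max of its values so the distribution
  summary is machine-checkable.
* **Stacked bars** store the raw value on every segment; per-bar segment
  sums therefore equal the entity total (count mode) or 1 (fraction mode)
  exactly, and bar lengths are scaled by the maximum entity total so bars
  remain comparable.
* **Export.** SVG elements carry stable ids `panel/kind/row/col` (with
  `/` in labels percent-escaped), numbers are formatted with two fixed
  decimals, and no timestamps are written, so repeated export of one
  model is byte-identical. PNG is rasterized from the same model at
  `dpi/96` scale on a cairo bitmap device. Interactive zooming of the
  original viewer is out of scope; its effect is reproduced by filtering
  to label ranges in the configuration.

`stackedBarPreset()` encodes the classical population plot: transpose (so
samples become columns), hide the heatmap, normalize within sample, and
draw one vertical stacked bar per sample in the column side panel. The
test suite asserts the preset's segment values equal
`normalize(ds, "within_sample")` entry by entry.

## View configurations

A `ViewConfig` captures everything needed to reproduce a figure and
round-trips through versioned JSON (`schema_version: 1`). Reading `{}`
yields the documented default view (counts heatmap, total-count bar
sidebars, rows sorted by total count descending); unknown keys are
rejected with their JSON path rather than ignored, so typos fail loudly.
The writer emits canonical JSON (fixed key order, all keys present),
making `write(read(x))` a fixed point — convenient for diffing view
provenance. The CLI (`exec/scpopviz`) exposes the same pipeline with
precedence defaults < config file < flags, and writes a JSON manifest
(inputs, config hash, package version) next to every output.

## AnnData ingestion

Population plots need per-cell annotations, never expression, so only the
AnnData observation table is read; `X` is never touched, which keeps
`.h5ad` and zarr stores cheap to open at atlas scale. The format work is
delegated to the reference AnnData implementation through a bridged
helper process shipped with the package (`inst/python/anndata_bridge.py`);
only a CSV of the obs table crosses the bridge. Per-sample metadata is
lifted from obs columns by first value per sample; a column that is not
constant within a sample is dropped with a warning, since it is not
sample-level metadata. The hierarchy is supplied as an explicit
child,parent edge list rather than inferred from ontology-ID obs columns —
annotation practice varies too much across atlases for an implicit
convention to be safe.

## The synthetic generator

`generateAtlas()` provides seed-reproducible atlases with exact ground
truth so every module is testable without downloads. Per sample it draws
a composition from a symmetric Dirichlet($\alpha$), forces each
(sample, type) pair absent with probability `absent_fraction` (guarding
at least one present type per sample) and renormalizes, draws the
sample's total from a log-normal, then allocates cells by giving every
present type one cell and distributing the remainder multinomially.
Multinomial allocation (rather than independent Poissons) makes
per-sample totals exact; the one-cell floor makes absence purely
structural, so presence statistics recover the forced-absent set exactly
instead of being confounded by sampling zeros. One seeded RNG stream is
consumed in a fixed per-sample order (rather than deriving a sub-seed per
sample), which is equally deterministic and avoids manufacturing 32-bit
seed collisions; the caller's RNG state is saved and restored.

Defaults describe a desk-scale atlas: 24 samples, 12 cell types in a
depth-2 ontology, Dirichlet concentration 2 (visibly heterogeneous but
not degenerate compositions), log-normal totals with median 2000 cells
and log-sd 0.5, 15% forced-absent pairs, and disease/age metadata. These
are one-time choices meant to be plausible for public multi-organ
RNA-seq atlases, not fits to any particular dataset.

What the generator does *not* emulate — and therefore what passing tests
do not demonstrate about real data: expression values and annotation
noise (labels are taken as given), batch effects, correlated compositions
between related samples, unbalanced ontologies with mixed annotation
depth, and atlas-scale cardinalities (hundreds of samples, millions of
cells). The transforms are dimension-agnostic dense-matrix operations, so
scale affects time, not correctness; the test suite runs them on matrices
up to ~10 samples × 9 types and tables of ~10^3–10^4 cells, and the
property suites repeat each invariant over 200 seeded instances.

## Known limitations

* The absent-cell glyph keys on a rendered value of exactly 0, which
  coincides with a raw zero count only for the default pseudocount of 1;
  with other pseudocounts zero counts land at $\log_b \varepsilon$ and
  are drawn as (minimum-color) cells instead.
* Cross-atlas harmonization of cell-type vocabularies is out of scope:
  `collapseToDepth` aggregates within one ontology, but mapping labels
  between differently-annotated datasets is a curation problem this
  package does not attempt.
* Delimited readers use a minimal dialect (no quoting); labels must not
  contain the delimiter.
* Composition-difference inference (scCODA-style models) is deliberately
  absent — this is a visualization and bookkeeping package, not a test.
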