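# scPopViz

Scalable, scriptable cell population plots for single-cell data.

## What it is for

Given per-cell annotations (each cell's sample and cell-type label),
scPopViz builds the sample-by-cell-type count matrix
*C = (c<sub>st</sub>)*, transforms it with a reproducible view algebra,
and renders a composite figure designed to stay readable where the
traditional stacked bar chart breaks down (many samples, many cell types,
absent types):

- a central **heatmap** (samples × cell types) for overall trends, with
  zero counts drawn as a distinct *absent* glyph;
- any heatmap row expandable into an inline **bar chart** for
  within-sample comparison;
- **aligned side panels** — bars, stacked bars, or violins — showing
  totals and marginal distributions;
- the classical **stacked bar chart** available as a one-call preset
  (transpose, hide the heatmap, stacked bars in the side panel,
  within-sample normalization).

Transforms: normalization to within-sample fractions
*f<sub>st</sub> = c<sub>st</sub> / Σ<sub>t′</sub> c<sub>st′</sub>* or
within-cell-type fractions
*g<sub>st</sub> = c<sub>st</sub> / Σ<sub>s′</sub> c<sub>s′t</sub>*;
log transform log<sub>b</sub>(v + ε); stable multi-key sorting (counts,
alphabetical, metadata, cell-ontology order); metadata filtering and
grouping; aggregation of cell types to any depth of a cell-ontology
hierarchy; transposition. A fixed pipeline order
(filter → group/collapse → normalize → log → sort → transpose) keeps
views reproducible and statistically sound.

Inputs: AnnData `.h5ad` files and zarr stores (observation table only),
delimited count matrices, metadata tables, child,parent hierarchy edge
lists, and JSON view configurations. A seed-reproducible synthetic atlas
generator with exact ground truth makes the whole pipeline testable
without downloading data. It is aimed at anyone who currently pastes
stacked-bar "cell composition" panels into atlas papers and wants them
scriptable, reproducible, and honest about absent cell types.

## Worked example

```r
library(scPopViz)

ds <- fixtureF1()          # 2 samples x 2 cell types, hand-checkable
popValues(ds)
#>   T B
#> A 3 1
#> B 0 2

popValues(normalize(ds, "within_sample"))
#>      T    B
#> A 0.75 0.25
#> B 0.00 1.00

presenceStats(ds)
#>   n_samples_present universally_present absent_everywhere
#> T                 1               FALSE             FALSE
#> B                 2                TRUE             FALSE
```

Sample A is 75% T cells and 25% B cells; sample B has no T cells at all —
`presenceStats` reports T present in 1 of 2 samples and B universally
present. Collapsing to ontology depth 0 merges both types into their
common ancestor: `popValues(collapseToDepth(ds, 0))` gives the single
`lymphocyte` column `[4, 2]`.

The same pipeline at atlas scale, on a synthetic atlas:

```r
atlas <- generateAtlas(atlasSpec(seed = 1))
atlas$dataset
#> CellPopDataset: 24 sample(s) x 12 cell type(s) [count]
#>  sample metadata: disease, age
#>  cell-type metadata: lineage
#>  hierarchy: 16 node(s)

cfg <- viewConfig(normalization = "within_sample")
fig <- layoutFigure(applyView(atlas$dataset, cfg), cfg)
fig
#> FigureModel: 6 panel(s), 420 x 652 units [fraction_within_sample]
#>   col_sidebar    col_sidebar    12 mark(s)
#>   col_axis       axis           12 mark(s)
#>   heatmap        heatmap       288 mark(s)
#>   row_axis       axis           24 mark(s)
#>   row_sidebar    row_sidebar    24 mark(s)
#>   legend         legend          7 mark(s)

exportFigure(fig, "atlas.svg")            # byte-stable, addressable marks
exportFigure(fig, "atlas.png", dpi = 300)
```

The heatmap panel carries exactly 24 × 12 = 288 marks, one per
(sample, cell type) pair; every SVG element has a stable id
(`heatmap/cell_rect/s01/ct02`, ...) so figures can be post-processed or
diffed. The traditional plot is one call away:
`p <- stackedBarPreset(); exportFigure(layoutFigure(applyView(atlas$dataset, p), p), "stacked.svg")`.

From the shell (after install, via the script in `exec/`):

```sh
scpopviz simulate --seed 7 --out demo/
scpopviz plot demo/counts.csv --preset stacked-bars --out demo/stacked.svg
scpopviz plot demo/counts.csv --hierarchy demo/hierarchy.csv \
    --collapse-depth 0 --normalize within_sample --out demo/coarse.svg
```

Each run writes a JSON manifest (inputs, config hash, versions) next to
its output.

## Documentation

See the methods vignette (`vignettes/population-views.Rmd`) for the data
model, the transform algebra and its fixed composition order, the figure
model and export determinism, the synthetic generator's assumptions, and
known limitations.
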