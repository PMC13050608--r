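#' @import methods
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame
NULL

.VALUE_KINDS <- c("count", "fraction_within_sample", "fraction_within_celltype",
                  "log_count", "log_fraction")
.ORIENTATIONS <- c("samples_as_rows", "celltypes_as_rows")

#' PopulationMatrix: a sample-by-cell-type value matrix
#'
#' The central data container: a dense numeric matrix whose rows and columns
#' are samples and cell types (in either orientation). `valueKind` records
#' what the entries mean: raw cell counts, within-sample or within-cell-type
#' fractions, or their log transforms. Label order is part of the object and
#' carries the current display order.
#'
#' @slot values numeric matrix; `dimnames` hold the ordered, unique row and
#'   column labels.
#' @slot valueKind one of `"count"`, `"fraction_within_sample"`,
#'   `"fraction_within_celltype"`, `"log_count"`, `"log_fraction"`.
#' @slot orientation `"samples_as_rows"` (default) or `"celltypes_as_rows"`.
#'
#' @seealso [buildPopulationMatrix()], [CellPopDataset-class]
#' @exportClass PopulationMatrix
setClass("PopulationMatrix",
         representation(values = "matrix",
                        valueKind = "character",
                        orientation = "character"))

setValidity("PopulationMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "'values' must be a numeric matrix")
  dn <- dimnames(v)
  if (is.null(dn) || is.null(dn[[1L]]) || is.null(dn[[2L]]))
    msgs <- c(msgs, "'values' must carry row and column labels")
  else {
    if (anyDuplicated(dn[[1L]])) msgs <- c(msgs, "row labels must be unique")
    if (anyDuplicated(dn[[2L]])) msgs <- c(msgs, "column labels must be unique")
    if (any(!nzchar(dn[[1L]])) || any(!nzchar(dn[[2L]])))
      msgs <- c(msgs, "labels must be non-empty strings")
  }
  if (length(object@valueKind) != 1L || !object@valueKind %in% .VALUE_KINDS)
    msgs <- c(msgs, sprintf("valueKind must be one of: %s",
                            paste(.VALUE_KINDS, collapse = ", ")))
  if (length(object@orientation) != 1L ||
      !object@orientation %in% .ORIENTATIONS)
    msgs <- c(msgs, "orientation must be 'samples_as_rows' or 'celltypes_as_rows'")
  if (length(msgs) == 0L && is.numeric(v)) {
    kind <- object@valueKind
    if (kind %in% c("count", "fraction_within_sample",
                    "fraction_within_celltype")) {
      if (any(v < 0)) msgs <- c(msgs, "values must be non-negative")
    }
    if (kind == "count" && any(v != floor(v)))
      msgs <- c(msgs, "count values must be integers")
    if (kind == "fraction_within_sample" && nrow(v) > 0L && ncol(v) > 0L) {
      # the sample axis depends on orientation
      sums <- if (object@orientation == "samples_as_rows") rowSums(v) else colSums(v)
      bad <- abs(sums - 1) > 1e-9 & sums != 0
      if (any(bad))
        msgs <- c(msgs, "within-sample fractions must sum to 1 (or 0) per sample")
    }
    if (kind == "fraction_within_celltype" && nrow(v) > 0L && ncol(v) > 0L) {
      sums <- if (object@orientation == "samples_as_rows") colSums(v) else rowSums(v)
      bad <- abs(sums - 1) > 1e-9 & sums != 0
      if (any(bad))
        msgs <- c(msgs, "within-cell-type fractions must sum to 1 (or 0) per cell type")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' CellTypeHierarchy: a cell-ontology forest
#'
#' A forest over cell-type labels: each node has at most one parent, roots
#' have none. Used to aggregate fine-grained annotations to coarser
#' granularity ([collapseToDepth()]) and to order cell types by a
#' depth-first traversal ([hierarchyOrder()]).
#'
#' @slot nodes character vector of all node labels.
#' @slot parent named character vector mapping child label to parent label;
#'   roots are absent from the mapping.
#'
#' @seealso [cellTypeHierarchy()], [readHierarchyEdges()]
#' @exportClass CellTypeHierarchy
setClass("CellTypeHierarchy",
         representation(nodes = "character", parent = "character"))

setValidity("CellTypeHierarchy", function(object) {
  msgs <- character()
  if (anyDuplicated(object@nodes)) msgs <- c(msgs, "node labels must be unique")
  p <- object@parent
  if (length(p)) {
    if (is.null(names(p)) || any(!nzchar(names(p))))
      msgs <- c(msgs, "'parent' must be named by child labels")
    else {
      if (anyDuplicated(names(p)))
        msgs <- c(msgs, "a node may have at most one parent")
      if (!all(names(p) %in% object@nodes) || !all(p %in% object@nodes))
        msgs <- c(msgs, "parent mapping refers to unknown nodes")
      else {
        # acyclicity: follow each chain; a chain longer than |nodes| is a cycle
        n <- length(object@nodes)
        for (start in names(p)) {
          cur <- start; steps <- 0L
          while (!is.na(p[cur])) {
            cur <- unname(p[cur]); steps <- steps + 1L
            if (steps > n) { msgs <- c(msgs, sprintf(
              "cycle in hierarchy involving '%s'", start)); break }
            if (is.na(match(cur, names(p)))) break
          }
          if (steps > n) break
        }
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

setClassUnion("CellTypeHierarchyOrNULL", c("CellTypeHierarchy", "NULL"))

#' CellPopDataset: population matrix plus metadata and hierarchy
#'
#' Bundles a [PopulationMatrix-class] with sample metadata, cell-type
#' metadata (both `DataFrame`s keyed by row name) and an optional
#' [CellTypeHierarchy-class]. All view transforms
#' ([normalize()][normalize,CellPopDataset-method], [sortBy()],
#' [filterBy()], [groupBy()], [collapseToDepth()], [transposeView()])
#' operate on this class.
#'
#' @slot matrix a [PopulationMatrix-class].
#' @slot sampleMeta `DataFrame` of per-sample metadata; row names are sample
#'   ids and must cover the matrix's sample labels.
#' @slot celltypeMeta `DataFrame` of per-cell-type metadata; row names must
#'   cover the matrix's cell-type labels.
#' @slot hierarchy a [CellTypeHierarchy-class] or `NULL`. When attached it
#'   must contain every matrix cell-type label.
#'
#' @seealso [cellPopDataset()], [fixtureF1()], [generateAtlas()]
#' @exportClass CellPopDataset
setClass("CellPopDataset",
         representation(matrix = "PopulationMatrix",
                        sampleMeta = "DataFrame",
                        celltypeMeta = "DataFrame",
                        hierarchy = "CellTypeHierarchyOrNULL"))

setValidity("CellPopDataset", function(object) {
  msgs <- character()
  sl <- sampleLabels(object@matrix)
  cl <- celltypeLabels(object@matrix)
  if (!all(sl %in% rownames(object@sampleMeta)))
    msgs <- c(msgs, "sampleMeta must cover every sample label of the matrix")
  if (!all(cl %in% rownames(object@celltypeMeta)))
    msgs <- c(msgs, "celltypeMeta must cover every cell-type label of the matrix")
  if (!is.null(object@hierarchy) &&
      !all(cl %in% object@hierarchy@nodes))
    msgs <- c(msgs, "every matrix cell type must be a node of the attached hierarchy")
  if (length(msgs)) msgs else TRUE
})

#' FigureModel: renderer-independent scene graph
#'
#' The deterministic pre-image of an exported figure: a list of panels
#' (heatmap, sidebars, expanded rows, axes, legend), each with a rectangle
#' in abstract layout coordinates (origin top-left, y downward) and a
#' data.frame of marks. Exporters ([exportFigure()]) map this model to SVG
#' or PNG without recomputing anything.
#'
#' @slot panels list of panels; each panel is a list with elements
#'   `panel_id`, `kind`, `rect` (named numeric x, y, w, h) and `marks`
#'   (data.frame with columns id, kind, row, col, value, color, x, y, w, h
#'   and, for violins, list-columns with outline coordinates).
#' @slot meta list of figure-level metadata (value kind, theme, extents).
#'
#' @exportClass FigureModel
setClass("FigureModel",
         representation(panels = "list", meta = "list"))

#' ViewConfig: declarative description of one view
#'
#' Everything needed to reproduce a figure from a dataset: the transform
#' pipeline (filters, grouping or hierarchy collapse, normalization, log
#' transform, sorting, transposition) plus panel, color and export options.
#' Serializes to/from JSON via [readViewConfig()] / [writeViewConfig()].
#'
#' Construct with [viewConfig()]; slot defaults give the package's default
#' view: a counts heatmap with total-count bar sidebars, rows sorted by
#' total count descending.
#'
#' @slot normalization `"none"`, `"within_sample"` or `"within_celltype"`.
#' @slot log apply a log transform after normalization.
#' @slot logBase,pseudocount log-transform parameters.
#' @slot showHeatmap draw the central heatmap.
#' @slot sidePanelRows,sidePanelCols `"bars"`, `"stacked_bars"`, `"violins"`
#'   or `"none"`.
#' @slot expandedRows row labels (post-transform) rendered as inline bar
#'   charts instead of heatmap strips.
#' @slot sortKeys list of [sortKey()] objects, applied as a stable
#'   lexicographic multi-key sort.
#' @slot filters list of [filterSpec()] objects, applied in order.
#' @slot groupField,groupAxis optional metadata grouping (counts only).
#' @slot collapseDepth optional hierarchy collapse depth (`NA` = off).
#' @slot transposed flip samples/cell types between rows and columns.
#' @slot colorOverrides named character vector label -> color.
#' @slot heatmapScheme continuous scheme name for heatmap cells (a
#'   `grDevices::hcl.colors` palette).
#' @slot categoricalScheme qualitative scheme name for bars/segments (a
#'   `grDevices::palette.colors` palette).
#' @slot theme `"light"` or `"dark"`.
#' @slot exportFormat,exportDpi,exportWidth,exportHeight export defaults;
#'   width/height `NA` means "use the layout's natural extent".
#'
#' @exportClass ViewConfig
setClass("ViewConfig",
         representation(normalization = "character",
                        log = "logical",
                        logBase = "numeric",
                        pseudocount = "numeric",
                        showHeatmap = "logical",
                        sidePanelRows = "character",
                        sidePanelCols = "character",
                        expandedRows = "character",
                        sortKeys = "list",
                        filters = "list",
                        groupField = "character",
                        groupAxis = "character",
                        collapseDepth = "numeric",
                        transposed = "logical",
                        colorOverrides = "character",
                        heatmapScheme = "character",
                        categoricalScheme = "character",
                        theme = "character",
                        exportFormat = "character",
                        exportDpi = "numeric",
                        exportWidth = "numeric",
                        exportHeight = "numeric"),
         prototype(normalization = "none",
                   log = FALSE,
                   logBase = 10,
                   pseudocount = 1,
                   showHeatmap = TRUE,
                   sidePanelRows = "bars",
                   sidePanelCols = "bars",
                   expandedRows = character(),
                   sortKeys = list(),
                   filters = list(),
                   groupField = character(),
                   groupAxis = "rows",
                   collapseDepth = NA_real_,
                   transposed = FALSE,
                   colorOverrides = character(),
                   heatmapScheme = "Viridis",
                   categoricalScheme = "Okabe-Ito",
                   theme = "light",
                   exportFormat = "svg",
                   exportDpi = 96,
                   exportWidth = NA_real_,
                   exportHeight = NA_real_))

.SIDE_PANELS <- c("bars", "stacked_bars", "violins", "none")
.NORMALIZATIONS <- c("none", "within_sample", "within_celltype")

setValidity("ViewConfig", function(object) {
  msgs <- character()
  chk1 <- function(x, what, choices = NULL) {
    if (length(x) != 1L || is.na(x))
      return(sprintf("'%s' must be a single non-missing value", what))
    if (!is.null(choices) && !x %in% choices)
      return(sprintf("'%s' must be one of: %s", what,
                     paste(choices, collapse = ", ")))
    NULL
  }
  msgs <- c(msgs,
            chk1(object@normalization, "normalization", .NORMALIZATIONS),
            chk1(object@log, "log"),
            chk1(object@showHeatmap, "showHeatmap"),
            chk1(object@sidePanelRows, "sidePanelRows", .SIDE_PANELS),
            chk1(object@sidePanelCols, "sidePanelCols", .SIDE_PANELS),
            chk1(object@groupAxis, "groupAxis", c("rows", "cols")),
            chk1(object@transposed, "transposed"),
            chk1(object@theme, "theme", c("light", "dark")),
            chk1(object@exportFormat, "exportFormat", c("svg", "png")))
  if (length(object@exportDpi) != 1L || is.na(object@exportDpi) ||
      object@exportDpi < 72)
    msgs <- c(msgs, "exportDpi must be a single number >= 72")
  if (length(object@collapseDepth) != 1L ||
      (!is.na(object@collapseDepth) &&
       (object@collapseDepth < 0 ||
        object@collapseDepth != floor(object@collapseDepth))))
    msgs <- c(msgs, "collapseDepth must be NA or a non-negative integer")
  if (length(object@groupField) > 1L)
    msgs <- c(msgs, "groupField must be empty or a single field name")
  for (k in object@sortKeys)
    if (!inherits(k, "SortKey")) {
      msgs <- c(msgs, "sortKeys must be a list of sortKey() objects"); break
    }
  for (f in object@filters)
    if (!inherits(f, "FilterSpec")) {
      msgs <- c(msgs, "filters must be a list of filterSpec() objects"); break
    }
  if (length(object@colorOverrides) &&
      (is.null(names(object@colorOverrides)) ||
       any(!nzchar(names(object@colorOverrides)))))
    msgs <- c(msgs, "colorOverrides must be a named character vector")
  if (length(msgs)) msgs else TRUE
})
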