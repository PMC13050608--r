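#' Construct a table of per-cell annotation records
#'
#' A CellTable holds one record per cell: its id, the sample it came from,
#' and its cell-type label. It is the raw ingestion unit that
#' [buildPopulationMatrix()] tallies into a [PopulationMatrix-class].
#'
#' Cells with a missing or empty cell-type label are assigned the reserved
#' label `"unknown"` rather than dropped; how many were relabelled is
#' reported via a message and stored in the `"n_unknown"` attribute.
#'
#' @param cell_id,sample_id,celltype character vectors of equal length.
#' @param extras optional data.frame of additional per-cell columns.
#' @return a data.frame with class `"CellTable"` and columns `cell_id`,
#'   `sample_id`, `celltype` (plus any extras).
#' @export
cellTable <- function(cell_id, sample_id, celltype, extras = NULL) {
  cell_id <- as.character(cell_id)
  sample_id <- as.character(sample_id)
  celltype <- as.character(celltype)
  n <- length(cell_id)
  if (length(sample_id) != n || length(celltype) != n)
    stopInput("cell_id, sample_id and celltype must have equal length")
  if (n == 0L)
    stopInput("a CellTable must contain at least one cell")
  dup <- anyDuplicated(cell_id)
  if (dup)
    stopInput("duplicate cell_id: '%s'", cell_id[dup])
  if (any(is.na(sample_id) | !nzchar(sample_id)))
    stopInput("sample_id must be non-empty for every cell")
  unk <- is.na(celltype) | !nzchar(celltype)
  if (any(unk)) {
    celltype[unk] <- "unknown"
    message(sprintf("%d cell(s) without a cell-type label assigned 'unknown'",
                    sum(unk)))
  }
  df <- data.frame(cell_id = cell_id, sample_id = sample_id,
                   celltype = celltype, stringsAsFactors = FALSE)
  if (!is.null(extras)) {
    if (nrow(extras) != n)
      stopInput("'extras' must have one row per cell")
    df <- cbind(df, as.data.frame(extras, stringsAsFactors = FALSE))
  }
  class(df) <- c("CellTable", "data.frame")
  attr(df, "n_unknown") <- sum(unk)
  df
}

#' Construct a PopulationMatrix
#'
#' Low-level constructor; most users build one from cells with
#' [buildPopulationMatrix()] or from a file with [readCountsDelimited()].
#'
#' @param values numeric matrix with row and column dimnames.
#' @param valueKind what the entries mean; see [PopulationMatrix-class].
#' @param orientation which axis holds samples.
#' @return a [PopulationMatrix-class] object.
#' @export
populationMatrix <- function(values, valueKind = "count",
                             orientation = "samples_as_rows") {
  new("PopulationMatrix", values = values, valueKind = valueKind,
      orientation = orientation)
}

#' Tally per-cell records into a count matrix
#'
#' Counts, for every (sample, cell type) pair, the number of cells with that
#' combination. Row and column label order is first-appearance order in the
#' table; display order is a view concern, applied later by [sortBy()].
#' The grand total always equals the number of records.
#'
#' @param cells a [cellTable()] (or a data.frame with columns `cell_id`,
#'   `sample_id`, `celltype`).
#' @return a [PopulationMatrix-class] with `valueKind = "count"`, samples as
#'   rows.
#' @examples
#' ct <- cellTable(paste0("c", 1:6),
#'                 c("A", "A", "A", "A", "B", "B"),
#'                 c("T", "T", "T", "B", "B", "B"))
#' popValues(buildPopulationMatrix(ct))
#' @export
buildPopulationMatrix <- function(cells) {
  if (!is.data.frame(cells) ||
      !all(c("cell_id", "sample_id", "celltype") %in% names(cells)))
    stopInput("'cells' must have columns cell_id, sample_id, celltype")
  if (nrow(cells) == 0L)
    stopInput("cannot build a population matrix from an empty cell table")
  dup <- anyDuplicated(cells$cell_id)
  if (dup)
    stopInput("duplicate cell_id: '%s'", cells$cell_id[dup])
  s <- factor(cells$sample_id, levels = unique(cells$sample_id))
  t <- factor(cells$celltype, levels = unique(cells$celltype))
  m <- unclass(table(s, t))
  dimnames(m) <- list(levels(s), levels(t))
  storage.mode(m) <- "double"
  populationMatrix(m, "count", "samples_as_rows")
}

#' Assemble a CellPopDataset
#'
#' @param matrix a [PopulationMatrix-class].
#' @param sampleMeta,celltypeMeta `DataFrame`s (or data.frames) keyed by row
#'   name; missing tables default to empty metadata covering the labels.
#' @param hierarchy optional [CellTypeHierarchy-class].
#' @return a [CellPopDataset-class].
#' @export
cellPopDataset <- function(matrix, sampleMeta = NULL, celltypeMeta = NULL,
                           hierarchy = NULL) {
  emptyMeta <- function(ids) {
    d <- S4Vectors::DataFrame(row.names = ids)
    d
  }
  toDF <- function(x, ids) {
    if (is.null(x)) return(emptyMeta(ids))
    d <- S4Vectors::DataFrame(x)
    if (is.null(rownames(d)))
      stopInput("metadata tables must be keyed by row name (entity id)")
    d
  }
  new("CellPopDataset",
      matrix = matrix,
      sampleMeta = toDF(sampleMeta, sampleLabels(matrix)),
      celltypeMeta = toDF(celltypeMeta, celltypeLabels(matrix)),
      hierarchy = hierarchy)
}

## ---- accessors ----

#' @describeIn PopulationMatrix-class the raw value matrix.
#' @param x a PopulationMatrix or CellPopDataset.
#' @export
setMethod("popValues", "PopulationMatrix", function(x) x@values)

#' @export
setMethod("popValues", "CellPopDataset", function(x) x@matrix@values)

#' @export
setMethod("valueKind", "PopulationMatrix", function(x) x@valueKind)

#' @export
setMethod("valueKind", "CellPopDataset", function(x) x@matrix@valueKind)

#' @export
setMethod("orientation", "PopulationMatrix", function(x) x@orientation)

#' @export
setMethod("orientation", "CellPopDataset", function(x) x@matrix@orientation)

#' @export
setMethod("rowLabels", "PopulationMatrix", function(x) rownames(x@values))

#' @export
setMethod("rowLabels", "CellPopDataset", function(x) rownames(x@matrix@values))

#' @export
setMethod("colLabels", "PopulationMatrix", function(x) colnames(x@values))

#' @export
setMethod("colLabels", "CellPopDataset", function(x) colnames(x@matrix@values))

#' @export
setMethod("sampleLabels", "PopulationMatrix", function(x)
  if (x@orientation == "samples_as_rows") rownames(x@values) else colnames(x@values))

#' @export
setMethod("sampleLabels", "CellPopDataset", function(x) sampleLabels(x@matrix))

#' @export
setMethod("celltypeLabels", "PopulationMatrix", function(x)
  if (x@orientation == "samples_as_rows") colnames(x@values) else rownames(x@values))

#' @export
setMethod("celltypeLabels", "CellPopDataset", function(x)
  celltypeLabels(x@matrix))

#' @export
setMethod("popMatrix", "CellPopDataset", function(x) x@matrix)

#' @export
setMethod("sampleMeta", "CellPopDataset", function(x) x@sampleMeta)

#' @export
setMethod("celltypeMeta", "CellPopDataset", function(x) x@celltypeMeta)

#' @export
setMethod("hierarchy", "CellPopDataset", function(x) x@hierarchy)

## ---- summaries ----

#' Row or column totals of a count matrix
#'
#' Per-row (or per-column) cell-count sums, in label order. Restricted to
#' `valueKind == "count"`: summing fractions is not a cell count.
#'
#' @param x a [PopulationMatrix-class] or [CellPopDataset-class].
#' @param axis `"rows"` or `"cols"`.
#' @return named numeric vector in label order.
#' @export
setMethod("totalCounts", "PopulationMatrix", function(x, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  if (x@valueKind != "count")
    stopTransform("totalCounts requires counts, got valueKind '%s'", x@valueKind)
  if (axis == "rows") rowSums(x@values) else colSums(x@values)
})

#' @export
setMethod("totalCounts", "CellPopDataset", function(x, axis = c("rows", "cols"))
  totalCounts(x@matrix, axis))

#' Presence/absence summary per cell type
#'
#' For each cell type, in how many samples it is present (count > 0),
#' whether it is present in every sample, and whether it is absent
#' everywhere. Makes the absent-cell-type question — hard to read off a
#' stacked bar chart — a direct query.
#'
#' @param x a [PopulationMatrix-class] or [CellPopDataset-class] holding
#'   counts.
#' @return a `DataFrame` keyed by cell type with columns
#'   `n_samples_present`, `universally_present`, `absent_everywhere`.
#' @export
setMethod("presenceStats", "PopulationMatrix", function(x) {
  if (x@valueKind != "count")
    stopTransform("presenceStats requires counts, got valueKind '%s'",
                  x@valueKind)
  v <- x@values
  if (x@orientation == "celltypes_as_rows") v <- t(v)
  nPresent <- colSums(v > 0)
  S4Vectors::DataFrame(
    n_samples_present = as.integer(nPresent),
    universally_present = nPresent == nrow(v),
    absent_everywhere = nPresent == 0L,
    row.names = colnames(v))
})

#' @export
setMethod("presenceStats", "CellPopDataset", function(x) presenceStats(x@matrix))

## ---- show ----

setMethod("show", "PopulationMatrix", function(object) {
  v <- object@values
  cat(sprintf("PopulationMatrix: %d x %d [%s], %s\n",
              nrow(v), ncol(v), object@valueKind, object@orientation))
  cat(" rows:", paste(utils::head(rownames(v), 5), collapse = ", "),
      if (nrow(v) > 5) "..." else "", "\n")
  cat(" cols:", paste(utils::head(colnames(v), 5), collapse = ", "),
      if (ncol(v) > 5) "..." else "", "\n")
})

setMethod("show", "CellPopDataset", function(object) {
  m <- object@matrix
  cat(sprintf("CellPopDataset: %d sample(s) x %d cell type(s) [%s]\n",
              length(sampleLabels(m)), length(celltypeLabels(m)),
              m@valueKind))
  cat(sprintf(" sample metadata: %s\n",
              if (ncol(object@sampleMeta)) paste(colnames(object@sampleMeta),
                                                 collapse = ", ") else "<none>"))
  cat(sprintf(" cell-type metadata: %s\n",
              if (ncol(object@celltypeMeta)) paste(colnames(object@celltypeMeta),
                                                   collapse = ", ") else "<none>"))
  cat(sprintf(" hierarchy: %s\n",
              if (is.null(object@hierarchy)) "<none>"
              else sprintf("%d node(s)", length(object@hierarchy@nodes))))
})
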