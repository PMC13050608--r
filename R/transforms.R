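## View-transform algebra over CellPopDataset. The pipeline order used by
## applyView() is fixed: filter -> group/collapse -> normalize -> log ->
## sort -> transpose. Individual transforms enforce their own preconditions
## so out-of-order use fails loudly instead of producing wrong statistics.

#' Describe one sort key
#'
#' @param axis `"rows"` or `"cols"` (of the current orientation).
#' @param kind `"total_count"`, `"alphabetical"`, `"metadata_field"` or
#'   `"hierarchy"`.
#' @param field metadata field name; required iff `kind = "metadata_field"`.
#' @param direction `"ascending"` or `"descending"`.
#' @return a `SortKey` object for [sortBy()] / [viewConfig()].
#' @export
sortKey <- function(axis = c("rows", "cols"),
                    kind = c("total_count", "alphabetical",
                             "metadata_field", "hierarchy"),
                    field = NULL,
                    direction = c("ascending", "descending")) {
  axis <- match.arg(axis)
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  if (kind == "metadata_field") {
    if (is.null(field)) stopUsage("sortKey(kind='metadata_field') needs 'field'")
    field <- .assertString(field, "field")
  } else if (!is.null(field)) {
    stopUsage("'field' is only meaningful for kind='metadata_field'")
  }
  structure(list(axis = axis, kind = kind, field = field,
                 direction = direction),
            class = "SortKey")
}

#' Describe one metadata filter
#'
#' @param axis `"rows"` or `"cols"` (of the current orientation).
#' @param field metadata field name.
#' @param mode `"keep_values"`, `"drop_values"` or `"numeric_range"`.
#' @param values character vector of categories (keep/drop modes) or a
#'   numeric `c(lo, hi)` with inclusive bounds (`numeric_range`).
#' @return a `FilterSpec` object for [filterBy()] / [viewConfig()].
#' @export
filterSpec <- function(axis = c("rows", "cols"), field,
                       mode = c("keep_values", "drop_values", "numeric_range"),
                       values) {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  field <- .assertString(field, "field")
  if (mode == "numeric_range") {
    if (!is.numeric(values) || length(values) != 2L || anyNA(values) ||
        values[1] > values[2])
      stopUsage("numeric_range needs values = c(lo, hi) with lo <= hi")
    values <- as.numeric(values)
  } else {
    values <- as.character(values)
    if (length(values) == 0L)
      stopUsage("keep/drop filters need at least one value")
  }
  structure(list(axis = axis, field = field, mode = mode, values = values),
            class = "FilterSpec")
}

## which metadata table / entity role backs an axis, given orientation
.axisRole <- function(x, axis) {
  samplesOnRows <- orientation(x) == "samples_as_rows"
  isSampleAxis <- (axis == "rows") == samplesOnRows
  list(isSampleAxis = isSampleAxis,
       labels = if (axis == "rows") rowLabels(x) else colLabels(x),
       meta = if (isSampleAxis) x@sampleMeta else x@celltypeMeta)
}

.replaceMatrix <- function(ds, values, kind = valueKind(ds),
                           orient = orientation(ds)) {
  new("CellPopDataset",
      matrix = populationMatrix(values, kind, orient),
      sampleMeta = ds@sampleMeta,
      celltypeMeta = ds@celltypeMeta,
      hierarchy = ds@hierarchy)
}

#' Normalize a count matrix to fractions
#'
#' `within_sample` divides each sample's vector by that sample's total cell
#' count (the quantity classical stacked bars show); samples with zero
#' cells stay all-zero. `within_celltype` divides each cell type's vector
#' by that type's grand total across samples, answering "what share of all
#' cells of this type does each sample contribute". `none` is the identity.
#'
#' Transforms always start from counts: normalizing an already-normalized
#' or log-transformed matrix is rejected.
#'
#' @param object a [CellPopDataset-class] with `valueKind == "count"`.
#' @param method `"within_sample"` (default), `"within_celltype"` or
#'   `"none"`.
#' @param ... ignored.
#' @return a [CellPopDataset-class] with updated values and `valueKind`.
#' @examples
#' ds <- fixtureF1()
#' popValues(normalize(ds, "within_sample"))
#' @export
setMethod("normalize", "CellPopDataset",
          function(object, method = c("within_sample", "within_celltype",
                                      "none"), ...) {
  method <- match.arg(method)
  if (valueKind(object) != "count")
    stopTransform("normalize requires counts, got valueKind '%s' (transforms always start from counts)",
                  valueKind(object))
  if (method == "none") return(object)
  v <- popValues(object)
  samplesOnRows <- orientation(object) == "samples_as_rows"
  overSampleAxis <- (method == "within_sample")
  byRows <- (overSampleAxis == samplesOnRows)
  if (byRows) {
    tot <- rowSums(v)
    out <- v / ifelse(tot == 0, 1, tot)
  } else {
    tot <- colSums(v)
    out <- sweep(v, 2L, ifelse(tot == 0, 1, tot), "/")
  }
  kind <- if (method == "within_sample") "fraction_within_sample"
          else "fraction_within_celltype"
  .replaceMatrix(object, out, kind)
})

#' Log-transform matrix values
#'
#' Elementwise `log_base(v + pseudocount)`. With the default pseudocount of
#' 1, zero counts map to exactly 0, keeping absence visually and
#' numerically at the floor of the scale.
#'
#' @param x a [CellPopDataset-class] holding counts or fractions.
#' @param base logarithm base (default 10).
#' @param pseudocount value added before taking the log (default 1). A
#'   pseudocount `<= 0` is rejected when any zero value is present.
#' @return a [CellPopDataset-class] with `valueKind` `"log_count"` or
#'   `"log_fraction"`.
#' @export
setMethod("logTransform", "CellPopDataset",
          function(x, base = 10, pseudocount = 1) {
  base <- .assertNumber(base, "base")
  pseudocount <- .assertNumber(pseudocount, "pseudocount")
  kind <- valueKind(x)
  if (kind %in% c("log_count", "log_fraction"))
    stopTransform("matrix is already log-transformed")
  if (base <= 0 || base == 1) stopUsage("'base' must be positive and != 1")
  v <- popValues(x)
  if (pseudocount <= 0 && any(v == 0))
    stopTransform("pseudocount <= 0 with zero values present")
  if (any(v + pseudocount <= 0))
    stopTransform("log of non-positive value; increase pseudocount")
  out <- log(v + pseudocount, base = base)
  newKind <- if (kind == "count") "log_count" else "log_fraction"
  .replaceMatrix(x, out, newKind)
})

## build the (missing-last, direction-aware) ordering for one axis
.axisOrder <- function(ds, axis, keys) {
  role <- .axisRole(ds, axis)
  labels <- role$labels
  cols <- list()
  decr <- logical(0)
  for (key in keys) {
    kv <- switch(key$kind,
      total_count = {
        v <- popValues(ds)
        if (axis == "rows") rowSums(v) else colSums(v)
      },
      alphabetical = labels,
      metadata_field = {
        if (!key$field %in% colnames(role$meta))
          stopInput("sort field '%s' not found in %s metadata", key$field,
                    if (role$isSampleAxis) "sample" else "cell-type")
        v <- role$meta[[key$field]][match(labels, rownames(role$meta))]
        if (is.factor(v)) as.character(v) else v
      },
      hierarchy = {
        if (role$isSampleAxis)
          stopTransform("hierarchy sort applies to the cell-type axis")
        h <- ds@hierarchy
        if (is.null(h))
          stopTransform("hierarchy sort requires an attached hierarchy")
        match(labels, hierarchyOrder(h))
      })
    miss <- is.na(kv)
    if (is.numeric(kv)) kv[miss] <- 0 else kv[miss] <- ""
    # missing sorts last regardless of direction
    cols <- c(cols, list(miss), list(kv))
    decr <- c(decr, FALSE, key$direction == "descending")
  }
  cols <- c(cols, list(seq_along(labels)))   # stability tiebreak
  decr <- c(decr, FALSE)
  do.call(order, c(cols, list(method = "radix", decreasing = decr)))
}

#' Reorder rows/columns by sort keys
#'
#' Applies the keys as a stable lexicographic multi-key sort (first key is
#' primary); the original order is the final tiebreaker and entities with
#' missing metadata sort last regardless of direction. Keys for the row and
#' the column axis are handled independently. Sorting only permutes labels
#' and values; the data are unchanged.
#'
#' `kind = "hierarchy"` orders cell types by a depth-first traversal of the
#' attached hierarchy with roots and siblings alphabetical.
#'
#' @param x a [CellPopDataset-class].
#' @param keys a [sortKey()] or list of them.
#' @return the permuted [CellPopDataset-class].
#' @export
setMethod("sortBy", "CellPopDataset", function(x, keys) {
  if (inherits(keys, "SortKey")) keys <- list(keys)
  for (k in keys)
    if (!inherits(k, "SortKey")) stopUsage("'keys' must be sortKey() objects")
  v <- popValues(x)
  for (axis in c("rows", "cols")) {
    axisKeys <- Filter(function(k) k$axis == axis, keys)
    if (!length(axisKeys)) next
    idx <- .axisOrder(.replaceMatrix(x, v), axis, axisKeys)
    v <- if (axis == "rows") v[idx, , drop = FALSE] else v[, idx, drop = FALSE]
  }
  .replaceMatrix(x, v)
})

#' Filter rows/columns by metadata
#'
#' Keeps only the entities whose metadata satisfies the spec; the matrix and
#' the corresponding metadata table are subset together and survivor order
#' is preserved. Entities with a missing value in the filtered field are
#' dropped under `keep_values` and `numeric_range` and kept under
#' `drop_values`.
#'
#' @param x a [CellPopDataset-class].
#' @param spec a [filterSpec()].
#' @return the filtered [CellPopDataset-class].
#' @export
setMethod("filterBy", "CellPopDataset", function(x, spec) {
  if (!inherits(spec, "FilterSpec")) stopUsage("'spec' must be a filterSpec()")
  role <- .axisRole(x, spec$axis)
  if (!spec$field %in% colnames(role$meta))
    stopInput("filter field '%s' not found in %s metadata (available: %s)",
              spec$field, if (role$isSampleAxis) "sample" else "cell-type",
              paste(colnames(role$meta), collapse = ", "))
  vals <- role$meta[[spec$field]][match(role$labels, rownames(role$meta))]
  if (is.factor(vals)) vals <- as.character(vals)
  keep <- switch(spec$mode,
    keep_values = !is.na(vals) & vals %in% spec$values,
    drop_values = is.na(vals) | !(vals %in% spec$values),
    numeric_range = {
      if (!is.numeric(vals))
        stopInput("numeric_range filter on non-numeric field '%s'", spec$field)
      !is.na(vals) & vals >= spec$values[1] & vals <= spec$values[2]
    })
  v <- popValues(x)
  survivors <- role$labels[keep]
  v <- if (spec$axis == "rows") v[keep, , drop = FALSE]
       else v[, keep, drop = FALSE]
  newMeta <- role$meta[rownames(role$meta) %in% survivors, , drop = FALSE]
  new("CellPopDataset",
      matrix = populationMatrix(v, valueKind(x), orientation(x)),
      sampleMeta = if (role$isSampleAxis) newMeta else x@sampleMeta,
      celltypeMeta = if (role$isSampleAxis) x@celltypeMeta else newMeta,
      hierarchy = x@hierarchy)
})

#' Aggregate rows/columns by a categorical metadata field
#'
#' Sums counts over all entities sharing a category, yielding one row (or
#' column) per category. Category order is first-appearance order among the
#' current labels. Grouping happens before normalization — summing
#' fractions would be statistically wrong — so counts are required.
#' Entities with a missing value in the grouping field form a
#' `"(missing)"` category.
#'
#' @param x a [CellPopDataset-class] with `valueKind == "count"`.
#' @param axis `"rows"` or `"cols"`.
#' @param field a categorical metadata field of that axis.
#' @return the aggregated [CellPopDataset-class]; the grouped axis's
#'   metadata is replaced by a table carrying the grouping field only.
#' @export
setMethod("groupBy", "CellPopDataset", function(x, axis, field) {
  axis <- match.arg(axis, c("rows", "cols"))
  field <- .assertString(field, "field")
  if (valueKind(x) != "count")
    stopTransform("groupBy requires counts (group before normalizing)")
  role <- .axisRole(x, axis)
  if (!field %in% colnames(role$meta))
    stopInput("grouping field '%s' not found in %s metadata", field,
              if (role$isSampleAxis) "sample" else "cell-type")
  vals <- role$meta[[field]][match(role$labels, rownames(role$meta))]
  if (is.numeric(vals))
    stopTransform("grouping on numeric field '%s'; bin it first", field)
  vals <- as.character(vals)
  vals[is.na(vals)] <- "(missing)"
  cats <- unique(vals)                      # first-appearance order
  f <- factor(vals, levels = cats)
  v <- popValues(x)
  agg <- if (axis == "rows") rowsum(v, f)
         else t(rowsum(t(v), f))
  agg <- if (axis == "rows") agg[cats, , drop = FALSE]
         else agg[, cats, drop = FALSE]
  newMeta <- S4Vectors::DataFrame(stats::setNames(list(cats), field),
                                  row.names = cats)
  new("CellPopDataset",
      matrix = populationMatrix(agg, "count", orientation(x)),
      sampleMeta = if (role$isSampleAxis) newMeta else x@sampleMeta,
      celltypeMeta = if (role$isSampleAxis) x@celltypeMeta else newMeta,
      # grouped cell types are no longer hierarchy nodes
      hierarchy = if (role$isSampleAxis) x@hierarchy else NULL)
})

#' Collapse cell types to a hierarchy depth
#'
#' Replaces every cell type by its ancestor at the given depth (itself when
#' its own depth is already `<= depth`) and sums the counts of merged
#' types. The result's cell types are ordered by the hierarchy's
#' depth-first traversal. The grand total is conserved exactly.
#'
#' @param x a [CellPopDataset-class] with counts and an attached hierarchy.
#' @param depth non-negative integer target depth (0 = roots).
#' @return the collapsed [CellPopDataset-class].
#' @examples
#' popValues(collapseToDepth(fixtureF1(), 0))
#' @export
setMethod("collapseToDepth", "CellPopDataset", function(x, depth) {
  if (is.null(x@hierarchy))
    stopTransform("collapseToDepth requires an attached hierarchy")
  depth <- .assertNumber(depth, "depth")
  if (depth < 0 || depth != floor(depth))
    stopUsage("'depth' must be a non-negative integer")
  if (valueKind(x) != "count")
    stopTransform("collapseToDepth requires counts (collapse before normalizing)")
  h <- x@hierarchy
  ctAxis <- if (orientation(x) == "samples_as_rows") "cols" else "rows"
  labels <- celltypeLabels(x)
  anc <- ancestorAtDepth(h, labels, depth)
  newLabels <- intersect(hierarchyOrder(h), unique(anc))
  f <- factor(anc, levels = newLabels)
  v <- popValues(x)
  agg <- if (ctAxis == "rows") rowsum(v, f)[newLabels, , drop = FALSE]
         else t(rowsum(t(v), f))[, newLabels, drop = FALSE]
  depths <- hierarchyDepths(h)
  newMeta <- S4Vectors::DataFrame(depth = unname(depths[newLabels]),
                                  row.names = newLabels)
  new("CellPopDataset",
      matrix = populationMatrix(agg, "count", orientation(x)),
      sampleMeta = x@sampleMeta,
      celltypeMeta = newMeta,
      hierarchy = h)
})

#' Transpose the view
#'
#' Swaps rows and columns (values, labels, orientation flag). Metadata
#' stays attached to samples and cell types; only their on-screen role
#' flips. Applying it twice is the identity.
#'
#' @param x a [CellPopDataset-class].
#' @return the transposed [CellPopDataset-class].
#' @export
setMethod("transposeView", "CellPopDataset", function(x) {
  flipped <- if (orientation(x) == "samples_as_rows")
    "celltypes_as_rows" else "samples_as_rows"
  .replaceMatrix(x, t(popValues(x)), valueKind(x), flipped)
})
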