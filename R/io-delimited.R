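## Delimited-text formats: count matrices and hierarchy edge lists.
## Dialect: comma by default, tab when the file extension is .tsv; UTF-8.
## Labels must not contain the delimiter (no quoting dialect).

.delimiterFor <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a count matrix from delimited text
#'
#' Expects a rectangular table whose header row names the cell types, whose
#' first column holds the sample labels and whose cells are non-negative
#' integers.
#'
#' @param path file path; `.tsv` switches the delimiter to tab.
#' @param delimiter optional explicit field delimiter.
#' @return a [PopulationMatrix-class] with `valueKind = "count"`, samples as
#'   rows.
#' @export
readCountsDelimited <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stopInput("file not found: %s", path)
  sep <- .delimiterFor(path, delimiter)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stopInput("count matrix needs a header row and at least one sample row")
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1L]]
  ncols <- length(header)
  types <- header[-1L]
  if (length(types) == 0L) stopInput("header names no cell types")
  if (anyDuplicated(types))
    stopInput("duplicate cell-type label '%s' in header",
              types[anyDuplicated(types)])
  nSamples <- length(fields) - 1L
  m <- matrix(0, nrow = nSamples, ncol = length(types))
  samples <- character(nSamples)
  for (i in seq_len(nSamples)) {
    row <- fields[[i + 1L]]
    if (length(row) != ncols)
      stopInput("ragged row %d: expected %d fields, found %d",
                i + 1L, ncols, length(row))
    samples[i] <- row[1L]
    vals <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(vals) || any(vals != floor(vals)) || any(vals < 0))
      stopInput("non-integer count in row %d", i + 1L)
    m[i, ] <- vals
  }
  if (anyDuplicated(samples))
    stopInput("duplicate sample label '%s' (row %d)",
              samples[anyDuplicated(samples)], anyDuplicated(samples) + 1L)
  dimnames(m) <- list(samples, types)
  populationMatrix(m, "count", "samples_as_rows")
}

#' Write a count matrix as delimited text
#'
#' Writes the canonical layout read back by [readCountsDelimited()]:
#' header = cell types, first column = sample labels. A matrix in
#' `celltypes_as_rows` orientation is transposed to the canonical
#' orientation first.
#'
#' @param x a [PopulationMatrix-class] or [CellPopDataset-class] with
#'   counts.
#' @param path destination; `.tsv` switches the delimiter to tab.
#' @param delimiter optional explicit field delimiter.
#' @return `path`, invisibly.
#' @export
writeCountsDelimited <- function(x, path, delimiter = NULL) {
  if (is(x, "CellPopDataset")) x <- popMatrix(x)
  stopifnot(is(x, "PopulationMatrix"))
  if (x@valueKind != "count")
    stopTransform("writeCountsDelimited stores counts, got '%s'", x@valueKind)
  sep <- .delimiterFor(path, delimiter)
  v <- x@values
  if (x@orientation == "celltypes_as_rows") v <- t(v)
  lines <- c(paste(c("sample", colnames(v)), collapse = sep),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(rownames(v)[i], format(v[i, ], scientific = FALSE,
                                              trim = TRUE)),
                     collapse = sep), character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a cell-type hierarchy from a child,parent edge list
#'
#' Two-column delimited file, one edge per line, child first. A header line
#' `child,parent` is recognized and skipped. An empty file yields an empty
#' hierarchy (every label later behaves as a root). Cycles and children
#' with two different parents are rejected.
#'
#' @param path file path; `.tsv` switches the delimiter to tab.
#' @param delimiter optional explicit field delimiter.
#' @return a [CellTypeHierarchy-class].
#' @export
readHierarchyEdges <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stopInput("file not found: %s", path)
  sep <- .delimiterFor(path, delimiter)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(cellTypeHierarchy())
  fields <- strsplit(lines, sep, fixed = TRUE)
  if (identical(tolower(trimws(fields[[1L]])), c("child", "parent")))
    fields <- fields[-1L]
  if (length(fields) == 0L) return(cellTypeHierarchy())
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stopInput("edge line %d does not have two fields", bad[1L])
  children <- vapply(fields, `[`, character(1), 1L)
  parents <- vapply(fields, `[`, character(1), 2L)
  keep <- !duplicated(paste0(children, "\r", parents))
  children <- children[keep]; parents <- parents[keep]
  dup <- children[duplicated(children)]
  if (length(dup))
    stopInput("child '%s' has conflicting parents", dup[1L])
  # explicit cycle detection so the offending chain can be reported
  pmap <- stats::setNames(parents, children)
  for (start in children) {
    seen <- start; cur <- start
    while (!is.na(pmap[cur])) {
      cur <- unname(pmap[cur])
      if (cur %in% seen)
        stopInput("cycle in hierarchy: %s",
                  paste(c(seen[match(cur, seen):length(seen)], cur),
                        collapse = " -> "))
      seen <- c(seen, cur)
    }
  }
  cellTypeHierarchy(pmap)
}

#' Write a hierarchy as a child,parent edge list
#'
#' @param h a [CellTypeHierarchy-class].
#' @param path destination; `.tsv` switches the delimiter to tab.
#' @param delimiter optional explicit field delimiter.
#' @return `path`, invisibly.
#' @export
writeHierarchyEdges <- function(h, path, delimiter = NULL) {
  stopifnot(is(h, "CellTypeHierarchy"))
  sep <- .delimiterFor(path, delimiter)
  lines <- c(paste(c("child", "parent"), collapse = sep),
             paste(names(h@parent), unname(h@parent), sep = sep))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
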