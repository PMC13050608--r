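## AnnData ingestion. Only the per-cell observation (obs) table is read:
## population plots need annotations, not expression, so the X matrix is
## never touched and backed/zarr stores are cheap to open. The format work
## is delegated to the reference AnnData implementation through a small
## bridge script shipped with the package.

.pythonBin <- function() {
  py <- Sys.getenv("SCPOPVIZ_PYTHON", unset = Sys.which("python"))
  if (!nzchar(py))
    stopInput("no 'python' interpreter found on PATH (needed for AnnData stores)")
  py
}

.bridge <- function(args) {
  script <- system.file("python", "anndata_bridge.py", package = "scPopViz",
                        mustWork = TRUE)
  out <- tempfile("bridge_stderr_")
  on.exit(unlink(out))
  status <- suppressWarnings(
    system2(.pythonBin(), c(shQuote(script), args), stdout = out, stderr = out))
  if (status != 0L) {
    diag <- paste(readLines(out, warn = FALSE), collapse = " | ")
    stopInput("AnnData bridge failed (exit %d): %s", status, diag)
  }
  invisible(TRUE)
}

#' Describe a per-cell data source
#'
#' @param source_path path to the store or file.
#' @param source_kind `"anndata_h5"`, `"anndata_zarr"` or
#'   `"counts_delimited"`; `NULL` infers it from the path (`.h5ad`,
#'   directory/`.zarr`, `.csv`/`.tsv`).
#' @param sample_field,celltype_field obs columns holding the sample id and
#'   cell-type label.
#' @param metadata_fields optional obs columns lifted to per-sample
#'   metadata (first value per sample; columns that are not constant within
#'   a sample are dropped with a warning).
#' @return a `LoadSpec` object for [readCells()].
#' @export
loadSpec <- function(source_path, source_kind = NULL,
                     sample_field = "sample", celltype_field = "cell_type",
                     metadata_fields = NULL) {
  source_path <- .assertString(source_path, "source_path")
  sample_field <- .assertString(sample_field, "sample_field")
  celltype_field <- .assertString(celltype_field, "celltype_field")
  if (sample_field == celltype_field)
    stopUsage("sample_field and celltype_field must differ")
  if (is.null(source_kind)) {
    source_kind <-
      if (grepl("\\.h5ad$", source_path, ignore.case = TRUE)) "anndata_h5"
      else if (dir.exists(source_path) ||
               grepl("\\.zarr$", source_path, ignore.case = TRUE)) "anndata_zarr"
      else if (grepl("\\.(csv|tsv)$", source_path, ignore.case = TRUE))
        "counts_delimited"
      else stopUsage("cannot infer source_kind for '%s'; pass it explicitly",
                     source_path)
  }
  source_kind <- match.arg(source_kind,
                           c("anndata_h5", "anndata_zarr", "counts_delimited"))
  structure(list(source_path = source_path, source_kind = source_kind,
                 sample_field = sample_field, celltype_field = celltype_field,
                 metadata_fields = metadata_fields),
            class = "LoadSpec")
}

#' Read per-cell records from an AnnData store
#'
#' Loads the obs table of an `.h5ad` file or AnnData zarr store, builds a
#' [cellTable()] (one record per observation; obs index = cell id) and a
#' per-sample metadata table from the lifted columns.
#'
#' @param spec a [loadSpec()] with an AnnData `source_kind`.
#' @return a list with elements `cells` (CellTable) and `sampleMeta`
#'   (`DataFrame` keyed by sample id).
#' @export
readCells <- function(spec) {
  if (!inherits(spec, "LoadSpec")) stopUsage("'spec' must be a loadSpec()")
  if (spec$source_kind == "counts_delimited")
    stopUsage("counts_delimited sources hold no per-cell records; use readCountsDelimited()")
  if (!file.exists(spec$source_path))
    stopInput("source not found: %s", spec$source_path)
  kind <- if (spec$source_kind == "anndata_h5") "h5ad" else "zarr"
  csv <- tempfile("obs_", fileext = ".csv")
  on.exit(unlink(csv))
  .bridge(c("dump-obs", "--path", shQuote(spec$source_path),
            "--kind", kind, "--out", shQuote(csv)))
  obs <- utils::read.csv(csv, stringsAsFactors = FALSE,
                         colClasses = c(`__obs_id__` = "character"),
                         check.names = FALSE)
  need <- c(spec$sample_field, spec$celltype_field, spec$metadata_fields)
  missing <- setdiff(need, colnames(obs))
  if (length(missing))
    stopInput("column(s) %s not in obs table; available: %s",
              paste(sQuote(missing), collapse = ", "),
              paste(setdiff(colnames(obs), "__obs_id__"), collapse = ", "))
  cells <- cellTable(obs[["__obs_id__"]],
                     obs[[spec$sample_field]],
                     obs[[spec$celltype_field]])
  sampleIds <- unique(cells$sample_id)
  metaCols <- list()
  for (field in spec$metadata_fields) {
    vals <- split(obs[[field]], factor(cells$sample_id, levels = sampleIds))
    uniq <- lapply(vals, unique)
    if (any(lengths(uniq) > 1L)) {
      warning(sprintf(
        "obs column '%s' is not constant within every sample; dropped", field))
      next
    }
    metaCols[[field]] <- unname(unlist(lapply(uniq, `[`, 1L)))
  }
  sm <- S4Vectors::DataFrame(metaCols, row.names = sampleIds)
  list(cells = cells, sampleMeta = sm)
}

#' Write per-cell records as an AnnData store
#'
#' Serializes a [cellTable()] (plus optional per-sample metadata broadcast
#' onto the cells) as an obs-only AnnData `.h5ad` file or zarr store — the
#' layout [readCells()] reads back. Used to exchange synthetic atlases with
#' scverse tools and for end-to-end round trips.
#'
#' @param cells a [cellTable()].
#' @param path destination file (`.h5ad`) or store directory.
#' @param kind `"h5ad"` or `"zarr"`; inferred from `path` when `NULL`.
#' @param sampleMeta optional `DataFrame`/data.frame keyed by sample id;
#'   its columns become obs columns, constant within each sample.
#' @param sample_field,celltype_field obs column names to write.
#' @return `path`, invisibly.
#' @export
writeCellsAnnData <- function(cells, path, kind = NULL, sampleMeta = NULL,
                              sample_field = "sample",
                              celltype_field = "cell_type") {
  if (!is.data.frame(cells) ||
      !all(c("cell_id", "sample_id", "celltype") %in% names(cells)))
    stopUsage("'cells' must be a cellTable()")
  if (is.null(kind))
    kind <- if (grepl("\\.h5ad$", path, ignore.case = TRUE)) "h5ad" else "zarr"
  kind <- match.arg(kind, c("h5ad", "zarr"))
  obs <- data.frame(`__obs_id__` = cells$cell_id, check.names = FALSE,
                    stringsAsFactors = FALSE)
  obs[[sample_field]] <- cells$sample_id
  obs[[celltype_field]] <- cells$celltype
  if (!is.null(sampleMeta)) {
    sm <- as.data.frame(sampleMeta)
    idx <- match(cells$sample_id, rownames(sm))
    for (col in colnames(sm)) obs[[col]] <- sm[[col]][idx]
  }
  csv <- tempfile("obs_", fileext = ".csv")
  on.exit(unlink(csv))
  utils::write.csv(obs, csv, row.names = FALSE)
  if (kind == "zarr" && dir.exists(path)) unlink(path, recursive = TRUE)
  .bridge(c("write-obs", "--csv", shQuote(csv),
            "--path", shQuote(path), "--kind", kind))
  invisible(path)
}
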