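#' Construct a view configuration
#'
#' All arguments have defaults giving the package's default view: a counts
#' heatmap with total-count bar sidebars and rows sorted by total count
#' descending. See [ViewConfig-class] for the meaning of each field.
#'
#' @param normalization,log,logBase,pseudocount transform pipeline options.
#' @param showHeatmap,sidePanelRows,sidePanelCols,expandedRows panels.
#' @param sortKeys,filters,groupField,groupAxis,collapseDepth,transposed
#'   transform pipeline options.
#' @param colorOverrides,heatmapScheme,categoricalScheme,theme colors.
#' @param exportFormat,exportDpi,exportWidth,exportHeight export defaults.
#' @return a validated [ViewConfig-class].
#' @examples
#' cfg <- viewConfig(normalization = "within_sample", log = TRUE)
#' @export
viewConfig <- function(normalization = "none",
                       log = FALSE,
                       logBase = 10,
                       pseudocount = 1,
                       showHeatmap = TRUE,
                       sidePanelRows = "bars",
                       sidePanelCols = "bars",
                       expandedRows = character(),
                       sortKeys = list(sortKey("rows", "total_count",
                                               direction = "descending")),
                       filters = list(),
                       groupField = character(),
                       groupAxis = "rows",
                       collapseDepth = NA,
                       transposed = FALSE,
                       colorOverrides = character(),
                       heatmapScheme = "Viridis",
                       categoricalScheme = "Okabe-Ito",
                       theme = "light",
                       exportFormat = "svg",
                       exportDpi = 96,
                       exportWidth = NA,
                       exportHeight = NA) {
  if (inherits(sortKeys, "SortKey")) sortKeys <- list(sortKeys)
  if (inherits(filters, "FilterSpec")) filters <- list(filters)
  new("ViewConfig",
      normalization = normalization,
      log = .assertFlag(log, "log"),
      logBase = .assertNumber(logBase, "logBase"),
      pseudocount = .assertNumber(pseudocount, "pseudocount"),
      showHeatmap = .assertFlag(showHeatmap, "showHeatmap"),
      sidePanelRows = sidePanelRows,
      sidePanelCols = sidePanelCols,
      expandedRows = as.character(expandedRows),
      sortKeys = sortKeys,
      filters = filters,
      groupField = as.character(groupField),
      groupAxis = groupAxis,
      collapseDepth = as.numeric(collapseDepth),
      transposed = .assertFlag(transposed, "transposed"),
      colorOverrides = colorOverrides,
      heatmapScheme = .assertString(heatmapScheme, "heatmapScheme"),
      categoricalScheme = .assertString(categoricalScheme, "categoricalScheme"),
      theme = theme,
      exportFormat = exportFormat,
      exportDpi = .assertNumber(exportDpi, "exportDpi"),
      exportWidth = as.numeric(exportWidth),
      exportHeight = as.numeric(exportHeight))
}

#' The traditional stacked-bar population plot, as a preset
#'
#' Transposes the view (cell types become rows, samples columns), hides the
#' heatmap, normalizes within sample, and shows one vertical stacked bar
#' per sample in the column side panel — the classical cell population
#' plot.
#'
#' @return a [ViewConfig-class].
#' @export
stackedBarPreset <- function() {
  viewConfig(normalization = "within_sample",
             showHeatmap = FALSE,
             sidePanelRows = "none",
             sidePanelCols = "stacked_bars",
             transposed = TRUE)
}

## ---- JSON schema (version 1) ----

.CONFIG_SCHEMA_VERSION <- 1L

.sortKeyToList <- function(k)
  Filter(Negate(is.null),
         list(axis = k$axis, kind = k$kind, field = k$field,
              direction = k$direction))

.filterToList <- function(f)
  list(axis = f$axis, field = f$field, mode = f$mode,
       values = as.list(f$values))

#' Convert a ViewConfig to its canonical JSON-ready list
#'
#' Fixed key order, all keys present; `NA`/empty optionals become `null`.
#' @param config a [ViewConfig-class].
#' @return a named list mirroring the JSON schema.
#' @export
configToList <- function(config) {
  stopifnot(is(config, "ViewConfig"))
  validObject(config)
  list(
    schema_version = .CONFIG_SCHEMA_VERSION,
    normalization = config@normalization,
    log = list(enabled = config@log, base = config@logBase,
               pseudocount = config@pseudocount),
    show_heatmap = config@showHeatmap,
    side_panel_rows = config@sidePanelRows,
    side_panel_cols = config@sidePanelCols,
    expanded_rows = as.list(config@expandedRows),
    sort_keys = lapply(config@sortKeys, .sortKeyToList),
    filters = lapply(config@filters, .filterToList),
    group_field = if (length(config@groupField)) config@groupField else NULL,
    group_axis = config@groupAxis,
    collapse_depth = if (is.na(config@collapseDepth)) NULL
                     else config@collapseDepth,
    transposed = config@transposed,
    colors = list(
      overrides = as.list(config@colorOverrides),
      heatmap_scheme = config@heatmapScheme,
      categorical_scheme = config@categoricalScheme),
    theme = config@theme,
    export = list(
      format = config@exportFormat,
      dpi = config@exportDpi,
      width = if (is.na(config@exportWidth)) NULL else config@exportWidth,
      height = if (is.na(config@exportHeight)) NULL else config@exportHeight))
}

.rejectUnknown <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    stopConfig("unknown key '%s' at %s", unknown[1L], where)
}

.scalar <- function(x, where) {
  if (is.null(x) || length(x) != 1L)
    stopConfig("expected a scalar at %s", where)
  x
}

#' Build a ViewConfig from a JSON-shaped list
#'
#' Unknown keys are rejected by name (with their JSON path); omitted keys
#' take the documented defaults.
#' @param x a named list as produced by `jsonlite::fromJSON(...,
#'   simplifyVector = FALSE)`.
#' @return a [ViewConfig-class].
#' @export
configFromList <- function(x) {
  if (!is.list(x)) stopConfig("config must be a JSON object at $")
  .rejectUnknown(x, c("schema_version", "normalization", "log",
                      "show_heatmap", "side_panel_rows", "side_panel_cols",
                      "expanded_rows", "sort_keys", "filters", "group_field",
                      "group_axis", "collapse_depth", "transposed", "colors",
                      "theme", "export"), "$")
  if (!is.null(x$schema_version) &&
      .scalar(x$schema_version, "$.schema_version") != .CONFIG_SCHEMA_VERSION)
    stopConfig("unsupported schema_version at $.schema_version")
  logBlock <- x$log %||% list()
  if (!is.list(logBlock)) stopConfig("expected an object at $.log")
  .rejectUnknown(logBlock, c("enabled", "base", "pseudocount"), "$.log")
  colorsBlock <- x$colors %||% list()
  if (!is.list(colorsBlock)) stopConfig("expected an object at $.colors")
  .rejectUnknown(colorsBlock, c("overrides", "heatmap_scheme",
                                "categorical_scheme"), "$.colors")
  exportBlock <- x$export %||% list()
  if (!is.list(exportBlock)) stopConfig("expected an object at $.export")
  .rejectUnknown(exportBlock, c("format", "dpi", "width", "height"),
                 "$.export")
  parseSortKey <- function(k, i) {
    where <- sprintf("$.sort_keys[%d]", i)
    if (!is.list(k)) stopConfig("expected an object at %s", where)
    .rejectUnknown(k, c("axis", "kind", "field", "direction"), where)
    tryCatch(
      sortKey(axis = .scalar(k$axis %||% "rows", where),
              kind = .scalar(k$kind %||% "total_count", where),
              field = if (is.null(k$field)) NULL else .scalar(k$field, where),
              direction = .scalar(k$direction %||% "ascending", where)),
      scpop_usage_error = function(e)
        stopConfig("invalid sort key at %s: %s", where, conditionMessage(e)))
  }
  parseFilter <- function(f, i) {
    where <- sprintf("$.filters[%d]", i)
    if (!is.list(f)) stopConfig("expected an object at %s", where)
    .rejectUnknown(f, c("axis", "field", "mode", "values"), where)
    mode <- .scalar(f$mode %||% "keep_values", where)
    vals <- unlist(f$values)
    tryCatch(
      filterSpec(axis = .scalar(f$axis %||% "rows", where),
                 field = .scalar(f$field, paste0(where, ".field")),
                 mode = mode,
                 values = if (mode == "numeric_range") as.numeric(vals)
                          else as.character(vals)),
      scpop_usage_error = function(e)
        stopConfig("invalid filter at %s: %s", where, conditionMessage(e)))
  }
  overrides <- colorsBlock$overrides %||% list()
  overrides <- stats::setNames(as.character(unlist(overrides)),
                               names(overrides))
  defaults <- formals(viewConfig)
  sortKeys <- if (is.null(x$sort_keys))
    eval(defaults$sortKeys)
  else
    lapply(seq_along(x$sort_keys),
           function(i) parseSortKey(x$sort_keys[[i]], i))
  tryCatch(
    viewConfig(
      normalization = .scalar(x$normalization %||% "none", "$.normalization"),
      log = .scalar(logBlock$enabled %||% FALSE, "$.log.enabled"),
      logBase = .scalar(logBlock$base %||% 10, "$.log.base"),
      pseudocount = .scalar(logBlock$pseudocount %||% 1, "$.log.pseudocount"),
      showHeatmap = .scalar(x$show_heatmap %||% TRUE, "$.show_heatmap"),
      sidePanelRows = .scalar(x$side_panel_rows %||% "bars",
                              "$.side_panel_rows"),
      sidePanelCols = .scalar(x$side_panel_cols %||% "bars",
                              "$.side_panel_cols"),
      expandedRows = as.character(unlist(x$expanded_rows)),
      sortKeys = sortKeys,
      filters = lapply(seq_along(x$filters),
                       function(i) parseFilter(x$filters[[i]], i)),
      groupField = if (is.null(x$group_field)) character()
                   else .scalar(x$group_field, "$.group_field"),
      groupAxis = .scalar(x$group_axis %||% "rows", "$.group_axis"),
      collapseDepth = if (is.null(x$collapse_depth)) NA
                      else .scalar(x$collapse_depth, "$.collapse_depth"),
      transposed = .scalar(x$transposed %||% FALSE, "$.transposed"),
      colorOverrides = overrides,
      heatmapScheme = .scalar(colorsBlock$heatmap_scheme %||% "Viridis",
                              "$.colors.heatmap_scheme"),
      categoricalScheme = .scalar(colorsBlock$categorical_scheme %||%
                                    "Okabe-Ito",
                                  "$.colors.categorical_scheme"),
      theme = .scalar(x$theme %||% "light", "$.theme"),
      exportFormat = .scalar(exportBlock$format %||% "svg", "$.export.format"),
      exportDpi = .scalar(exportBlock$dpi %||% 96, "$.export.dpi"),
      exportWidth = if (is.null(exportBlock$width)) NA
                    else .scalar(exportBlock$width, "$.export.width"),
      exportHeight = if (is.null(exportBlock$height)) NA
                     else .scalar(exportBlock$height, "$.export.height")),
    scpop_usage_error = function(e) stopConfig("%s", conditionMessage(e)),
    error = function(e) {
      if (inherits(e, "scpop_config_error")) stop(e)
      stopConfig("invalid config: %s", conditionMessage(e))
    })
}

#' Read a view configuration from JSON
#'
#' `{}` yields the full default [ViewConfig-class]; unknown keys are
#' rejected with their JSON path.
#' @param path JSON file path.
#' @return a [ViewConfig-class].
#' @export
readViewConfig <- function(path) {
  if (!file.exists(path)) stopInput("config file not found: %s", path)
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e)
                  stopConfig("not valid JSON: %s", conditionMessage(e)))
  configFromList(x)
}

#' Write a view configuration as canonical JSON
#'
#' The output is canonical (fixed key order, all keys present), so
#' `writeViewConfig(readViewConfig(p))` is a fixed point.
#' @param config a [ViewConfig-class].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
writeViewConfig <- function(config, path) {
  jsonlite::write_json(configToList(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}
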