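## Deterministic layout: (Dataset, ViewConfig) -> FigureModel.
## Abstract coordinates, origin top-left, y increasing downward; exporters
## map to device space. All geometry below is in these units.

.LAYOUT <- list(
  cell = 18,        # heatmap cell width/height
  expanded = 72,    # height of an expanded-row bar panel
  side = 70,        # sidebar thickness
  gap = 8,
  pad = 8,
  rowlab = 110,     # row label band width
  collab = 64,      # column label band height
  legend = 52)

.themeColors <- function(theme) {
  if (theme == "dark")
    list(bg = "#1e1e1e", fg = "#e8e8e8", absent = "#3c3c3c")
  else
    list(bg = "#ffffff", fg = "#222222", absent = "#e3e3e3")
}

.marksDF <- function(id = character(), kind = character(), row = character(),
                     col = character(), value = numeric(), color = character(),
                     x = numeric(), y = numeric(), w = numeric(),
                     h = numeric(), vmin = NA_real_, vmed = NA_real_,
                     vmax = NA_real_, px = NULL, py = NULL) {
  n <- length(id)
  df <- data.frame(id = id, kind = kind, row = row, col = col,
                   value = value, color = color, x = x, y = y, w = w, h = h,
                   vmin = rep_len(vmin, n), vmed = rep_len(vmed, n),
                   vmax = rep_len(vmax, n), stringsAsFactors = FALSE)
  df$px <- if (is.null(px)) rep(list(NULL), n) else px
  df$py <- if (is.null(py)) rep(list(NULL), n) else py
  df
}

.markId <- function(panel, kind, row, col) {
  esc <- function(x) gsub("/", "%2F", ifelse(is.na(x), "-", x), fixed = TRUE)
  paste(panel, kind, esc(row), esc(col), sep = "/")
}

## violin outline for a value vector, in the unit box [0,1]x[0,1]:
## u = position along the value domain, v = half-thickness (0..0.5 each side
## of the midline). Kernel density, Scott's-rule bandwidth, clipped to the
## data range; degenerate inputs (n < 2 or zero spread) give a flat sliver.
.violinOutline <- function(vals, n = 48L) {
  stats <- c(vmin = min(vals), vmed = stats::median(vals), vmax = max(vals))
  if (length(vals) < 2L || length(unique(vals)) < 2L) {
    u <- c(0, 1); d <- c(1, 1)
  } else {
    bw <- stats::bw.nrd(vals)
    if (!is.finite(bw) || bw <= 0) bw <- stats::bw.nrd0(vals)
    den <- stats::density(vals, bw = bw, from = stats["vmin"],
                          to = stats["vmax"], n = n)
    u <- (den$x - stats["vmin"]) / (stats["vmax"] - stats["vmin"])
    d <- den$y / max(den$y)
  }
  list(u = c(u, rev(u)), v = c(0.5 - d / 2, rev(0.5 + d / 2)),
       stats = stats)
}

.panel <- function(panel_id, kind, rect, marks) {
  list(panel_id = panel_id, kind = kind, rect = rect, marks = marks)
}

#' Lay out a view-applied dataset as a FigureModel
#'
#' Turns a dataset (already transformed by [applyView()]) and a
#' [ViewConfig-class] into a deterministic [FigureModel-class]: the central
#' heatmap, expanded-row bar panels inline with the row grid, bar /
#' stacked-bar / violin sidebars aligned with the rows and columns, axis
#' label panels and a legend. Zero-valued heatmap cells become
#' `absent_glyph` marks so absent cell types stay visible. The layout is a
#' pure function: identical inputs give structurally identical models.
#'
#' @param x a [CellPopDataset-class] (view-applied).
#' @param config a [ViewConfig-class].
#' @return a [FigureModel-class].
#' @examples
#' fig <- layoutFigure(fixtureF1(), viewConfig(sortKeys = list()))
#' fig
#' @export
setMethod("layoutFigure", "CellPopDataset", function(x, config) {
  stopifnot(is(config, "ViewConfig"))
  validObject(config)
  L <- .LAYOUT
  tc <- .themeColors(config@theme)
  v <- popValues(x)
  rows <- rownames(v); cols <- colnames(v)
  nR <- length(rows); nC <- length(cols)
  if (nR == 0L || nC == 0L)
    stopInput("cannot lay out an empty matrix (no rows or no columns)")

  expanded <- config@expandedRows
  badExp <- setdiff(expanded, rows)
  if (length(badExp))
    stopInput("expanded row '%s' is not a row of the dataset", badExp[1L])
  if (length(expanded) && !config@showHeatmap)
    stopUsage("expanded rows require the heatmap")

  haveRowSide <- config@sidePanelRows != "none"
  haveColSide <- config@sidePanelCols != "none"
  haveRowsArea <- config@showHeatmap || haveRowSide

  ## horizontal frame
  x0 <- L$pad + L$rowlab                     # left edge of the column grid
  colX <- x0 + (seq_len(nC) - 1L) * L$cell   # column left edges
  colCX <- colX + L$cell / 2                 # column centers
  gridW <- nC * L$cell
  sideX <- x0 + gridW + L$gap
  totalW <- (if (haveRowSide) sideX + L$side else x0 + gridW) + L$pad

  ## vertical frame
  y <- L$pad
  ySideCols <- y
  if (haveColSide) y <- y + L$side + L$gap
  yColLab <- y
  y <- y + L$collab + 2
  yMain <- y
  rowH <- rep(L$cell, nR)
  if (config@showHeatmap) rowH[rows %in% expanded] <- L$expanded
  if (!haveRowsArea) rowH <- rep(0, nR)
  rowY <- yMain + cumsum(c(0, rowH))[seq_len(nR)]
  yAfterRows <- yMain + sum(rowH)
  yLegend <- yAfterRows + L$gap
  totalH <- yLegend + L$legend + L$pad

  catColors <- assignColors(cols, config@colorOverrides,
                            config@categoricalScheme)
  rowCatColors <- assignColors(rows, config@colorOverrides,
                               config@categoricalScheme)
  heatCol <- matrix(.heatRamp(v, config@heatmapScheme), nrow = nR)

  panels <- list()

  ## column sidebar (totals / stacked segments / violins per column)
  if (haveColSide) {
    colTot <- colSums(v)
    maxTot <- max(colTot, 0)
    marks <- switch(config@sidePanelCols,
      bars = {
        bh <- if (maxTot > 0) L$side * colTot / maxTot else rep(0, nC)
        bw <- L$cell * 0.7
        .marksDF(id = .markId("col_sidebar", "bar_rect", NA, cols),
                 kind = "bar_rect", row = NA_character_, col = cols,
                 value = unname(colTot), color = unname(catColors),
                 x = colCX - bw / 2, y = ySideCols + L$side - bh,
                 w = rep(bw, nC), h = bh)
      },
      stacked_bars = {
        dfs <- lapply(seq_len(nC), function(j) {
          vals <- v[, j]
          tot <- sum(vals)
          hts <- if (maxTot > 0) L$side * vals / maxTot else rep(0, nR)
          yTop <- ySideCols + L$side - rev(cumsum(rev(hts)))
          bw <- L$cell * 0.7
          .marksDF(id = .markId("col_sidebar", "stacked_segment", rows,
                                cols[j]),
                   kind = "stacked_segment", row = rows, col = cols[j],
                   value = unname(vals), color = unname(rowCatColors),
                   x = rep(colCX[j] - bw / 2, nR), y = yTop,
                   w = rep(bw, nR), h = hts)
        })
        do.call(rbind, dfs)
      },
      violins = {
        dfs <- lapply(seq_len(nC), function(j) {
          out <- .violinOutline(v[, j])
          bx <- colX[j] + 1; bw <- L$cell - 2
          .marksDF(id = .markId("col_sidebar", "violin_path", NA, cols[j]),
                   kind = "violin_path", row = NA_character_, col = cols[j],
                   value = unname(out$stats["vmed"]),
                   color = unname(catColors[j]),
                   x = bx, y = ySideCols, w = bw, h = L$side,
                   vmin = out$stats["vmin"], vmed = out$stats["vmed"],
                   vmax = out$stats["vmax"],
                   px = list(bx + out$v * bw),
                   py = list(ySideCols + L$side - out$u * L$side))
        })
        do.call(rbind, dfs)
      })
    panels <- c(panels, list(.panel("col_sidebar", "col_sidebar",
      c(x = x0, y = ySideCols, w = gridW, h = L$side), marks)))
  }

  ## column axis labels
  colAxis <- .marksDF(id = .markId("col_axis", "text", NA, cols),
                      kind = "text", row = NA_character_, col = cols,
                      value = NA_real_, color = tc$fg,
                      x = colCX, y = rep(yColLab + L$collab - 4, nC),
                      w = rep(0, nC), h = rep(0, nC))
  panels <- c(panels, list(.panel("col_axis", "axis",
    c(x = x0, y = yColLab, w = gridW, h = L$collab), colAxis)))

  ## heatmap (expanded rows replaced by their own panels)
  if (config@showHeatmap) {
    plain <- setdiff(rows, expanded)
    if (length(plain)) {
      ri <- match(plain, rows)
      idx <- expand.grid(i = ri, j = seq_len(nC))
      val <- v[cbind(idx$i, idx$j)]
      kind <- ifelse(val == 0, "absent_glyph", "cell_rect")
      col <- ifelse(val == 0, tc$absent, heatCol[cbind(idx$i, idx$j)])
      marks <- .marksDF(
        id = .markId("heatmap", kind, rows[idx$i], cols[idx$j]),
        kind = kind, row = rows[idx$i], col = cols[idx$j],
        value = val, color = col,
        x = colX[idx$j], y = rowY[idx$i],
        w = rep(L$cell, nrow(idx)), h = rep(L$cell, nrow(idx)))
    } else {
      marks <- .marksDF()
    }
    panels <- c(panels, list(.panel("heatmap", "heatmap",
      c(x = x0, y = yMain, w = gridW, h = sum(rowH)), marks)))
    for (r in expanded) {
      i <- match(r, rows)
      vals <- v[i, ]
      vmax <- max(vals, 0)
      bh <- if (vmax > 0) (L$expanded - 6) * vals / vmax else rep(0, nC)
      bw <- L$cell * 0.7
      marks <- .marksDF(
        id = .markId(paste0("expanded:", r), "bar_rect", r, cols),
        kind = "bar_rect", row = r, col = cols,
        value = unname(vals), color = unname(catColors),
        x = colCX - bw / 2, y = rowY[i] + L$expanded - 3 - bh,
        w = rep(bw, nC), h = bh)
      panels <- c(panels, list(.panel(paste0("expanded:", r), "expanded_row",
        c(x = x0, y = rowY[i], w = gridW, h = L$expanded), marks)))
    }
  }

  ## row axis labels
  if (haveRowsArea) {
    rowAxis <- .marksDF(id = .markId("row_axis", "text", rows, NA),
                        kind = "text", row = rows, col = NA_character_,
                        value = NA_real_, color = tc$fg,
                        x = rep(L$pad + L$rowlab - 6, nR),
                        y = rowY + rowH / 2,
                        w = rep(0, nR), h = rep(0, nR))
    panels <- c(panels, list(.panel("row_axis", "axis",
      c(x = L$pad, y = yMain, w = L$rowlab, h = sum(rowH)), rowAxis)))
  }

  ## row sidebar
  if (haveRowSide) {
    rowTot <- rowSums(v)
    maxTot <- max(rowTot, 0)
    marks <- switch(config@sidePanelRows,
      bars = {
        bw <- if (maxTot > 0) L$side * rowTot / maxTot else rep(0, nR)
        bt <- pmin(rowH, L$cell) * 0.7
        .marksDF(id = .markId("row_sidebar", "bar_rect", rows, NA),
                 kind = "bar_rect", row = rows, col = NA_character_,
                 value = unname(rowTot), color = unname(rowCatColors),
                 x = rep(sideX, nR), y = rowY + (rowH - bt) / 2,
                 w = bw, h = bt)
      },
      stacked_bars = {
        dfs <- lapply(seq_len(nR), function(i) {
          vals <- v[i, ]
          wds <- if (maxTot > 0) L$side * vals / maxTot else rep(0, nC)
          xl <- sideX + cumsum(c(0, wds))[seq_len(nC)]
          bt <- min(rowH[i], L$cell) * 0.7
          .marksDF(id = .markId("row_sidebar", "stacked_segment", rows[i],
                                cols),
                   kind = "stacked_segment", row = rows[i], col = cols,
                   value = unname(vals), color = unname(catColors),
                   x = xl, y = rep(rowY[i] + (rowH[i] - bt) / 2, nC),
                   w = wds, h = rep(bt, nC))
        })
        do.call(rbind, dfs)
      },
      violins = {
        dfs <- lapply(seq_len(nR), function(i) {
          out <- .violinOutline(v[i, ])
          by <- rowY[i] + 1; bh <- rowH[i] - 2
          .marksDF(id = .markId("row_sidebar", "violin_path", rows[i], NA),
                   kind = "violin_path", row = rows[i], col = NA_character_,
                   value = unname(out$stats["vmed"]),
                   color = unname(rowCatColors[i]),
                   x = sideX, y = by, w = L$side, h = bh,
                   vmin = out$stats["vmin"], vmed = out$stats["vmed"],
                   vmax = out$stats["vmax"],
                   px = list(sideX + out$u * L$side),
                   py = list(by + out$v * bh))
        })
        do.call(rbind, dfs)
      })
    panels <- c(panels, list(.panel("row_sidebar", "row_sidebar",
      c(x = sideX, y = yMain, w = L$side, h = sum(rowH)), marks)))
  }

  ## legend: value-scale swatches plus the active transform, so exports are
  ## self-describing
  rng <- range(v)
  nSw <- 6L
  swVals <- seq(rng[1], rng[2], length.out = nSw)
  swCols <- .heatRamp(swVals, config@heatmapScheme)
  swX <- L$pad + (seq_len(nSw) - 1L) * (L$cell + 2)
  legendMarks <- rbind(
    .marksDF(id = .markId("legend", "cell_rect", NA, as.character(seq_len(nSw))),
             kind = "cell_rect", row = NA_character_,
             col = as.character(seq_len(nSw)),
             value = swVals, color = swCols,
             x = swX, y = rep(yLegend + 6, nSw),
             w = rep(L$cell, nSw), h = rep(L$cell, nSw)),
    .marksDF(id = .markId("legend", "text", NA, "scale"),
             kind = "text", row = NA_character_, col = "scale",
             value = NA_real_, color = tc$fg,
             x = swX[nSw] + L$cell + 10, y = yLegend + 6 + L$cell / 2,
             w = 0, h = 0))
  panels <- c(panels, list(.panel("legend", "legend",
    c(x = L$pad, y = yLegend, w = totalW - 2 * L$pad, h = L$legend),
    legendMarks)))

  new("FigureModel", panels = panels,
      meta = list(width = totalW, height = totalH,
                  valueKind = valueKind(x), orientation = orientation(x),
                  theme = config@theme, background = tc$bg, fg = tc$fg,
                  heatmapScheme = config@heatmapScheme,
                  categoricalScheme = config@categoricalScheme,
                  valueRange = rng,
                  scaleLabel = sprintf("%s [%.3g, %.3g]", valueKind(x),
                                       rng[1], rng[2]),
                  nRows = nR, nCols = nC,
                  rowLabels = rows, colLabels = cols,
                  colCenters = colCX, rowTops = rowY, rowHeights = rowH))
})

#' Compose the transform pipeline described by a ViewConfig
#'
#' Applies, in this fixed order: filters, metadata grouping or hierarchy
#' collapse, normalization, log transform, sorting, transposition. The
#' fixed order keeps views reproducible and statistically sound (grouping
#' fractions would be wrong).
#'
#' @param x a [CellPopDataset-class] holding counts.
#' @param config a [ViewConfig-class].
#' @return the transformed [CellPopDataset-class].
#' @export
setMethod("applyView", "CellPopDataset", function(x, config) {
  stopifnot(is(config, "ViewConfig"))
  validObject(config)
  for (f in config@filters) x <- filterBy(x, f)
  if (length(config@groupField))
    x <- groupBy(x, config@groupAxis, config@groupField)
  if (!is.na(config@collapseDepth))
    x <- collapseToDepth(x, config@collapseDepth)
  if (config@normalization != "none")
    x <- normalize(x, config@normalization)
  if (config@log)
    x <- logTransform(x, base = config@logBase,
                      pseudocount = config@pseudocount)
  if (length(config@sortKeys)) x <- sortBy(x, config@sortKeys)
  if (config@transposed) x <- transposeView(x)
  x
})

#' Panels of a FigureModel
#' @param fig a [FigureModel-class].
#' @return the list of panels.
#' @export
figurePanels <- function(fig) {
  stopifnot(is(fig, "FigureModel"))
  fig@panels
}

#' Figure-level metadata of a FigureModel
#' @param fig a [FigureModel-class].
#' @return the metadata list (width, height, value kind, theme, ...).
#' @export
figureMeta <- function(fig) {
  stopifnot(is(fig, "FigureModel"))
  fig@meta
}

#' All marks of a FigureModel as one data.frame
#' @param fig a [FigureModel-class].
#' @param panelKind optional panel kind(s) to restrict to.
#' @return data.frame of marks with a `panel_id` column prepended.
#' @export
figureMarks <- function(fig, panelKind = NULL) {
  stopifnot(is(fig, "FigureModel"))
  ps <- fig@panels
  if (!is.null(panelKind)) ps <- Filter(function(p) p$kind %in% panelKind, ps)
  dfs <- lapply(ps, function(p) {
    if (nrow(p$marks) == 0L) return(NULL)
    cbind(panel_id = p$panel_id, p$marks, stringsAsFactors = FALSE)
  })
  dfs <- Filter(Negate(is.null), dfs)
  if (!length(dfs)) return(cbind(panel_id = character(), .marksDF()))
  do.call(rbind, dfs)
}

setMethod("show", "FigureModel", function(object) {
  cat(sprintf("FigureModel: %d panel(s), %.0f x %.0f units [%s]\n",
              length(object@panels), object@meta$width, object@meta$height,
              object@meta$valueKind))
  for (p in object@panels)
    cat(sprintf("  %-14s %-12s %4d mark(s)\n", p$panel_id, p$kind,
                nrow(p$marks)))
})
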