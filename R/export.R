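## Figure export. The SVG writer emits one addressable element per mark
## with a stable id ("panel/kind/row/col"), fixed numeric formatting and no
## timestamps, so the same FigureModel always yields byte-identical SVG.
## PNG is rasterized from the same model on an R bitmap device.

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

.num <- function(x) sprintf("%.2f", x + 0)

.svgMark <- function(m, fg) {
  id <- .xmlEscape(m$id)
  switch(m$kind,
    cell_rect = ,
    bar_rect = ,
    stacked_segment = sprintf(
      '<rect id="%s" class="%s" x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
      id, m$kind, .num(m$x), .num(m$y), .num(m$w), .num(m$h),
      .toHex(m$color)),
    absent_glyph = {
      cx <- m$x + m$w / 2; cy <- m$y + m$h / 2; r <- m$w / 6
      sprintf(
        '<circle id="%s" class="absent_glyph" cx="%s" cy="%s" r="%s" fill="none" stroke="%s" stroke-width="0.75"/>',
        id, .num(cx), .num(cy), .num(r), .toHex(m$color))
    },
    violin_path = {
      px <- m$px[[1L]]; py <- m$py[[1L]]
      d <- paste0("M", .num(px[1L]), ",", .num(py[1L]), " L",
                  paste(paste0(.num(px[-1L]), ",", .num(py[-1L])),
                        collapse = " L"), " Z")
      sprintf('<path id="%s" class="violin_path" d="%s" fill="%s" fill-opacity="0.85"/>',
              id, d, .toHex(m$color))
    },
    text = {
      label <- if (!is.na(m$row)) m$row
               else if (!is.na(m$col)) m$col else ""
      anchor <- if (!is.na(m$row) && is.na(m$col)) "end" else "middle"
      sprintf(
        '<text id="%s" class="text" x="%s" y="%s" font-family="sans-serif" font-size="9" text-anchor="%s" fill="%s">%s</text>',
        id, .num(m$x), .num(m$y), anchor, .toHex(m$color),
        .xmlEscape(label))
    },
    stop(sprintf("unknown mark kind '%s'", m$kind)))
}

.writeSVG <- function(fig, path) {
  meta <- fig@meta
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
            .num(meta$width), .num(meta$height),
            .num(meta$width), .num(meta$height)),
    sprintf('<rect id="background" x="0" y="0" width="%s" height="%s" fill="%s"/>',
            .num(meta$width), .num(meta$height), .toHex(meta$background)))
  for (p in fig@panels) {
    lines <- c(lines, sprintf('<g id="%s" class="panel %s">',
                              .xmlEscape(p$panel_id), p$kind))
    m <- p$marks
    if (nrow(m)) {
      special <- p$kind == "legend" & m$kind == "text"
      for (i in seq_len(nrow(m))) {
        mk <- m[i, , drop = FALSE]
        mk <- list(id = mk$id, kind = mk$kind, row = mk$row, col = mk$col,
                   value = mk$value, color = mk$color, x = mk$x, y = mk$y,
                   w = mk$w, h = mk$h, px = mk$px, py = mk$py)
        line <- if (special[i])
          sprintf('<text id="%s" class="text" x="%s" y="%s" font-family="sans-serif" font-size="9" text-anchor="start" fill="%s">%s</text>',
                  .xmlEscape(mk$id), .num(mk$x), .num(mk$y),
                  .toHex(mk$color), .xmlEscape(meta$scaleLabel))
        else .svgMark(mk, meta$fg)
        lines <- c(lines, line)
      }
    }
    lines <- c(lines, "</g>")
  }
  lines <- c(lines, "</svg>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

.renderPNG <- function(fig, path, dpi) {
  meta <- fig@meta
  scale <- dpi / 96
  grDevices::png(path, width = max(1, round(meta$width * scale)),
                 height = max(1, round(meta$height * scale)),
                 res = dpi, type = "cairo")
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot(NA, xlim = c(0, meta$width), ylim = c(meta$height, 0),
                 axes = FALSE, xlab = "", ylab = "", asp = 1)
  graphics::rect(0, meta$height, meta$width, 0, col = meta$background,
                 border = NA)
  for (p in fig@panels) {
    m <- p$marks
    for (i in seq_len(nrow(m))) {
      kind <- m$kind[i]
      if (kind %in% c("cell_rect", "bar_rect", "stacked_segment")) {
        graphics::rect(m$x[i], m$y[i] + m$h[i], m$x[i] + m$w[i], m$y[i],
                       col = m$color[i], border = NA)
      } else if (kind == "absent_glyph") {
        graphics::points(m$x[i] + m$w[i] / 2, m$y[i] + m$h[i] / 2, pch = 1,
                         cex = 0.4, col = m$color[i])
      } else if (kind == "violin_path") {
        graphics::polygon(m$px[[i]], m$py[[i]], col = m$color[i],
                          border = NA)
      } else if (kind == "text") {
        label <- if (p$kind == "legend") meta$scaleLabel
                 else if (!is.na(m$row[i])) m$row[i]
                 else if (!is.na(m$col[i])) m$col[i] else ""
        adj <- if (!is.na(m$row[i]) && is.na(m$col[i])) c(1, 0.5)
               else c(0.5, 0.5)
        graphics::text(m$x[i], m$y[i], label, cex = 0.5, adj = adj,
                       col = m$color[i])
      }
    }
  }
  invisible(path)
}

#' Export a FigureModel to SVG or PNG
#'
#' SVG output carries one addressable element per mark with a stable id of
#' the form `panel/kind/row/col` and contains no timestamps: exporting the
#' same model twice gives byte-identical files. PNG is rasterized at the
#' requested resolution (layout units are mapped at 96 units per inch).
#'
#' @param fig a [FigureModel-class] from [layoutFigure()].
#' @param path destination file.
#' @param format `"svg"` or `"png"`; inferred from the path extension when
#'   `NULL`.
#' @param dpi raster resolution for PNG (>= 72; ignored for SVG).
#' @return `path`, invisibly.
#' @export
exportFigure <- function(fig, path, format = NULL, dpi = 96) {
  stopifnot(is(fig, "FigureModel"))
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (!nzchar(format))
      stopUsage("cannot infer format from '%s'; pass format=", path)
  }
  if (!format %in% c("svg", "png"))
    stopUsage("unsupported format '%s' (svg or png)", format)
  dpi <- .assertNumber(dpi, "dpi")
  if (dpi < 72) stopUsage("dpi must be >= 72")
  dir <- dirname(path)
  if (!dir.exists(dir))
    stopInput("directory does not exist: %s", dir)
  if (format == "svg") .writeSVG(fig, path) else .renderPNG(fig, path, dpi)
  invisible(path)
}
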