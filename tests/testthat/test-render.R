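test_that("applyView composes the fixed pipeline order", {
  ds <- fixtureF1()
  shown <- applyView(ds, viewConfig())
  # default view: counts unchanged, rows sorted by total descending
  expect_identical(rowLabels(shown), c("A", "B"))
  expect_identical(popValues(shown)[c("A", "B"), ], popValues(ds))

  cfg <- viewConfig(transposed = TRUE, sortKeys = list())
  once <- applyView(ds, cfg)
  expect_identical(orientation(once), "celltypes_as_rows")
  twice <- transposeView(once)
  expect_identical(popValues(twice), popValues(ds))

  # random chains equal the manual composition in the documented order
  for (seed in 1:8) {
    a <- randAtlas(seed)
    cfg <- viewConfig(
      filters = list(filterSpec("rows", "age", "numeric_range", c(30, 75))),
      collapseDepth = 1,
      normalization = "within_sample",
      log = TRUE, logBase = 2,
      sortKeys = list(sortKey("rows", "alphabetical",
                              direction = "descending")),
      transposed = (seed %% 2 == 0))
    got <- applyView(a$dataset, cfg)
    manual <- filterBy(a$dataset,
                       filterSpec("rows", "age", "numeric_range", c(30, 75)))
    manual <- collapseToDepth(manual, 1)
    manual <- normalize(manual, "within_sample")
    manual <- logTransform(manual, base = 2)
    manual <- sortBy(manual, sortKey("rows", "alphabetical",
                                     direction = "descending"))
    if (seed %% 2 == 0) manual <- transposeView(manual)
    expect_identical(popValues(got), popValues(manual))
    expect_identical(valueKind(got), valueKind(manual))
  }
})

test_that("heatmap panel carries one mark per cell, zeros as absent glyphs", {
  ds <- fixtureF1()
  cfg <- viewConfig(sortKeys = list())
  fig <- layoutFigure(ds, cfg)
  hm <- figureMarks(fig, "heatmap")
  expect_equal(nrow(hm), 4)
  expect_setequal(paste(hm$row, hm$col), c("A T", "A B", "B T", "B B"))
  expect_identical(hm$kind[hm$row == "B" & hm$col == "T"], "absent_glyph")
  expect_equal(sum(hm$kind == "cell_rect"), 3)
  rs <- figureMarks(fig, "row_sidebar")
  expect_equal(rs$value[match(c("A", "B"), rs$row)], c(4, 2))
  cs <- figureMarks(fig, "col_sidebar")
  expect_equal(cs$value[match(c("T", "B"), cs$col)], c(3, 3))
})

test_that("layout is deterministic and heatmap colors are monotone in value", {
  a <- randAtlas(4)
  cfg <- viewConfig()
  shown <- applyView(a$dataset, cfg)
  f1 <- layoutFigure(shown, cfg)
  f2 <- layoutFigure(shown, cfg)
  expect_identical(figurePanels(f1), figurePanels(f2))
  hm <- figureMarks(f1, "heatmap")
  cells <- hm[hm$kind == "cell_rect", ]
  pal <- grDevices::hcl.colors(256, "Viridis")
  idx <- match(cells$color, pal)
  expect_false(anyNA(idx))
  ord <- order(cells$value)
  expect_true(all(diff(idx[ord]) >= 0))   # monotone value -> color index
})

test_that("expanded rows replace their strip with aligned bars", {
  ds <- fixtureF1()
  cfg <- viewConfig(expandedRows = "A", sortKeys = list())
  fig <- layoutFigure(ds, cfg)
  hm <- figureMarks(fig, "heatmap")
  expect_equal(nrow(hm), 2)               # only row B remains in the heatmap
  exp <- figureMarks(fig, "expanded_row")
  expect_equal(nrow(exp), 2)              # one bar per column
  expect_equal(exp$value[match(c("T", "B"), exp$col)], c(3, 1))
  # bar centers coincide with heatmap column centers
  hmB <- hm[match(exp$col, hm$col), ]
  expect_equal(exp$x + exp$w / 2, hmB$x + hmB$w / 2)
  expect_error(layoutFigure(ds, viewConfig(expandedRows = "Z",
                                           sortKeys = list())),
               "Z", class = "scpop_input_error")
})

test_that("stacked-bar segments conserve totals and fractions", {
  for (seed in 1:10) {
    a <- randAtlas(seed)
    cfg <- viewConfig(sidePanelRows = "stacked_bars", sortKeys = list())
    fig <- layoutFigure(a$dataset, cfg)
    seg <- figureMarks(fig, "row_sidebar")
    sums <- tapply(seg$value, seg$row, sum)
    tot <- rowSums(popValues(a$dataset))
    expect_equal(as.vector(sums[names(tot)]), unname(tot),
                 tolerance = 1e-9)

    p <- stackedBarPreset()
    shown <- applyView(a$dataset, p)
    figp <- layoutFigure(shown, p)
    segp <- figureMarks(figp, "col_sidebar")
    sums1 <- tapply(segp$value, segp$col, sum)
    expect_true(all(abs(sums1 - 1) < 1e-9))
  }
})

test_that("the stacked-bar preset reproduces within-sample fractions without a heatmap", {
  ds <- fixtureF1()
  p <- stackedBarPreset()
  shown <- applyView(ds, p)
  fig <- layoutFigure(shown, p)
  kinds <- vapply(figurePanels(fig), `[[`, "", "kind")
  expect_false("heatmap" %in% kinds)
  seg <- figureMarks(fig, "col_sidebar")
  expect_equal(seg$value[seg$col == "A"][match(c("T", "B"),
                                               seg$row[seg$col == "A"])],
               c(0.75, 0.25))
  expect_equal(sort(seg$value[seg$col == "B"]), c(0, 1))
  # preset equivalence: segment values equal normalize(within_sample)
  frac <- popValues(normalize(ds, "within_sample"))
  for (i in seq_len(nrow(seg)))
    expect_equal(seg$value[i], frac[seg$col[i], seg$row[i]])
})

test_that("violin marks carry the column order statistics", {
  a <- randAtlas(6)
  cfg <- viewConfig(sidePanelCols = "violins", sortKeys = list())
  fig <- layoutFigure(a$dataset, cfg)
  vio <- figureMarks(fig, "col_sidebar")
  v <- popValues(a$dataset)
  for (i in seq_len(nrow(vio))) {
    vals <- sort(v[, vio$col[i]])        # order-statistics oracle
    n <- length(vals)
    med <- if (n %% 2) vals[[(n + 1) / 2]] else mean(vals[n / 2 + 0:1])
    expect_equal(vio$vmin[i], vals[[1]])
    expect_equal(vio$vmax[i], vals[[n]])
    expect_equal(vio$vmed[i], med)
    expect_gte(length(vio$px[[i]]), 4)
  }
})

test_that("SVG export is addressable, complete and byte-stable", {
  a <- randAtlas(12)
  cfg <- viewConfig()
  shown <- applyView(a$dataset, cfg)
  fig <- layoutFigure(shown, cfg)
  p1 <- withr::local_tempfile(fileext = ".svg")
  p2 <- withr::local_tempfile(fileext = ".svg")
  exportFigure(fig, p1)
  exportFigure(fig, p2)
  expect_identical(readBin(p1, "raw", file.size(p1) + 10),
                   readBin(p2, "raw", file.size(p2) + 10))
  nR <- figureMeta(fig)$nRows; nC <- figureMeta(fig)$nCols
  expect_equal(countSvgMarks(p1, "heatmap/"), nR * nC)
  expect_equal(countSvgMarks(p1, "row_sidebar/"), nR)
  expect_equal(countSvgMarks(p1, "col_sidebar/"), nC)
  # model-vs-file count over every panel
  all <- figureMarks(fig)
  expect_equal(countSvgMarks(p1, ""), nrow(all) + 1L)   # + background
})

test_that("PNG export writes a raster at the requested size", {
  ds <- fixtureF1()
  cfg <- viewConfig(sortKeys = list())
  fig <- layoutFigure(ds, cfg)
  p <- withr::local_tempfile(fileext = ".png")
  exportFigure(fig, p, dpi = 144)
  img <- png::readPNG(p)
  expect_equal(dim(img)[2], round(figureMeta(fig)$width * 144 / 96))
  expect_error(exportFigure(fig, p, format = "pdf"),
               class = "scpop_usage_error")
  expect_error(exportFigure(fig, "no/such/dir/out.svg"),
               class = "scpop_input_error")
})

test_that("assignColors is deterministic, override-aware and cycles the scheme", {
  labs <- paste0("t", 1:12)
  c1 <- assignColors(labs)
  c2 <- assignColors(labs)
  expect_identical(c1, c2)
  ov <- assignColors(c("T", "B"), overrides = c(T = "#ff0000"))
  expect_identical(unname(ov["T"]), "#ff0000")
  base <- grDevices::palette.colors(palette = "Okabe-Ito")
  # modular-index oracle for cycling past the palette size
  for (i in seq_along(labs)) {
    expected <- grDevices::col2rgb(base[((i - 1) %% length(base)) + 1])
    expect_identical(unname(grDevices::col2rgb(c1[i])), unname(expected))
  }
  expect_error(assignColors("T", overrides = c(T = "notacolor#")),
               class = "scpop_config_error")
})
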