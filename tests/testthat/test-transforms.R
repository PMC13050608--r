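test_that("normalization divides by sample or cell-type totals", {
  ds <- fixtureF1()
  expect_equal(unname(popValues(normalize(ds, "within_sample"))),
               rbind(c(0.75, 0.25), c(0, 1)))
  expect_equal(unname(popValues(normalize(ds, "within_celltype"))),
               rbind(c(1, 1 / 3), c(0, 2 / 3)))
  expect_identical(popValues(normalize(ds, "none")), popValues(ds))
  expect_identical(valueKind(normalize(ds, "within_sample")),
                   "fraction_within_sample")
  # transforms always start from counts
  expect_error(normalize(normalize(ds, "within_sample"), "within_sample"),
               class = "scpop_transform_error")
})

test_that("all-zero samples stay all-zero under normalization", {
  m <- populationMatrix(matrix(c(2, 0, 2, 0), 2,
                               dimnames = list(c("A", "Z"), c("x", "y"))))
  ds <- cellPopDataset(m)
  f <- popValues(normalize(ds, "within_sample"))
  expect_equal(unname(f["Z", ]), c(0, 0))
  expect_equal(sum(f["A", ]), 1)
})

test_that("normalization sums hold on random atlases", {
  for (seed in 1:30) {
    a <- randAtlas(seed)
    ws <- popValues(normalize(a$dataset, "within_sample"))
    expect_true(all(abs(rowSums(ws) - 1) < 1e-9))
    wc <- popValues(normalize(a$dataset, "within_celltype"))
    tot <- colSums(popValues(a$dataset))
    expect_true(all(abs(colSums(wc)[tot > 0] - 1) < 1e-9))
    expect_true(all(colSums(wc)[tot == 0] == 0))
  }
})

test_that("logTransform matches elementwise recomputation and maps 0 to 0", {
  ds <- fixtureF1()
  lt <- logTransform(ds, base = 10, pseudocount = 1)
  expect_identical(valueKind(lt), "log_count")
  expect_equal(popValues(lt)["B", "T"], 0)
  m99 <- populationMatrix(matrix(99, 1, 1, dimnames = list("s", "t")))
  expect_equal(unname(popValues(logTransform(cellPopDataset(m99)))),
               matrix(2))
  a <- randAtlas(3)
  got <- popValues(logTransform(a$dataset, base = 2, pseudocount = 0.5))
  v <- popValues(a$dataset)
  expect_equal(got, log2(v + 0.5), tolerance = 1e-12)
  expect_identical(valueKind(logTransform(normalize(a$dataset,
                                                    "within_sample"))),
                   "log_fraction")
})

test_that("logTransform rejects bad pseudocounts and double transforms", {
  ds <- fixtureF1()   # has a zero count
  expect_error(logTransform(ds, pseudocount = 0),
               class = "scpop_transform_error")
  expect_error(logTransform(logTransform(ds)),
               class = "scpop_transform_error")
})

test_that("logTransform is strictly monotone", {
  a <- randAtlas(9)
  v <- as.vector(popValues(a$dataset))
  lv <- as.vector(popValues(logTransform(a$dataset)))
  ord <- order(v)
  expect_true(all(diff(lv[ord])[diff(v[ord]) > 0] > 0))
})

test_that("sorting matches a comparator oracle, with missing metadata last", {
  for (seed in 1:10) {
    a <- randAtlas(seed, n_samples = 8)
    ds <- a$dataset
    age <- sampleMeta(ds)$age
    age[sample(length(age), 2)] <- NA
    ds@sampleMeta$age <- age
    sorted <- sortBy(ds, list(
      sortKey("rows", "metadata_field", field = "age"),
      sortKey("rows", "total_count", direction = "descending")))
    keys <- list(list(values = age, descending = FALSE),
                 list(values = rowSums(popValues(ds)), descending = TRUE))
    expect_identical(rowLabels(sorted), rowLabels(ds)[oracleOrder(keys)])
    # permutation: the multiset of (label, vector) pairs is unchanged
    expect_identical(popValues(sorted)[rowLabels(ds), ], popValues(ds))
  }
})

test_that("alphabetical and total-count sorts order labels as stated", {
  m <- populationMatrix(matrix(c(1, 5, 2, 1, 1, 1), 3,
                               dimnames = list(c("b", "a", "c"),
                                               c("x", "y"))))
  ds <- cellPopDataset(m)
  expect_identical(rowLabels(sortBy(ds, sortKey("rows", "alphabetical"))),
                   c("a", "b", "c"))
  # totals: a = 6, c = 3, b = 2
  expect_identical(rowLabels(sortBy(ds, sortKey("rows", "total_count",
                                                direction = "descending"))),
                   c("a", "c", "b"))
  # ties broken by original order: equal totals keep b before c
  tie <- cellPopDataset(populationMatrix(matrix(c(1, 5, 1, 1, 1, 1), 3,
    dimnames = list(c("b", "a", "c"), c("x", "y")))))
  expect_identical(rowLabels(sortBy(tie, sortKey("rows", "total_count",
                                                 direction = "descending"))),
                   c("a", "b", "c"))
})

test_that("hierarchy sort orders cell types depth-first and needs a hierarchy", {
  a <- randAtlas(5)
  sorted <- sortBy(a$dataset, sortKey("cols", "hierarchy"))
  h <- hierarchy(a$dataset)
  expect_identical(colLabels(sorted),
                   intersect(hierarchyOrder(h), colLabels(a$dataset)))
  noH <- a$dataset; noH@hierarchy <- NULL
  expect_error(sortBy(noH, sortKey("cols", "hierarchy")),
               class = "scpop_transform_error")
  expect_error(sortBy(a$dataset, sortKey("rows", "metadata_field",
                                         field = "nope")),
               class = "scpop_input_error")
})

test_that("filtering keeps the matching entities in order", {
  ds <- fixtureF1()
  kept <- filterBy(ds, filterSpec("rows", "disease", "keep_values", "covid"))
  expect_identical(rowLabels(kept), "A")
  expect_identical(rownames(sampleMeta(kept)), "A")
  # numeric range spanning everything is the identity on rows
  a <- randAtlas(8)
  all <- filterBy(a$dataset, filterSpec("rows", "age", "numeric_range",
                                        c(0, 200)))
  expect_identical(popValues(all), popValues(a$dataset))
})

test_that("filter survivors equal a set-comprehension oracle; missing handled by mode", {
  for (seed in 1:15) {
    a <- randAtlas(seed)
    ds <- a$dataset
    dis <- sampleMeta(ds)$disease
    dis[1] <- NA
    ds@sampleMeta$disease <- dis
    pick <- sample(unique(stats::na.omit(dis)), 1)
    kept <- filterBy(ds, filterSpec("rows", "disease", "keep_values", pick))
    oracle <- rowLabels(ds)[vapply(seq_along(dis), function(i)
      !is.na(dis[i]) && dis[i] %in% pick, logical(1))]
    expect_identical(rowLabels(kept), oracle)
    dropped <- filterBy(ds, filterSpec("rows", "disease", "drop_values", pick))
    oracleDrop <- rowLabels(ds)[vapply(seq_along(dis), function(i)
      is.na(dis[i]) || !dis[i] %in% pick, logical(1))]
    expect_identical(rowLabels(dropped), oracleDrop)
  }
})

test_that("successive keep filters compose as intersection", {
  a <- randAtlas(21, n_samples = 8)
  ds <- a$dataset
  lv <- unique(sampleMeta(ds)$disease)
  V <- lv; W <- lv[1]
  twice <- filterBy(filterBy(ds, filterSpec("rows", "disease",
                                            "keep_values", V)),
                    filterSpec("rows", "disease", "keep_values", W))
  once <- filterBy(ds, filterSpec("rows", "disease", "keep_values",
                                  intersect(V, W)))
  expect_identical(popValues(twice), popValues(once))
})

test_that("groupBy sums counts per category in first-appearance order", {
  m <- populationMatrix(matrix(c(1, 2, 5, 0, 2, 1), 3,
                               dimnames = list(c("A", "B", "C"),
                                               c("x", "y"))))
  ds <- cellPopDataset(m, sampleMeta = S4Vectors::DataFrame(
    dataset = c("d1", "d1", "d2"), row.names = c("A", "B", "C")))
  g <- groupBy(ds, "rows", "dataset")
  expect_identical(rowLabels(g), c("d1", "d2"))
  expect_equal(unname(popValues(g)), rbind(c(3, 2), c(5, 1)))
  expect_equal(sum(popValues(g)), sum(popValues(ds)))   # conservation
  # a single category collapses to the column totals
  ds1 <- cellPopDataset(m, sampleMeta = S4Vectors::DataFrame(
    dataset = rep("all", 3), row.names = c("A", "B", "C")))
  expect_equal(unname(popValues(groupBy(ds1, "rows", "dataset"))),
               matrix(colSums(popValues(ds)), 1))
})

test_that("groupBy matches an accumulation oracle and rejects bad input", {
  for (seed in 1:15) {
    a <- randAtlas(seed)
    g <- groupBy(a$dataset, "rows", "disease")
    v <- popValues(a$dataset)
    dis <- sampleMeta(a$dataset)$disease
    for (cat in rowLabels(g)) {
      acc <- rep(0, ncol(v))
      for (i in which(dis == cat)) acc <- acc + v[i, ]
      expect_equal(unname(popValues(g)[cat, ]), unname(acc))
    }
    expect_equal(sum(popValues(g)), sum(v))
  }
  a <- randAtlas(2)
  expect_error(groupBy(a$dataset, "rows", "age"),
               class = "scpop_transform_error")
  expect_error(groupBy(normalize(a$dataset, "within_sample"), "rows",
                       "disease"),
               class = "scpop_transform_error")
})

test_that("collapseToDepth merges counts into ancestors and conserves totals", {
  ds <- fixtureF1()
  c0 <- collapseToDepth(ds, 0)
  expect_identical(colLabels(c0), "lymphocyte")
  expect_equal(unname(popValues(c0)), cbind(c(4, 2)))
  # depth beyond the leaves changes nothing except possibly label order
  c9 <- collapseToDepth(ds, 9)
  expect_equal(popValues(c9)[, colLabels(ds)], popValues(ds))
  noH <- ds; noH@hierarchy <- NULL
  expect_error(collapseToDepth(noH, 0), class = "scpop_transform_error")
})

test_that("collapse agrees with an ancestor-walk oracle on random forests", {
  for (seed in 1:15) {
    a <- randAtlas(seed)
    ds <- a$dataset
    h <- hierarchy(ds)
    got <- collapseToDepth(ds, 1)
    v <- popValues(ds)
    depths <- hierarchyDepths(h)
    walk <- function(lab) {            # independent parent-chain walk
      while (depths[[lab]] > 1) lab <- unname(h@parent[[lab]])
      lab
    }
    anc <- vapply(colnames(v), walk, character(1))
    for (node in colLabels(got))
      expect_equal(unname(popValues(got)[, node]),
                   unname(rowSums(v[, anc == node, drop = FALSE])))
    expect_equal(sum(popValues(got)), sum(v))
    expect_identical(colLabels(got),
                     intersect(hierarchyOrder(h), unique(unname(anc))))
  }
})

test_that("transposeView is an involution and swaps indices exactly", {
  ds <- fixtureF1()
  t1 <- transposeView(ds)
  expect_identical(orientation(t1), "celltypes_as_rows")
  expect_equal(unname(popValues(t1)), rbind(c(3, 0), c(1, 2)))
  t2 <- transposeView(t1)
  expect_identical(popValues(t2), popValues(ds))
  expect_identical(orientation(t2), orientation(ds))
  a <- randAtlas(13)
  v <- popValues(a$dataset)
  tv <- popValues(transposeView(a$dataset))
  for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v)))
    expect_identical(tv[j, i], v[i, j])
})

test_that("sample-axis semantics follow the orientation flag", {
  ds <- transposeView(fixtureF1())   # celltypes_as_rows
  ws <- normalize(ds, "within_sample")
  expect_equal(unname(colSums(popValues(ws))), c(1, 1))
  expect_identical(valueKind(ws), "fraction_within_sample")
  expect_identical(sampleLabels(ds), c("A", "B"))
  expect_identical(celltypeLabels(ds), c("T", "B"))
})
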