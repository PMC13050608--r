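test_that("identical seeds give identical atlases", {
  a1 <- generateAtlas(atlasSpec(seed = 11))
  a2 <- generateAtlas(atlasSpec(seed = 11))
  expect_identical(popValues(a1$dataset), popValues(a2$dataset))
  expect_identical(a1$cells, a2$cells)
  expect_identical(as.data.frame(sampleMeta(a1$dataset)),
                   as.data.frame(sampleMeta(a2$dataset)))
  a3 <- generateAtlas(atlasSpec(seed = 12))
  expect_false(identical(popValues(a1$dataset), popValues(a3$dataset)))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(3)
  set.seed(99)
  invisible(generateAtlas(atlasSpec(n_samples = 3, n_celltypes = 4,
                                    seed = 5)))
  expect_identical(runif(3), before)
})

test_that("absence is structural: observed zeros equal the forced set", {
  a <- generateAtlas(atlasSpec(n_samples = 40, n_celltypes = 9,
                               branching = 3, absent_fraction = 0.3,
                               seed = 21))
  expect_gte(sum(a$groundTruth$absent), 50)   # ~0.3 * 360 forced pairs
  expect_identical(popValues(a$dataset) == 0, a$groundTruth$absent)
  # presence flags recover the same set through the public API
  ps <- presenceStats(a$dataset)
  expect_equal(ps$n_samples_present,
               unname(colSums(!a$groundTruth$absent)))
  none <- generateAtlas(atlasSpec(n_samples = 10, n_celltypes = 8,
                                  absent_fraction = 0, seed = 3))
  expect_false(any(none$groundTruth$absent))
  expect_true(all(popValues(none$dataset) > 0))
})

test_that("per-sample totals equal the drawn N and the cells tally back", {
  a <- randAtlas(17)
  expect_equal(unname(rowSums(popValues(a$dataset))),
               unname(a$groundTruth$totals))
  m <- buildPopulationMatrix(a$cells)
  gt <- a$groundTruth$counts
  got <- popValues(m)
  expect_setequal(rownames(got), rownames(gt))
  for (s in rownames(got)) for (t in colnames(got))
    expect_equal(got[s, t], gt[s, t])
  # cell-type columns never observed are exactly the absent-everywhere ones
  expect_setequal(setdiff(colnames(gt), colnames(got)),
                  colnames(gt)[colSums(gt) == 0])
})

test_that("high concentration gives near-uniform compositions", {
  a <- generateAtlas(atlasSpec(n_samples = 20, n_celltypes = 9,
                               branching = 3, dirichlet_alpha = 1000,
                               absent_fraction = 0,
                               total_cells_per_sample = c(log(5000), 0.1),
                               seed = 8))
  v <- popValues(a$dataset)
  frac <- v / rowSums(v)
  p0 <- 1 / ncol(v)
  se <- sqrt(p0 * (1 - p0) / rowSums(v))
  # 3·SE binomial band plus the Dirichlet(1000) spread itself
  tol <- 3 * (se + sqrt(p0 * (1 - p0) / 1001))
  expect_true(all(abs(frac - p0) <= tol))
})

test_that("hierarchies are balanced forests with leaves at the stated depth", {
  a <- generateAtlas(atlasSpec(n_samples = 3, n_celltypes = 7,
                               hierarchy_depth = 3, branching = 2, seed = 2))
  h <- hierarchy(a$dataset)
  d <- hierarchyDepths(h)
  leaves <- celltypeLabels(a$dataset)
  expect_true(all(d[leaves] == 3))
  kids <- table(h@parent)
  expect_true(all(kids <= 2))
  expect_identical(unname(ancestorAtDepth(h, leaves, 0)),
                   as.character(celltypeMeta(a$dataset)$lineage))
})

test_that("infeasible specs are rejected", {
  expect_error(atlasSpec(n_celltypes = 10, hierarchy_depth = 2,
                         branching = 3),
               class = "scpop_usage_error")
  expect_error(atlasSpec(absent_fraction = 1), class = "scpop_usage_error")
  expect_error(atlasSpec(dirichlet_alpha = 0), class = "scpop_usage_error")
})

test_that("the worked fixture has its documented shape", {
  ds <- fixtureF1()
  expect_equal(sum(popValues(ds)), 6)
  expect_identical(sampleMeta(ds)$disease, c("covid", "normal"))
  expect_setequal(hierarchy(ds)@nodes, c("B", "lymphocyte", "T"))
})
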