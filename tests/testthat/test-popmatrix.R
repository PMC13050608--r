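test_that("buildPopulationMatrix tallies cells with first-appearance label order", {
  ct <- cellTable(paste0("c", 1:6),
                  c("A", "A", "A", "A", "B", "B"),
                  c("T", "T", "T", "B", "B", "B"))
  m <- buildPopulationMatrix(ct)
  expect_identical(rownames(popValues(m)), c("A", "B"))
  expect_identical(colnames(popValues(m)), c("T", "B"))
  expect_equal(unname(popValues(m)), rbind(c(3, 1), c(0, 2)))
  expect_identical(valueKind(m), "count")

  single <- buildPopulationMatrix(cellTable("c1", "S", "X"))
  expect_equal(unname(popValues(single)), matrix(1))
  expect_identical(dimnames(popValues(single)), list("S", "X"))
})

test_that("counting agrees with a brute-force tally on seeded random tables", {
  set.seed(42)
  n <- 1000
  samples <- paste0("s", sample.int(4, n, replace = TRUE))
  types <- paste0("t", sample.int(5, n, replace = TRUE))
  ct <- cellTable(paste0("c", seq_len(n)), samples, types)
  m <- popValues(buildPopulationMatrix(ct))
  # independent nested-loop tally
  for (s in rownames(m)) for (t in colnames(m))
    expect_equal(m[s, t], sum(samples == s & types == t))
  expect_equal(sum(m), n)    # conservation
})

test_that("conservation holds across random tables", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(1:400, 1)
    ct <- cellTable(paste0("c", seq_len(n)),
                    sample(letters[1:5], n, replace = TRUE),
                    sample(LETTERS[1:6], n, replace = TRUE))
    expect_equal(sum(popValues(buildPopulationMatrix(ct))), n)
  }
})

test_that("invalid cell tables are rejected and unknown labels reserved", {
  expect_error(cellTable(c("c1", "c1"), c("A", "A"), c("T", "T")),
               class = "scpop_input_error")
  expect_error(cellTable(c("c1", "c1"), c("A", "A"), c("T", "T")), "c1")
  expect_error(cellTable(character(), character(), character()),
               class = "scpop_input_error")
  expect_error(cellTable("c1", "", "T"), class = "scpop_input_error")
  expect_message(ct <- cellTable(c("c1", "c2"), c("A", "A"), c("T", NA)),
                 "unknown")
  expect_identical(ct$celltype, c("T", "unknown"))
  expect_identical(attr(ct, "n_unknown"), 1L)
})

test_that("totalCounts sums per axis and rejects non-count matrices", {
  ds <- fixtureF1()
  expect_equal(unname(totalCounts(ds, "rows")), c(4, 2))
  expect_equal(unname(totalCounts(ds, "cols")), c(3, 3))
  a <- randAtlas(11)
  v <- popValues(a$dataset)
  expect_equal(totalCounts(a$dataset, "rows"), apply(v, 1, sum))
  expect_equal(totalCounts(a$dataset, "cols"), apply(v, 2, sum))
  expect_error(totalCounts(normalize(ds, "within_sample"), "rows"),
               class = "scpop_transform_error")
})

test_that("presenceStats flags absent and universally present cell types", {
  ps <- presenceStats(fixtureF1())
  expect_equal(ps["T", "n_samples_present"], 1L)
  expect_equal(ps["B", "n_samples_present"], 2L)
  expect_true(ps["B", "universally_present"])
  expect_false(any(ps$absent_everywhere))

  m <- populationMatrix(matrix(c(1, 2, 0, 0), 2,
                               dimnames = list(c("A", "B"), c("x", "y"))))
  ps2 <- presenceStats(m)
  expect_true(ps2["y", "absent_everywhere"])
  expect_equal(ps2["y", "n_samples_present"], 0L)
})

test_that("presenceStats is invariant under sample permutation", {
  a <- randAtlas(7)
  v <- popValues(a$dataset)
  perm <- sample(nrow(v))
  mp <- populationMatrix(v[perm, , drop = FALSE])
  expect_identical(presenceStats(popMatrix(a$dataset)), presenceStats(mp))
  ps <- presenceStats(mp)
  expect_true(all(ps$n_samples_present >= 0 & ps$n_samples_present <= nrow(v)))
})

test_that("matrix validity enforces value-kind invariants", {
  dn <- list(c("A", "B"), c("x", "y"))
  expect_error(populationMatrix(matrix(c(-1, 0, 0, 0), 2, dimnames = dn)),
               "non-negative")
  expect_error(populationMatrix(matrix(c(0.5, 0, 0, 0), 2, dimnames = dn)),
               "integers")
  expect_error(populationMatrix(matrix(c(0.7, 0.1, 0.3, 0.2), 2,
                                       dimnames = dn),
                                "fraction_within_sample"),
               "sum to 1")
  ok <- populationMatrix(matrix(c(0.75, 0, 0.25, 1), 2, dimnames = dn),
                         "fraction_within_sample")
  expect_s4_class(ok, "PopulationMatrix")
})
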