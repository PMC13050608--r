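## Seed-reproducible synthetic atlases with known ground truth. The
## generator emulates multi-sample single-cell atlases: Dirichlet cell-type
## compositions, log-normal per-sample totals, structurally absent
## (sample, cell type) pairs, categorical/numeric sample metadata and a
## balanced cell-ontology forest. Absence is structural by construction:
## every non-forced pair receives at least one cell, so presence flags
## recover the forced-absent set exactly.

#' Specify a synthetic atlas
#'
#' Defaults describe a desk-scale atlas in the spirit of public
#' multi-sample lung/kidney atlases: a few dozen samples, a dozen cell
#' types in a two-level ontology, moderately variable compositions
#' (Dirichlet concentration 2), ~2000 cells per sample (log-normal), 15%
#' of (sample, cell type) pairs structurally absent, and disease/age
#' sample metadata.
#'
#' @param n_samples,n_celltypes atlas dimensions.
#' @param hierarchy_depth depth of the cell-type leaves (>= 1).
#' @param branching maximum children per ontology node (>= 1);
#'   `n_celltypes` must not exceed `branching^hierarchy_depth`.
#' @param dirichlet_alpha concentration of the per-sample composition
#'   (larger = more even).
#' @param total_cells_per_sample `c(log_mean, log_sd)` of the log-normal
#'   per-sample cell total.
#' @param absent_fraction probability that a (sample, cell type) pair is
#'   forced to zero cells (0 <= p < 1).
#' @param metadata_spec list of sample-metadata field descriptors:
#'   `list(field=, kind="categorical", levels=)` or
#'   `list(field=, kind="numeric", range=c(lo, hi))`.
#' @param seed integer seed; identical specs give identical atlases.
#' @return an `AtlasSpec` object for [generateAtlas()].
#' @export
atlasSpec <- function(n_samples = 24,
                      n_celltypes = 12,
                      hierarchy_depth = 2,
                      branching = 4,
                      dirichlet_alpha = 2,
                      total_cells_per_sample = c(log_mean = log(2000),
                                                 log_sd = 0.5),
                      absent_fraction = 0.15,
                      metadata_spec = list(
                        list(field = "disease", kind = "categorical",
                             levels = c("normal", "covid",
                                        "cystic fibrosis")),
                        list(field = "age", kind = "numeric",
                             range = c(20, 80))),
                      seed = 1L) {
  n_samples <- as.integer(.assertNumber(n_samples, "n_samples"))
  n_celltypes <- as.integer(.assertNumber(n_celltypes, "n_celltypes"))
  hierarchy_depth <- as.integer(.assertNumber(hierarchy_depth,
                                              "hierarchy_depth"))
  branching <- as.integer(.assertNumber(branching, "branching"))
  if (n_samples < 1L || n_celltypes < 1L)
    stopUsage("n_samples and n_celltypes must be >= 1")
  if (hierarchy_depth < 1L || branching < 1L)
    stopUsage("hierarchy_depth and branching must be >= 1")
  if (n_celltypes > branching^hierarchy_depth)
    stopUsage("n_celltypes (%d) exceeds the %d leaves a depth-%d, branching-%d hierarchy implies",
              n_celltypes, branching^hierarchy_depth, hierarchy_depth,
              branching)
  if (!is.numeric(dirichlet_alpha) || dirichlet_alpha <= 0)
    stopUsage("dirichlet_alpha must be positive")
  if (length(total_cells_per_sample) != 2L ||
      total_cells_per_sample[2] < 0)
    stopUsage("total_cells_per_sample must be c(log_mean, log_sd >= 0)")
  if (absent_fraction < 0 || absent_fraction >= 1)
    stopUsage("absent_fraction must be in [0, 1)")
  structure(list(n_samples = n_samples, n_celltypes = n_celltypes,
                 hierarchy_depth = hierarchy_depth, branching = branching,
                 dirichlet_alpha = dirichlet_alpha,
                 total_cells_per_sample = unname(total_cells_per_sample),
                 absent_fraction = absent_fraction,
                 metadata_spec = metadata_spec,
                 seed = as.integer(seed)),
            class = "AtlasSpec")
}

## balanced forest: leaves at depth d, chunked by `branching` per level
.balancedForest <- function(leaves, depth, branching) {
  parent <- character(0)
  level <- leaves
  for (d in seq(depth, 1L)) {
    nUp <- ceiling(length(level) / branching)
    up <- sprintf("anc%d_%02d", d - 1L, seq_len(nUp))
    parent[level] <- up[ceiling(seq_along(level) / branching)]
    level <- up
  }
  cellTypeHierarchy(parent, nodes = leaves)
}

.withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

#' Generate a synthetic atlas with ground truth
#'
#' Per sample: draw a composition from Dirichlet(alpha), force the
#' structurally absent types to zero and renormalize, draw the sample's
#' total cell count from a log-normal, give every non-absent type one cell
#' and allocate the remainder multinomially (so per-sample totals are
#' exact and absence is structural, never a sampling artifact). One seeded
#' RNG stream is consumed in a fixed per-sample order, so identical specs
#' yield identical atlases.
#'
#' @param spec an [atlasSpec()].
#' @return a list with elements:
#'   \describe{
#'     \item{dataset}{a [CellPopDataset-class] with counts, metadata and
#'       hierarchy, labels in canonical generator order.}
#'     \item{cells}{the corresponding [cellTable()].}
#'     \item{groundTruth}{list with the exact `counts` matrix, logical
#'       `absent` matrix of forced-absent pairs, per-sample `totals`, and
#'       the spec.}
#'   }
#' @examples
#' atlas <- generateAtlas(atlasSpec(n_samples = 4, n_celltypes = 6,
#'                                  seed = 7))
#' atlas$dataset
#' @export
generateAtlas <- function(spec) {
  if (!inherits(spec, "AtlasSpec")) stopUsage("'spec' must be an atlasSpec()")
  nS <- spec$n_samples; nT <- spec$n_celltypes
  samples <- sprintf("s%02d", seq_len(nS))
  types <- sprintf("ct%02d", seq_len(nT))
  h <- .balancedForest(types, spec$hierarchy_depth, spec$branching)
  .withSeed(spec$seed, {
    ## sample metadata
    metaCols <- list()
    for (ms in spec$metadata_spec) {
      metaCols[[ms$field]] <- if (ms$kind == "categorical")
        sample(ms$levels, nS, replace = TRUE)
      else
        round(stats::runif(nS, ms$range[1], ms$range[2]), 1)
    }
    sampleMeta <- S4Vectors::DataFrame(metaCols, row.names = samples)
    ## per-sample compositions and counts, fixed consumption order
    counts <- matrix(0, nS, nT, dimnames = list(samples, types))
    absent <- matrix(FALSE, nS, nT, dimnames = list(samples, types))
    totals <- integer(nS)
    lm <- spec$total_cells_per_sample[1]; ls <- spec$total_cells_per_sample[2]
    for (i in seq_len(nS)) {
      p <- stats::rgamma(nT, shape = spec$dirichlet_alpha)
      forced <- stats::runif(nT) < spec$absent_fraction
      if (all(forced)) forced[which.max(p)] <- FALSE
      p[forced] <- 0
      p <- p / sum(p)
      present <- which(!forced)
      m <- length(present)
      n <- max(m, round(stats::rlnorm(1, lm, ls)))
      draw <- integer(nT)
      draw[present] <- 1L
      if (n > m)
        draw[present] <- draw[present] +
          as.integer(stats::rmultinom(1, n - m, p[present]))
      counts[i, ] <- draw
      absent[i, ] <- forced
      totals[i] <- n
    }
  })
  ## one record per cell, samples then canonical cell-type order
  reps <- as.vector(t(counts))
  cellSample <- rep(rep(samples, each = nT), reps)
  cellType <- rep(rep(types, nS), reps)
  cellId <- paste0(cellSample, "_c",
                   formatC(unlist(lapply(split(cellSample, factor(
                     cellSample, levels = samples)), seq_along),
                     use.names = FALSE), width = 5, flag = "0"))
  cells <- cellTable(cellId, cellSample, cellType)
  celltypeMeta <- S4Vectors::DataFrame(
    lineage = ancestorAtDepth(h, types, 0L),
    row.names = types)
  ds <- cellPopDataset(populationMatrix(counts, "count", "samples_as_rows"),
                       sampleMeta = sampleMeta,
                       celltypeMeta = celltypeMeta,
                       hierarchy = h)
  list(dataset = ds, cells = cells,
       groundTruth = list(counts = counts, absent = absent,
                          totals = stats::setNames(totals, samples),
                          spec = spec))
}

#' The canonical 2 x 2 worked fixture
#'
#' Two samples (A: covid, B: normal) by two cell types (T, B) with counts
#' `rbind(c(3, 1), c(0, 2))` and the hierarchy T -> lymphocyte,
#' B -> lymphocyte. Small enough to verify every transform by hand:
#' within-sample fractions are `[[0.75, 0.25], [0, 1]]` and collapsing to
#' depth 0 gives the single lymphocyte column `[4, 2]`.
#'
#' @return a [CellPopDataset-class].
#' @examples
#' popValues(fixtureF1())
#' @export
fixtureF1 <- function() {
  m <- matrix(c(3, 1, 0, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("T", "B")))
  cellPopDataset(
    populationMatrix(m, "count", "samples_as_rows"),
    sampleMeta = S4Vectors::DataFrame(disease = c("covid", "normal"),
                                      row.names = c("A", "B")),
    celltypeMeta = S4Vectors::DataFrame(row.names = c("T", "B")),
    hierarchy = cellTypeHierarchy(c(T = "lymphocyte", B = "lymphocyte")))
}
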