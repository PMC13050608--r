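# Small randomized datasets for property-style tests. Sizes are kept tiny
# (a handful of samples and cell types, ~100-2000 cells) so hundreds of
# instances run in seconds.

randAtlas <- function(seed, n_samples = NULL, n_celltypes = NULL, ...) {
  set.seed(seed)
  generateAtlas(atlasSpec(
    n_samples = n_samples %||% sample(3:8, 1),
    n_celltypes = n_celltypes %||% sample(4:9, 1),
    hierarchy_depth = 2,
    branching = 3,
    total_cells_per_sample = c(log(300), 0.4),
    seed = seed,
    ...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# selection-sort oracle: orders indices by an explicit tuple comparator
# (list of keys; each key = list(values, descending)); missing always last
oracleOrder <- function(keys) {
  n <- length(keys[[1]]$values)
  lessThan <- function(i, j) {
    for (k in keys) {
      vi <- k$values[i]; vj <- k$values[j]
      mi <- is.na(vi); mj <- is.na(vj)
      if (mi != mj) return(!mi)          # missing sorts last
      if (!mi && vi != vj) {
        if (k$descending) return(vi > vj) else return(vi < vj)
      }
    }
    i < j                                 # original order tiebreak
  }
  remaining <- seq_len(n)
  out <- integer(0)
  while (length(remaining)) {
    best <- remaining[1]
    for (r in remaining[-1]) if (lessThan(r, best)) best <- r
    out <- c(out, best)
    remaining <- setdiff(remaining, best)
  }
  out
}

countSvgMarks <- function(path, prefix) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, "//*[@id]")
  keep <- xml2::xml_name(nodes) != "g"     # panel groups are not marks
  sum(startsWith(xml2::xml_attr(nodes, "id")[keep], prefix))
}
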