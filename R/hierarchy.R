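#' Construct a cell-type hierarchy
#'
#' @param parent named character vector: `parent["child"] == "parent"`.
#'   Roots appear only as values (or in `nodes`).
#' @param nodes optional extra node labels (isolated roots); defaults to the
#'   union of children and parents.
#' @return a [CellTypeHierarchy-class].
#' @examples
#' h <- cellTypeHierarchy(c(Tcd4 = "T", Tcd8 = "T", T = "lymphocyte"))
#' hierarchyDepths(h)
#' @export
cellTypeHierarchy <- function(parent = character(), nodes = NULL) {
  parent <- vapply(parent, as.character, character(1))
  nodes <- unique(c(names(parent), unname(parent), nodes))
  new("CellTypeHierarchy", nodes = nodes, parent = parent)
}

#' Node depths in a hierarchy
#'
#' Roots have depth 0; every child is one deeper than its parent.
#'
#' @param h a [CellTypeHierarchy-class].
#' @return named integer vector over all nodes.
#' @export
hierarchyDepths <- function(h) {
  stopifnot(is(h, "CellTypeHierarchy"))
  depth <- integer(length(h@nodes))
  names(depth) <- h@nodes
  for (node in h@nodes) {
    d <- 0L
    cur <- node
    while (!is.na(h@parent[cur])) {
      cur <- unname(h@parent[cur])
      d <- d + 1L
      if (is.na(match(cur, names(h@parent)))) break
    }
    depth[node] <- d
  }
  depth
}

#' Ancestor of a node at a given depth
#'
#' Walks the parent chain of each label until it reaches the node whose
#' depth equals `depth`; labels already at or above that depth map to
#' themselves.
#'
#' @param h a [CellTypeHierarchy-class].
#' @param labels character vector of node labels.
#' @param depth non-negative integer.
#' @return character vector of ancestor labels, same length as `labels`.
#' @export
ancestorAtDepth <- function(h, labels, depth) {
  stopifnot(is(h, "CellTypeHierarchy"))
  if (depth < 0) stopUsage("'depth' must be >= 0")
  bad <- setdiff(labels, h@nodes)
  if (length(bad))
    stopInput("label(s) not in hierarchy: %s", paste(bad, collapse = ", "))
  depths <- hierarchyDepths(h)
  vapply(labels, function(lab) {
    while (depths[lab] > depth) lab <- unname(h@parent[lab])
    lab
  }, character(1), USE.NAMES = FALSE)
}

#' Depth-first node order
#'
#' Orders nodes by a depth-first traversal of the forest with roots and
#' siblings visited alphabetically (the on-screen "hierarchy" sort order
#' for cell types).
#'
#' @param h a [CellTypeHierarchy-class].
#' @return character vector of all node labels in traversal order.
#' @export
hierarchyOrder <- function(h) {
  stopifnot(is(h, "CellTypeHierarchy"))
  kids <- split(names(h@parent), unname(h@parent))
  # radix sort = C-locale collation, deterministic across platforms
  roots <- sort(setdiff(h@nodes, names(h@parent)), method = "radix")
  out <- character(0)
  visit <- function(node) {
    out[[length(out) + 1L]] <<- node
    for (k in sort(kids[[node]] %||% character(), method = "radix")) visit(k)
  }
  for (r in roots) visit(r)
  out
}

setMethod("show", "CellTypeHierarchy", function(object) {
  d <- if (length(object@nodes)) max(hierarchyDepths(object)) else 0L
  cat(sprintf("CellTypeHierarchy: %d node(s), %d root(s), max depth %d\n",
              length(object@nodes),
              length(setdiff(object@nodes, names(object@parent))), d))
})
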