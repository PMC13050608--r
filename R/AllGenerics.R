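#' @importFrom BiocGenerics normalize
NULL

#' @export
setGeneric("popValues", function(x) standardGeneric("popValues"))

#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))

#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))

#' @export
setGeneric("rowLabels", function(x) standardGeneric("rowLabels"))

#' @export
setGeneric("colLabels", function(x) standardGeneric("colLabels"))

#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @export
setGeneric("celltypeLabels", function(x) standardGeneric("celltypeLabels"))

#' @export
setGeneric("popMatrix", function(x) standardGeneric("popMatrix"))

#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' @export
setGeneric("celltypeMeta", function(x) standardGeneric("celltypeMeta"))

#' @export
setGeneric("hierarchy", function(x) standardGeneric("hierarchy"))

#' @export
setGeneric("totalCounts", function(x, axis = c("rows", "cols"))
  standardGeneric("totalCounts"))

#' @export
setGeneric("presenceStats", function(x) standardGeneric("presenceStats"))

#' @export
setGeneric("logTransform", function(x, base = 10, pseudocount = 1)
  standardGeneric("logTransform"))

#' @export
setGeneric("sortBy", function(x, keys) standardGeneric("sortBy"))

#' @export
setGeneric("filterBy", function(x, spec) standardGeneric("filterBy"))

#' @export
setGeneric("groupBy", function(x, axis, field) standardGeneric("groupBy"))

#' @export
setGeneric("collapseToDepth", function(x, depth)
  standardGeneric("collapseToDepth"))

#' @export
setGeneric("transposeView", function(x) standardGeneric("transposeView"))

#' @export
setGeneric("applyView", function(x, config) standardGeneric("applyView"))

#' @export
setGeneric("layoutFigure", function(x, config) standardGeneric("layoutFigure"))
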