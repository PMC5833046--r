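#' @rdname ExpressionStudy-class
#' @aliases studyId,ExpressionStudy-method
#' @export
setMethod("studyId", "ExpressionStudy", function(x) x@studyId)

#' @rdname ExpressionStudy-class
#' @export
setMethod("sampleGroups", "ExpressionStudy", function(x)
  setNames(as.character(colData(x)$group), colnames(x)))

#' @rdname CtExperiment-class
#' @export
setMethod("sampleGroups", "CtExperiment", function(x)
  setNames(as.character(colData(x)$group), colnames(x)))

#' @rdname CtExperiment-class
#' @export
setMethod("referenceGenes", "CtExperiment", function(x) x@referenceGenes)

#' @rdname CtExperiment-class
#' @export
setMethod("qcRecords", "CtExperiment", function(x)
  data.frame(sample = colnames(x),
             as.data.frame(colData(x)[, QC_COLUMNS, drop = FALSE]),
             row.names = NULL))

setMethod("show", "ExpressionStudy", function(object) {
  cat("ExpressionStudy '", object@studyId, "': ", nrow(object), " genes x ",
      ncol(object), " samples\n", sep = "")
  tab <- table(colData(object)$group)
  cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "CtExperiment", function(object) {
  cat("CtExperiment: ", nrow(object), " genes x ", ncol(object),
      " samples (", length(object@referenceGenes), " reference genes: ",
      paste(object@referenceGenes, collapse = ", "), ")\n", sep = "")
  tab <- table(colData(object)$group)
  cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

#' @rdname Dendrogram-class
#' @export
setMethod("leafOrder", "Dendrogram", function(x) x@order)

#' @rdname Dendrogram-class
#' @export
setMethod("leafLabels", "Dendrogram", function(x) x@labels)

#' @rdname Dendrogram-class
#' @export
setMethod("mergeHeights", "Dendrogram", function(x) x@height)

setMethod("show", "Dendrogram", function(object) {
  cat("Dendrogram (", object@axis, "): ", length(object@labels),
      " leaves, heights ", signif(min(object@height), 4), "..",
      signif(max(object@height), 4), "\n", sep = "")
})

#' Convert a Dendrogram to a base-R hclust object
#'
#' @param x a \linkS4class{Dendrogram}.
#' @param ... ignored.
#' @return an object of class \code{hclust} (method \code{"average"}).
#' @export
as.hclust.Dendrogram <- function(x, ...) {
  structure(list(merge = x@merge, height = x@height, order = x@order,
                 labels = x@labels, method = "average",
                 call = match.call(), dist.method = "centered.correlation"),
            class = "hclust")
}

#' @rdname GroupTestResult-class
#' @export
setMethod("kwTable", "GroupTestResult", function(x) x@kw)

#' @rdname GroupTestResult-class
#' @export
setMethod("dunnTable", "GroupTestResult", function(x) x@dunn)

#' @rdname GroupTestResult-class
#' @aliases significantGenes,GroupTestResult-method
#' @export
setMethod("significantGenes", "GroupTestResult", function(x, ...)
  flagSignificant(x, ...))

setMethod("show", "GroupTestResult", function(object) {
  cat("GroupTestResult:", nrow(object@kw), "genes,",
      sum(object@kw$significant), "significant at alpha =", object@alpha,
      "\n")
})

#' @rdname MCLResult-class
#' @export
setMethod("clusters", "MCLResult", function(x) x@clusters)

#' @rdname MCLResult-class
#' @export
setMethod("membership", "MCLResult", function(x) x@membership)

setMethod("show", "MCLResult", function(object) {
  sizes <- lengths(object@clusters)
  cat("MCLResult: ", length(sizes), " clusters (sizes ",
      paste(sizes, collapse = ", "), "), ", object@iterations,
      " iterations, converged = ", object@converged, "\n", sep = "")
})

setMethod("show", "InteractionGraph", function(object) {
  cat("InteractionGraph:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: ", length(object@genes), " genes, ",
      object@nStudies, " studies, effect ", object@effectSize,
      " log2, noise sd ", object@noiseSd, ", seed ", object@seed, "\n",
      sep = "")
  cat("  planted classes:",
      paste(names(table(object@effectClass)), table(object@effectClass),
            sep = "=", collapse = ", "), "\n")
})
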