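#' @rdname ExpressionStudy-class
#' @param x an object.
#' @export
setGeneric("studyId", function(x) standardGeneric("studyId"))

#' @rdname ExpressionStudy-class
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname CtExperiment-class
#' @param x an object.
#' @export
setGeneric("referenceGenes", function(x) standardGeneric("referenceGenes"))

#' @rdname CtExperiment-class
#' @export
setGeneric("qcRecords", function(x) standardGeneric("qcRecords"))

#' @rdname Dendrogram-class
#' @param x an object.
#' @export
setGeneric("leafOrder", function(x) standardGeneric("leafOrder"))

#' @rdname Dendrogram-class
#' @export
setGeneric("leafLabels", function(x) standardGeneric("leafLabels"))

#' @rdname Dendrogram-class
#' @export
setGeneric("mergeHeights", function(x) standardGeneric("mergeHeights"))

#' @rdname GroupTestResult-class
#' @param x an object.
#' @export
setGeneric("kwTable", function(x) standardGeneric("kwTable"))

#' @rdname GroupTestResult-class
#' @export
setGeneric("dunnTable", function(x) standardGeneric("dunnTable"))

#' @rdname GroupTestResult-class
#' @param ... passed on to methods.
#' @export
setGeneric("significantGenes",
           function(x, ...) standardGeneric("significantGenes"))

#' @rdname MCLResult-class
#' @param x an object.
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname MCLResult-class
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))
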