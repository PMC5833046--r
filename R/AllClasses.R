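## Central S4 containers. ExpressionStudy and CtExperiment extend
## SummarizedExperiment so the usual assay()/colData() machinery applies;
## the remaining classes are light-weight result holders.

VALID_GROUPS <- c("term", "preterm", "IUGR", "PE", "PE+IUGR")
CONTROL_GROUPS <- c("term", "preterm")
EFFECT_CLASSES <- c("null", "iugr_only", "pe_only", "equal", "equal_reversed")
SPECIFICITY_CLASSES <- c("IUGR_dominant", "PE_dominant", "equal",
                         "equal_reversed", "mixed", "unclassified")

#' ExpressionStudy: one study's log2 expression matrix with group labels
#'
#' Extends \linkS4class{SummarizedExperiment} with a single \code{exprs}
#' assay (genes in rows, samples in columns, log2 scale), a mandatory
#' \code{group} column in \code{colData}, and a study identifier.
#'
#' @slot studyId single study identifier.
#' @export
setClass("ExpressionStudy",
         contains = "SummarizedExperiment",
         representation(studyId = "character"))

setValidity("ExpressionStudy", function(object) {
  msg <- character()
  if (length(object@studyId) != 1L || is.na(object@studyId) ||
      !nzchar(object@studyId))
    msg <- c(msg, "'studyId' must be a single non-empty string")
  if (!"exprs" %in% assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  if (!"group" %in% colnames(colData(object))) {
    msg <- c(msg, "colData must contain a 'group' column")
  } else {
    grp <- colData(object)$group
    if (anyNA(grp)) msg <- c(msg, "every sample needs a group label")
    bad <- setdiff(unique(as.character(grp)), VALID_GROUPS)
    if (length(bad))
      msg <- c(msg, paste0("unknown group label(s): ",
                           paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionStudy
#'
#' @param exprs numeric matrix, genes x samples, log2 scale, with unique
#'   row (gene) and column (sample) names.
#' @param groups character vector of clinical group labels, one per sample
#'   (term, preterm, IUGR, PE, PE+IUGR). If named, names are matched against
#'   the matrix column names.
#' @param studyId single study identifier.
#' @return an \linkS4class{ExpressionStudy}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' es <- ExpressionStudy(m, c("term", "term", "IUGR", "IUGR"), "demo")
#' studyId(es)
#' @export
ExpressionStudy <- function(exprs, groups, studyId) {
  exprs <- as.matrix(exprs)
  if (!is.numeric(exprs)) stop("'exprs' must be numeric")
  if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
    stop("'exprs' needs gene row names and sample column names")
  groups <- as.character(unlist(groups))
  if (!is.null(names(groups))) {
    if (!setequal(names(groups), colnames(exprs)))
      stop("names of 'groups' do not match sample ids")
    groups <- groups[colnames(exprs)]
  }
  if (length(groups) != ncol(exprs))
    stop("one group label per sample is required")
  se <- SummarizedExperiment(assays = list(exprs = exprs),
                             colData = DataFrame(group = groups,
                                                 row.names = colnames(exprs)))
  new("ExpressionStudy", se, studyId = as.character(studyId))
}

#' CtExperiment: raw qPCR Ct values with per-sample QC records
#'
#' Extends \linkS4class{SummarizedExperiment} with a \code{ct} assay
#' (genes x samples, threshold cycles), \code{colData} columns
#' \code{group}, \code{rin}, \code{ratio_260_280}, \code{ratio_260_230}
#' and \code{yield}, and the identifiers of the stable reference genes
#' used for normalisation.
#'
#' @slot referenceGenes character vector (>= 1) of reference gene ids,
#'   each present among the assay rows.
#' @export
setClass("CtExperiment",
         contains = "SummarizedExperiment",
         representation(referenceGenes = "character"))

QC_COLUMNS <- c("rin", "ratio_260_280", "ratio_260_230", "yield")

setValidity("CtExperiment", function(object) {
  msg <- character()
  if (!"ct" %in% assayNames(object))
    msg <- c(msg, "assay 'ct' is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  need <- c("group", QC_COLUMNS)
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData is missing column(s): ",
                         paste(miss, collapse = ", ")))
  if (length(object@referenceGenes) < 1L)
    msg <- c(msg, "at least one reference gene is required")
  if (!all(object@referenceGenes %in% rownames(object)))
    msg <- c(msg, "all reference genes must be measured (present in rows)")
  if (length(msg)) msg else TRUE
})

#' Construct a CtExperiment
#'
#' @param ct numeric matrix of raw Ct values, genes x samples.
#' @param groups clinical group label per sample.
#' @param qc data.frame with columns \code{sample}, \code{rin},
#'   \code{ratio_260_280}, \code{ratio_260_230}, \code{yield} (one row per
#'   sample; order is matched by sample id).
#' @param referenceGenes ids of the stable reference genes (default the two
#'   used for placental qPCR normalisation, UBQ and YWHAZ).
#' @return a \linkS4class{CtExperiment}.
#' @export
CtExperiment <- function(ct, groups, qc,
                         referenceGenes = c("UBQ", "YWHAZ")) {
  ct <- as.matrix(ct)
  if (!is.numeric(ct)) stop("'ct' must be numeric")
  groups <- as.character(unlist(groups))
  if (!is.null(names(groups))) groups <- groups[colnames(ct)]
  if (length(groups) != ncol(ct))
    stop("one group label per sample is required")
  qc <- as.data.frame(qc)
  if (anyDuplicated(qc$sample)) stop("duplicate sample id in QC records")
  if (!all(colnames(ct) %in% qc$sample))
    stop("every sample needs a QC record")
  qc <- qc[match(colnames(ct), qc$sample), , drop = FALSE]
  cd <- DataFrame(group = groups,
                  rin = qc$rin,
                  ratio_260_280 = qc$ratio_260_280,
                  ratio_260_230 = qc$ratio_260_230,
                  yield = qc$yield,
                  row.names = colnames(ct))
  se <- SummarizedExperiment(assays = list(ct = ct), colData = cd)
  new("CtExperiment", se, referenceGenes = as.character(referenceGenes))
}

#' Dendrogram: an average-linkage merge tree with deterministic leaf order
#'
#' Stores the agglomeration in \code{\link[stats]{hclust}} convention:
#' \code{merge[i, ]} holds negative leaf indices or positive prior merge
#' indices, \code{height[i]} the (non-decreasing) merge height, and
#' \code{order} a permutation of the leaves in which, at every internal
#' node, the child containing the lexicographically smallest leaf label
#' comes first.
#'
#' @slot merge integer matrix (n-1) x 2.
#' @slot height numeric merge heights.
#' @slot order integer leaf permutation.
#' @slot labels leaf labels.
#' @slot axis which axis of the data matrix was clustered ("genes",
#'   "samples" or "none").
#' @export
setClass("Dendrogram",
         representation(merge = "matrix", height = "numeric",
                        order = "integer", labels = "character",
                        axis = "character"))

setValidity("Dendrogram", function(object) {
  n <- length(object@labels)
  msg <- character()
  if (nrow(object@merge) != n - 1L || length(object@height) != n - 1L)
    msg <- c(msg, "a tree on n leaves must have exactly n-1 merges")
  if (length(object@height) && any(diff(object@height) < -1e-9))
    msg <- c(msg, "merge heights must be non-decreasing")
  if (!identical(sort(object@order), seq_len(n)))
    msg <- c(msg, "leaf order must be a permutation of the leaves")
  if (length(msg)) msg else TRUE
})

#' GroupTestResult: Kruskal-Wallis and Dunn post-hoc results per gene
#'
#' @slot kw data.frame with one row per gene: \code{gene}, \code{H},
#'   \code{df}, \code{p}, \code{stars}, \code{significant}.
#' @slot dunn data.frame with one row per gene x comparison:
#'   \code{gene}, \code{comparison}, \code{z}, \code{p}, \code{p_adj}.
#' @slot alpha significance level used for flagging.
#' @export
setClass("GroupTestResult",
         representation(kw = "data.frame", dunn = "data.frame",
                        alpha = "numeric"))

setValidity("GroupTestResult", function(object) {
  msg <- character()
  if (nrow(object@kw) &&
      any(object@kw$H < -1e-12 | object@kw$p < 0 | object@kw$p > 1))
    msg <- c(msg, "H must be >= 0 and p in [0,1]")
  if (nrow(object@dunn) &&
      any(object@dunn$p_adj + 1e-12 < object@dunn$p |
          object@dunn$p_adj > 1 + 1e-12))
    msg <- c(msg, "adjusted p must lie in [raw p, 1]")
  if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "'alpha' must be a single value in (0,1)")
  if (length(msg)) msg else TRUE
})

#' InteractionGraph: an undirected confidence-weighted interaction graph
#'
#' @slot nodes character node universe (isolated nodes allowed).
#' @slot edges data.frame with columns \code{node_a}, \code{node_b},
#'   \code{score} (score in [0, 1], no self loops).
#' @export
setClass("InteractionGraph",
         representation(nodes = "character", edges = "data.frame"))

setValidity("InteractionGraph", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("node_a", "node_b", "score") %in% colnames(e)))
    msg <- c(msg, "edges need columns node_a, node_b, score")
  else {
    if (nrow(e) && any(e$score < 0 | e$score > 1))
      msg <- c(msg, "edge scores must lie in [0, 1]")
    if (nrow(e) && any(e$node_a == e$node_b))
      msg <- c(msg, "self loops are not allowed")
    if (!all(c(e$node_a, e$node_b) %in% object@nodes))
      msg <- c(msg, "all edge endpoints must be listed in 'nodes'")
  }
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate node ids")
  if (length(msg)) msg else TRUE
})

#' Construct an InteractionGraph
#'
#' @param edges data.frame with columns \code{node_a}, \code{node_b},
#'   \code{score}.
#' @param nodes optional node universe; defaults to the edge endpoints.
#'   Supplying a larger universe keeps isolated nodes as singletons
#'   through filtering and clustering.
#' @return an \linkS4class{InteractionGraph}.
#' @export
InteractionGraph <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (is.null(nodes))
    nodes <- sort(unique(c(as.character(edges$node_a),
                           as.character(edges$node_b))), method = "radix")
  new("InteractionGraph", nodes = as.character(nodes),
      edges = data.frame(node_a = as.character(edges$node_a),
                         node_b = as.character(edges$node_b),
                         score = as.numeric(edges$score)))
}

#' MCLResult: a hard partition of graph nodes from Markov clustering
#'
#' @slot clusters list of character vectors (disjoint, covering all nodes),
#'   each sorted, ordered by decreasing size then smallest member.
#' @slot membership named integer vector node -> cluster index.
#' @slot iterations number of expansion/inflation iterations performed.
#' @slot converged logical; \code{FALSE} flags a run stopped at
#'   \code{maxIter} (current partition returned).
#' @slot maxColSumDeviation largest observed deviation of any column sum
#'   from 1 across all inflation steps (stochasticity diagnostic).
#' @export
setClass("MCLResult",
         representation(clusters = "list", membership = "integer",
                        iterations = "integer", converged = "logical",
                        maxColSumDeviation = "numeric"))

#' SimulationConfig: all knobs of the synthetic-data generator
#'
#' Defaults describe the emulated wet-lab cohort: the five clinical groups
#' with sizes term 13, preterm 7, IUGR 8, PE 5, PE+IUGR 10, log2-scale
#' expression noise, and a Ct baseline for qPCR emulation.
#'
#' @slot nStudies number of expression studies to simulate (arm structure
#'   follows the seven-study meta-analysis design table).
#' @slot genes gene identifiers.
#' @slot effectClass named character vector gene -> one of null, iugr_only,
#'   pe_only, equal, equal_reversed.
#' @slot groupSizes named integer vector of qPCR cohort group sizes.
#' @slot effectSize planted log2 effect per disease (>= 0).
#' @slot noiseSd additive Gaussian noise sd, log2 units (expression) and
#'   cycles (Ct).
#' @slot ctBaseline baseline threshold cycle for a gene of zero abundance.
#' @slot referenceGenes stable reference genes added to Ct tables.
#' @slot qcFailFraction fraction of qPCR samples planted to fail RNA QC.
#' @slot seed master seed; per-study child seeds are derived
#'   deterministically from it.
#' @export
setClass("SimulationConfig",
         representation(nStudies = "integer", genes = "character",
                        effectClass = "character", groupSizes = "integer",
                        effectSize = "numeric", noiseSd = "numeric",
                        ctBaseline = "numeric", referenceGenes = "character",
                        qcFailFraction = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (length(object@genes) < 1L) msg <- c(msg, "empty gene list")
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate gene ids")
  if (!setequal(names(object@groupSizes), VALID_GROUPS))
    msg <- c(msg, "groupSizes must name all five clinical groups")
  if (any(object@groupSizes < 2L))
    msg <- c(msg, "all group sizes must be >= 2")
  if (length(object@noiseSd) != 1L || object@noiseSd <= 0)
    msg <- c(msg, "noiseSd must be > 0")
  if (length(object@effectSize) != 1L || object@effectSize < 0)
    msg <- c(msg, "effectSize must be >= 0")
  if (!setequal(names(object@effectClass), object@genes))
    msg <- c(msg, "effectClass must be named by the gene list")
  if (!all(object@effectClass %in% EFFECT_CLASSES))
    msg <- c(msg, paste0("effect classes must be one of: ",
                         paste(EFFECT_CLASSES, collapse = ", ")))
  if (length(object@referenceGenes) < 2L)
    msg <- c(msg, "at least two stable reference genes are required")
  if (object@qcFailFraction < 0 || object@qcFailFraction >= 1)
    msg <- c(msg, "qcFailFraction must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})
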