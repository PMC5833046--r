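## 2D hierarchical clustering: centred Pearson correlation distance and
## UPGMA (average linkage) with a deterministic lexicographic tie rule,
## plus the clustered-matrix/heatmap export.

#' Centred (or uncentred) correlation distance
#'
#' \code{d(u, v) = 1 - r(u, v)} where r is the Pearson correlation of
#' the mean-centred vectors (the classic clustering-software "centred
#' correlation"); \code{d} lies in [0, 2] with 0 on the diagonal. The
#' uncentred variant skips the mean subtraction.
#'
#' @param mat numeric matrix.
#' @param axis cluster the \code{"genes"} (rows) or \code{"samples"}
#'   (columns).
#' @param center subtract vector means (default TRUE).
#' @return symmetric distance matrix with zero diagonal.
#' @examples
#' centeredCorrelationDistance(rbind(a = c(1, 2, 3), b = c(1, 3, 2)),
#'                             axis = "genes")
#' @export
centeredCorrelationDistance <- function(mat, axis = c("genes", "samples"),
                                        center = TRUE) {
  axis <- match.arg(axis)
  v <- if (axis == "genes") t(as.matrix(mat)) else as.matrix(mat)
  if (ncol(v) < 2L) stop("need at least two vectors to cluster")
  if (center) {
    sds <- apply(v, 2, stats::sd)
    if (any(sds == 0))
      stop("zero-variance vector(s): ",
           paste(colnames(v)[sds == 0], collapse = ", "))
    d <- 1 - cor(v)
  } else {
    ss <- sqrt(colSums(v^2))
    if (any(ss == 0))
      stop("zero vector(s): ", paste(colnames(v)[ss == 0], collapse = ", "))
    d <- 1 - crossprod(v) / tcrossprod(ss)
  }
  diag(d) <- 0
  d
}

#' UPGMA (average linkage) clustering with a deterministic tie rule
#'
#' At each step the pair of clusters with the minimal average
#' inter-cluster distance is merged; the distance from the merged
#' cluster to any other is the size-weighted average of its parts
#' (Lance-Williams update, exactly the mean over all cross pairs). Ties
#' are broken by the lexicographically smallest member labels: among
#' tied pairs the one whose smallest member label sorts first wins, then
#' the smaller partner label. Leaf order puts, under every internal
#' node, the child containing the lexicographically smallest leaf first.
#'
#' @param dist symmetric distance matrix (zero diagonal) with labelled
#'   rows/columns, or a \code{\link[stats]{dist}} object.
#' @param axis recorded in the result ("genes", "samples" or "none").
#' @return a \linkS4class{Dendrogram}. Merge heights are non-decreasing
#'   (UPGMA monotonicity).
#' @export
averageLinkage <- function(dist, axis = "none") {
  D <- as.matrix(dist)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-12))
    stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix must have a zero diagonal")
  n <- nrow(D)
  labs <- rownames(D)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  ## locale-independent label ordering for all tie breaks
  lrank <- match(labs, sort(labs, method = "radix"))
  id <- -seq_len(n)               # hclust convention: leaves negative
  size <- rep(1L, n)
  minLab <- lrank                 # rank of smallest member label
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  cd <- D
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- NULL
    bestVal <- Inf
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a >= b) next
      i <- idx[a]; j <- idx[b]
      v <- cd[i, j]
      if (v < bestVal - 1e-15) {
        bestVal <- v; best <- c(i, j)
      } else if (abs(v - bestVal) <= 1e-15) {
        key <- sort(c(minLab[i], minLab[j]))
        cur <- sort(c(minLab[best[1]], minLab[best[2]]))
        if (key[1] < cur[1] || (key[1] == cur[1] && key[2] < cur[2]))
          best <- c(i, j)
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- cd[i, j]
    ## Lance-Williams size-weighted update into slot i
    for (k in idx) {
      if (k == i || k == j) next
      v <- (size[i] * cd[i, k] + size[j] * cd[j, k]) / (size[i] + size[j])
      cd[i, k] <- v; cd[k, i] <- v
    }
    size[i] <- size[i] + size[j]
    minLab[i] <- min(minLab[i], minLab[j])
    id[i] <- step
    active[j] <- FALSE
  }
  ## deterministic leaf order: child with smaller min label first
  nodeMin <- integer(n - 1L)
  nodeLeaves <- vector("list", n - 1L)
  childMin <- function(node) if (node < 0) lrank[-node] else nodeMin[node]
  childLeaves <- function(node)
    if (node < 0) -node else nodeLeaves[[node]]
  for (step in seq_len(n - 1L)) {
    a <- merge[step, 1]; b <- merge[step, 2]
    la <- childLeaves(a); lb <- childLeaves(b)
    ma <- childMin(a); mb <- childMin(b)
    nodeMin[step] <- min(ma, mb)
    nodeLeaves[[step]] <- if (ma <= mb) c(la, lb) else c(lb, la)
  }
  new("Dendrogram", merge = merge, height = height,
      order = as.integer(nodeLeaves[[n - 1L]]), labels = labs,
      axis = axis)
}

#' Build a clustered heatmap export
#'
#' Reorders the gene x sample matrix by the dendrogram leaf orders.
#' Per-gene values are median-centred log2 fold changes (the usual
#' red = up / green = down convention is recorded in the result, not
#' rendered). When \code{sampleTree} is NULL, samples are instead
#' grouped by their clinical annotation (genes-only clustering mode).
#'
#' @param mat numeric gene x sample matrix.
#' @param geneTree \linkS4class{Dendrogram} on the rows (or NULL to keep
#'   the row order).
#' @param sampleTree \linkS4class{Dendrogram} on the columns (or NULL).
#' @param annotations optional named vector sample -> clinical group,
#'   kept alongside and used to order samples when no sample tree is
#'   given.
#' @param centerRows median-centre each gene row (default TRUE).
#' @return list with \code{matrix} (reordered, centred), \code{geneOrder},
#'   \code{sampleOrder}, \code{annotations} (reordered) and
#'   \code{colors} (c(up = "red", down = "green", mid = "black")).
#' @export
buildHeatmap <- function(mat, geneTree = NULL, sampleTree = NULL,
                         annotations = NULL, centerRows = TRUE) {
  mat <- as.matrix(mat)
  ro <- seq_len(nrow(mat))
  if (!is.null(geneTree)) {
    if (!identical(sort(leafLabels(geneTree), method = "radix"),
                   sort(rownames(mat), method = "radix")))
      stop("gene tree leaves do not match matrix rows")
    ro <- match(leafLabels(geneTree)[leafOrder(geneTree)], rownames(mat))
  }
  co <- seq_len(ncol(mat))
  if (!is.null(sampleTree)) {
    if (!identical(sort(leafLabels(sampleTree), method = "radix"),
                   sort(colnames(mat), method = "radix")))
      stop("sample tree leaves do not match matrix columns")
    co <- match(leafLabels(sampleTree)[leafOrder(sampleTree)],
                colnames(mat))
  } else if (!is.null(annotations)) {
    grp <- factor(annotations[colnames(mat)], levels = VALID_GROUPS)
    co <- order(grp, colnames(mat), method = "radix")
  }
  out <- mat[ro, co, drop = FALSE]
  if (centerRows)
    out <- out - apply(out, 1, median)
  list(matrix = out, geneOrder = rownames(out),
       sampleOrder = colnames(out),
       annotations = if (is.null(annotations)) NULL else
         annotations[colnames(out)],
       colors = c(up = "red", down = "green", mid = "black"))
}

#' Render a clustered export with pheatmap (optional thin layer)
#'
#' @param export result of \code{\link{buildHeatmap}}.
#' @param ... passed to \code{\link[pheatmap]{pheatmap}}.
#' @return the pheatmap object, invisibly.
#' @export
plotHeatmap <- function(export, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("install 'pheatmap' to render heatmaps")
  ann <- if (!is.null(export$annotations))
    data.frame(group = export$annotations,
               row.names = export$sampleOrder) else NA
  invisible(pheatmap::pheatmap(export$matrix, cluster_rows = FALSE,
                               cluster_cols = FALSE, annotation_col = ann,
                               ...))
}
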