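## Medium-confidence edge filtering and Markov clustering (MCL) of a
## confidence-weighted interaction graph.

#' Filter an interaction graph at a confidence cutoff
#'
#' Keeps edges whose score is strictly larger than \code{minScore}
#' (the "medium confidence" convention: a 0.4-score edge is dropped).
#' The node universe is preserved, so nodes losing all their edges stay
#' in the graph as singletons.
#'
#' @param graph an \linkS4class{InteractionGraph}.
#' @param minScore confidence cutoff (default 0.4).
#' @return a filtered \linkS4class{InteractionGraph}.
#' @export
filterEdges <- function(graph, minScore = 0.4) {
  stopifnot(is(graph, "InteractionGraph"))
  validObject(graph)
  keep <- graph@edges$score > minScore
  InteractionGraph(graph@edges[keep, , drop = FALSE],
                   nodes = graph@nodes)
}

#' Markov clustering of a weighted graph
#'
#' Builds a column-stochastic transition matrix from the edge weights
#' with self loops (weight = the node's maximum incident edge weight;
#' 1 for isolated nodes), then alternates expansion (matrix squaring)
#' and inflation (elementwise power followed by column renormalisation)
#' with pruning of entries below \code{pruneBelow}, until the matrix
#' changes by less than \code{tol} or \code{maxIter} is reached (the
#' current partition is then returned with \code{converged = FALSE}).
#' Clusters are the attractor systems of the limit matrix; in the rare
#' overlapping case a node joins the cluster of its lexicographically
#' smallest attractor.
#'
#' @param graph an \linkS4class{InteractionGraph} (typically after
#'   \code{\link{filterEdges}}).
#' @param inflation inflation exponent (default 2.0, the de facto MCL
#'   standard; granularity increases with it).
#' @param maxIter iteration cap.
#' @param pruneBelow entries below this are zeroed each iteration.
#' @param tol convergence threshold on the max absolute matrix change.
#' @return an \linkS4class{MCLResult}.
#' @examples
#' g <- InteractionGraph(data.frame(node_a = c("a", "b", "c"),
#'                                  node_b = c("b", "c", "a"),
#'                                  score = 0.9))
#' clusters(mclCluster(g))
#' @export
mclCluster <- function(graph, inflation = 2.0, maxIter = 200L,
                       pruneBelow = 1e-5, tol = 1e-8) {
  stopifnot(is(graph, "InteractionGraph"))
  nodes <- sort(graph@nodes, method = "radix")
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- graph@edges
  if (nrow(e)) {
    ia <- match(e$node_a, nodes)
    ib <- match(e$node_b, nodes)
    A[cbind(ia, ib)] <- pmax(A[cbind(ia, ib)], e$score)
    A[cbind(ib, ia)] <- A[cbind(ia, ib)]
  }
  selfLoop <- apply(A, 1, max)
  selfLoop[selfLoop == 0] <- 1
  diag(A) <- selfLoop
  M <- sweep(A, 2, colSums(A), "/")
  maxDev <- 0
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    M2 <- M %*% M                         # expansion
    M2 <- M2^inflation                    # inflation
    M2[M2 < pruneBelow] <- 0
    cs <- colSums(M2)
    dead <- cs == 0
    if (any(dead)) {                      # fully pruned column: restart it
      M2[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    M2 <- sweep(M2, 2, cs, "/")
    maxDev <- max(maxDev, max(abs(colSums(M2) - 1)))
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within ", maxIter,
            " iterations; returning the current partition")
  memb <- interpretMCLMatrix(M, nodes)
  clusterIds <- sort(unique(memb))
  clusterList <- lapply(clusterIds, function(k)
    sort(nodes[memb == k], method = "radix"))
  ord <- order(-lengths(clusterList),
               vapply(clusterList, `[`, "", 1), method = "radix")
  clusterList <- clusterList[ord]
  membership <- integer(n)
  for (k in seq_along(clusterList))
    membership[nodes %in% clusterList[[k]]] <- k
  new("MCLResult", clusters = clusterList,
      membership = setNames(membership, nodes),
      iterations = it, converged = converged,
      maxColSumDeviation = maxDev)
}

interpretMCLMatrix <- function(M, nodes) {
  ## attractors carry positive mass on their own diagonal; attractor
  ## systems are connected components among attractors (shared support
  ## or direct flow); every node joins the system of the smallest
  ## attractor appearing in its column.
  n <- length(nodes)
  eps <- 1e-7
  attractors <- which(diag(M) > eps)
  if (!length(attractors)) attractors <- seq_len(n)
  sys <- seq_along(attractors)               # union-find over attractors
  findRoot <- function(i) { while (sys[i] != i) i <- sys[i]; i }
  for (a in seq_along(attractors)) for (b in seq_along(attractors)) {
    if (a >= b) next
    ia <- attractors[a]; ib <- attractors[b]
    linked <- M[ia, ib] > eps || M[ib, ia] > eps ||
      any(M[ia, ] > eps & M[ib, ] > eps)
    if (linked) {
      ra <- findRoot(a); rb <- findRoot(b)
      sys[max(ra, rb)] <- min(ra, rb)
    }
  }
  sysId <- vapply(seq_along(attractors), findRoot, integer(1))
  memb <- integer(n)
  for (j in seq_len(n)) {
    owners <- attractors[M[attractors, j] > eps]
    if (!length(owners)) {
      memb[j] <- -j                          # unattached: own singleton
    } else {
      a <- min(owners)                       # smallest attractor wins
      memb[j] <- sysId[match(a, attractors)]
    }
  }
  memb
}
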