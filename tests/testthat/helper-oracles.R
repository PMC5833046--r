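## Independent oracles used by the unit and acceptance tests. These
## deliberately take different computational routes than the package
## implementations they check.

## Brute-force UPGMA: clusters as leaf-index sets, inter-cluster
## distance recomputed each step as the mean over all cross pairs of
## the ORIGINAL distance matrix (no Lance-Williams update), same
## lexicographic tie rule as the implementation.
bruteUPGMA <- function(D) {
  n <- nrow(D)
  labs <- rownames(D)
  lrank <- match(labs, sort(labs, method = "radix"))
  clusters <- lapply(seq_len(n), identity)
  minLab <- lrank
  heights <- numeric(n - 1L)
  merges <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(clusters)
    best <- NULL; bestVal <- Inf
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      v <- mean(D[clusters[[a]], clusters[[b]]])
      take <- FALSE
      if (v < bestVal - 1e-15) take <- TRUE
      else if (abs(v - bestVal) <= 1e-15) {
        key <- sort(c(minLab[a], minLab[b]))
        cur <- sort(c(minLab[best[1]], minLab[best[2]]))
        if (key[1] < cur[1] || (key[1] == cur[1] && key[2] < cur[2]))
          take <- TRUE
      }
      if (take) { bestVal <- v; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    heights[step] <- bestVal
    newCluster <- sort(c(clusters[[a]], clusters[[b]]))
    merges[[step]] <- sort(labs[newCluster], method = "radix")
    clusters <- c(clusters[-c(a, b)], list(newCluster))
    minLab <- c(minLab[-c(a, b)], min(minLab[c(a, b)]))
  }
  list(heights = heights, merges = merges)
}

## Member sets of every internal node of a Dendrogram, for topology
## comparison against the brute-force oracle.
dendrogramMerges <- function(dend) {
  labs <- leafLabels(dend)
  m <- dend@merge
  sets <- vector("list", nrow(m))
  grab <- function(node) if (node < 0) labs[-node] else sets[[node]]
  for (i in seq_len(nrow(m)))
    sets[[i]] <- sort(c(grab(m[i, 1]), grab(m[i, 2])), method = "radix")
  sets
}

randomDistanceMatrix <- function(n, labels = NULL) {
  if (is.null(labels)) labels <- sprintf("L%02d", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  vals <- runif(n * (n - 1) / 2, 0.05, 2)
  D[upper.tri(D)] <- vals
  D <- D + t(D)
  D
}

## Monte-Carlo permutation null for the Kruskal-Wallis p value: the
## group labels are permuted B times over the fixed mid-ranks and the
## tail probability P(H >= H_obs) is estimated directly.
kwPermutationP <- function(values, groups, B = 20000L) {
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  lev <- unique(groups)
  nj <- tabulate(factor(groups, levels = lev))
  ind <- vapply(lev, function(g) as.numeric(groups == g),
                numeric(N))                       # N x g
  const <- 12 / (N * (N + 1))
  hFromRanks <- function(rmat) {                  # N x B
    Rj <- crossprod(ind, rmat)                    # g x B
    (const * colSums(Rj^2 / nj) - 3 * (N + 1)) / C
  }
  Hobs <- hFromRanks(matrix(r, ncol = 1))
  P <- vapply(seq_len(B), function(i) r[sample.int(N)], numeric(N))
  mean(hFromRanks(P) >= Hobs - 1e-12)
}

## Straightforward dense reference MCL (no pruning, fresh code path)
## used to cross-check the package implementation on small graphs.
referenceMCL <- function(A, inflation = 2, maxIter = 300, tol = 1e-10) {
  diag(A) <- pmax(apply(A, 1, max), 1e-12)
  M <- sweep(A, 2, colSums(A), "/")
  for (i in seq_len(maxIter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    if (max(abs(M2 - M)) < tol) { M <- M2; break }
    M <- M2
  }
  keep <- M > 1e-6
  adj <- keep | t(keep)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  unname(split(rownames(A), comp))
}

## In-memory qPCR arm of the pipeline, used by the recovery tests.
runQpcrPipeline <- function(config, alpha = 0.05, threshold = 1.14,
                            epsilon = 0.2, topN = 3L) {
  sim <- simulateCtTable(config)
  pass <- qcFilter(qcRecords(sim$ct))
  fc <- computeFoldChange(computeDeltaCt(sim$ct, samples = pass))
  res <- testGeneExpression(fc, alpha = alpha)
  sig <- flagSignificant(res)
  calls <- classifySpecificity(groupLogFC(fc), threshold = threshold,
                               epsilon = epsilon)
  targets <- intersectTargets(sig, calls, n = topN)
  list(truth = sim$truth, fc = fc, result = res, significant = sig,
       calls = calls, targets = targets)
}

PLANTED_TO_CALL <- c(iugr_only = "IUGR_dominant", pe_only = "PE_dominant",
                     equal = "equal", equal_reversed = "equal_reversed")

## Substrate-class communities planted in the packaged 46-node
## interaction fixture (the three of interest: amino acid, vitamin and
## microelement/ion transporters).
SUBSTRATE_COMMUNITIES <- list(
  amino_acids = c("SLC3A2", "SLC7A1", "SLC7A5", "SLC7A6", "SLC7A7",
                  "SLC7A8", "SLC7A11", "SLC38A1", "SLC38A2", "SLC38A5",
                  "SLC12A8"),
  vitamins = c("SLC19A1", "SLC19A2", "SLC19A3", "SLC46A1", "SLC5A6",
               "LMBRD1", "SLC22A15", "SLC23A1", "SLC23A2", "SLC23A3"),
  ions = c("SLC30A1", "SLC30A2", "SLC30A4", "SLC39A1", "SLC39A8",
           "TRPV6", "SLC4A1", "SLC26A2", "SLC26A6", "SLC9A1", "SLC9B2",
           "SLC5A5", "SLC26A4", "SLC11A2"))
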