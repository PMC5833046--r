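edgeFixture <- system.file("extdata", "synthetic_interaction_edges.tsv",
                           package = "placentaScreen")

test_that("edge filtering is strict at the confidence cutoff", {
  g <- InteractionGraph(data.frame(node_a = c("A", "B", "C"),
                                   node_b = c("B", "C", "D"),
                                   score = c(0.41, 0.40, 0.39)),
                        nodes = c("A", "B", "C", "D", "E"))
  f <- filterEdges(g)
  expect_equal(nrow(f@edges), 1L)
  expect_equal(f@edges$score, 0.41)
  ## isolated nodes survive as part of the universe
  expect_setequal(f@nodes, c("A", "B", "C", "D", "E"))
  empty <- filterEdges(InteractionGraph(
    data.frame(node_a = character(), node_b = character(),
               score = numeric()), nodes = character()))
  expect_equal(nrow(empty@edges), 0L)
  expect_error(InteractionGraph(data.frame(node_a = "A", node_b = "B",
                                           score = 1.2)), "0, 1")
})

test_that("MCL partitions disconnected structures exactly", {
  tri <- function(nodes, w = 1) data.frame(
    node_a = nodes, node_b = nodes[c(2, 3, 1)], score = w)
  g <- InteractionGraph(rbind(tri(c("a1", "a2", "a3")),
                              tri(c("b1", "b2", "b3"))))
  res <- mclCluster(g)
  expect_equal(clusters(res), list(c("a1", "a2", "a3"),
                                   c("b1", "b2", "b3")))
  ## single edge: one cluster
  single <- mclCluster(InteractionGraph(data.frame(node_a = "a",
                                                   node_b = "b",
                                                   score = 0.9)))
  expect_equal(clusters(single), list(c("a", "b")))
  ## singletons stay singleton clusters
  iso <- mclCluster(InteractionGraph(data.frame(node_a = "a",
                                                node_b = "b",
                                                score = 0.9),
                                     nodes = c("a", "b", "z")))
  expect_true(list("z") %in% clusters(iso) ||
                any(vapply(clusters(iso), identical, TRUE, "z")))
})

test_that("MCL output is a partition with stochastic columns", {
  set.seed(71)
  comm <- list(A = sprintf("a%02d", 1:6), B = sprintf("b%02d", 1:5),
               C = sprintf("c%02d", 1:7))
  g <- filterEdges(InteractionGraph(simulateEdgeList(comm, seed = 71)))
  res <- mclCluster(g)
  expect_lt(res@maxColSumDeviation, 1e-9)
  all_nodes <- unlist(clusters(res))
  expect_setequal(all_nodes, g@nodes)
  expect_equal(anyDuplicated(all_nodes), 0L)
  expect_true(res@converged)
})

test_that("two cliques joined by a weak bridge split into two clusters", {
  clique <- function(nodes, w = 1) {
    p <- t(combn(nodes, 2))
    data.frame(node_a = p[, 1], node_b = p[, 2], score = w)
  }
  edges <- rbind(clique(c("a1", "a2", "a3", "a4")),
                 clique(c("b1", "b2", "b3", "b4")),
                 data.frame(node_a = "a1", node_b = "b1", score = 0.41))
  res <- mclCluster(filterEdges(InteractionGraph(edges)))
  expect_equal(lengths(clusters(res)), c(4L, 4L))
  ## independent dense reference MCL run on the same matrix agrees
  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  A <- matrix(0, 8, 8, dimnames = list(nodes, nodes))
  A[cbind(edges$node_a, edges$node_b)] <- edges$score
  A <- pmax(A, t(A))
  ref <- referenceMCL(A)
  canon <- function(cls)
    sort(vapply(cls, function(x)
      paste(sort(x, method = "radix"), collapse = ","), ""),
      method = "radix")
  expect_equal(canon(clusters(res)), canon(ref))
})

test_that("clusters are invariant under node relabeling", {
  set.seed(72)
  comm <- list(A = sprintf("x%02d", 1:5), B = sprintf("y%02d", 1:6))
  edges <- simulateEdgeList(comm, seed = 72)
  res1 <- mclCluster(filterEdges(InteractionGraph(edges)))
  ## permute the labels
  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  relab <- setNames(sprintf("n%02d", sample(length(nodes))), nodes)
  edges2 <- data.frame(node_a = relab[edges$node_a],
                       node_b = relab[edges$node_b],
                       score = edges$score)
  res2 <- mclCluster(filterEdges(InteractionGraph(edges2)))
  back <- lapply(clusters(res2), function(cl)
    sort(names(relab)[match(cl, relab)], method = "radix"))
  canon <- function(cls)
    sort(vapply(cls, paste, "", collapse = ","), method = "radix")
  expect_equal(canon(back), canon(clusters(res1)))
})

test_that("the packaged 46-node fixture recovers the substrate communities", {
  g <- readEdgeList(edgeFixture)
  expect_length(g@nodes, 46L)
  res <- mclCluster(filterEdges(g))
  for (comm in SUBSTRATE_COMMUNITIES)
    expect_true(any(vapply(clusters(res), setequal, TRUE, comm)))
  expect_lt(res@maxColSumDeviation, 1e-9)
})
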