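makeStudy <- function(m, groups, id = "s1") ExpressionStudy(m, groups, id)

test_that("quantile normalization matches the hand-executed algorithm", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  rownames(m) <- paste0("g", 1:3)
  qn <- quantileNormalize(m)
  expect_equal(unname(qn[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, "b"]), c(2.5, 3.5, 4.5))
  ## identical columns are a fixed point; applying twice = applying once
  same <- cbind(a = c(2, 1, 5), b = c(2, 1, 5))
  expect_equal(quantileNormalize(same), same, ignore_attr = TRUE)
  set.seed(41)
  r <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  qr <- quantileNormalize(r)
  expect_equal(quantileNormalize(qr), qr, tolerance = 1e-12)
  expect_equal(max(colMeans(qr)) - min(colMeans(qr)), 0, tolerance = 1e-12)
  expect_warning(quantileNormalize(r[, 1, drop = FALSE]), "single-column")
})

test_that("de statistics: fold change, degenerate cases and d0 limits", {
  set.seed(7)
  m <- matrix(rnorm(40, 8), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  grp <- rep(c("term", "IUGR"), each = 4)
  ## identical group means: FC = 0, t = 0, p = 1
  m["g1", ] <- rep(c(1, 2, 3, 4), 2)
  de <- deStatistics(makeStudy(m, grp), "IUGR")
  expect_equal(de$log2_fc[de$gene == "g1"], 0)
  expect_equal(de$t[de$gene == "g1"], 0)
  expect_equal(de$p[de$gene == "g1"], 1)
  ## log2 FC invariant under adding a constant to all samples of a gene
  m2 <- m; m2["g2", ] <- m2["g2", ] + 100
  de2 <- deStatistics(makeStudy(m2, grp), "IUGR")
  expect_equal(de2$log2_fc[de2$gene == "g2"],
               de$log2_fc[de$gene == "g2"])
  ## d0 -> Inf: moderated t equals the ordinary t with variance s0^2
  deInf <- deStatistics(makeStudy(m, grp), "IUGR", d0 = Inf)
  s2 <- vapply(rownames(m), function(g) {
    (sum((m[g, 1:4] - mean(m[g, 1:4]))^2) +
       sum((m[g, 5:8] - mean(m[g, 5:8]))^2)) / 6
  }, numeric(1))
  e <- log(s2) - digamma(3) + log(3)
  s02 <- exp(mean(e))
  expect_equal(deInf$t, deInf$log2_fc / sqrt(s02 * (1 / 4 + 1 / 4)),
               tolerance = 1e-10)
  ## noise-free planted effect is recovered exactly
  cfg <- simulationConfig(nGenes = 15, nStudies = 2, noiseSd = 1e-9,
                          seed = 3)
  sim <- simulateStudies(cfg)
  de3 <- deStatistics(sim$studies[[2]], "IUGR")
  expect_equal(de3$log2_fc[match(sim$truth$gene, de3$gene)],
               sim$truth$effect_iugr, tolerance = 1e-6)
  ## errors
  expect_error(deStatistics(makeStudy(m, rep("term", 8)), "IUGR"),
               "absent")
})

test_that("variance shrinkage agrees with the limma moment estimator", {
  set.seed(11)
  s2 <- exp(rnorm(300, 0, 1))
  dg <- 6
  mine <- squeezeVariances(s2, dg)
  ref <- limma::squeezeVar(s2, df = dg)
  expect_equal(mine$d0, ref$df.prior, tolerance = 1e-4)
  expect_equal(mine$s02, ref$var.prior, tolerance = 1e-4)
  expect_equal(mine$s2Shrunk, ref$var.post, tolerance = 1e-6)
  ## degenerate moment estimate falls back to the documented cap
  capped <- squeezeVariances(rep(2, 50), dg)
  expect_equal(capped$d0, 50)
})

test_that("top-k ranking orders by fold change with p then id tie breaks", {
  de <- data.frame(gene = c("a", "b", "c"),
                   log2_fc = c(2, 1, -1), t = c(5, 3, -2),
                   p = c(0.01, 0.02, 0.04),
                   rank_up = c(1L, 2L, 3L), rank_down = c(3L, 2L, 1L))
  top <- rankTopK(de, k = 2)
  expect_equal(top$up, c("a", "b"))
  expect_equal(top$down, c("c", "b"))
  expect_error(rankTopK(de, k = 5), "exceeds")
  ## equal FC: smaller p first
  m <- matrix(8, 2, 6, dimnames = list(c("gA", "gB"), paste0("s", 1:6)))
  grp <- rep(c("term", "PE"), each = 3)
  m[, grp == "PE"] <- m[, grp == "PE"] + 1
  ## equal group means but extra control spread: same FC, larger p
  m["gA", 1] <- m["gA", 1] + 0.3
  m["gA", 2] <- m["gA", 2] - 0.3
  deq <- deStatistics(makeStudy(m, grp), "PE")
  expect_true(deq$rank_up[deq$gene == "gB"] <
                deq$rank_up[deq$gene == "gA"])
  ## k = n returns everything
  full <- rankTopK(deq, k = 2)
  expect_setequal(full$up, c("gA", "gB"))
})

test_that("planted non-null genes are selected across the seven studies", {
  hits <- 0L
  for (s in 1:20) {
    cfg <- simulationConfig(nGenes = 40, nStudies = 7, effectSize = 1.0,
                            noiseSd = 0.3, seed = 400 + s)
    sim <- simulateStudies(cfg)
    ann <- setNames(rep(TRUE, 40), cfg@genes)
    results <- list()
    for (st in sim$studies)
      for (ctr in intersect(c("IUGR", "PE"), sampleGroups(st)))
        results[[paste(studyId(st), ctr)]] <- deStatistics(st, ctr)
    sel <- selectCandidates(results, ann)
    nn <- sim$truth$gene[sim$truth$class != "null"]
    if (all(nn %in% sel$gene)) hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.95)
})

test_that("candidate selection applies the three criteria and is monotone", {
  mkDe <- function(genes, fc, study) {
    n <- length(genes)
    de <- data.frame(gene = genes, log2_fc = fc, t = fc,
                     p = rep(0.01, n), rank_up = integer(n),
                     rank_down = integer(n))
    de$rank_up[order(-fc, de$p, genes, method = "radix")] <- seq_len(n)
    de$rank_down[order(fc, de$p, genes, method = "radix")] <- seq_len(n)
    attr(de, "studyId") <- study
    attr(de, "contrast") <- "IUGR"
    de
  }
  genes <- sprintf("g%02d", 1:20)
  ann <- setNames(rep(TRUE, 20), genes)
  ## g01 strongly up everywhere; in 4 studies
  studies <- lapply(1:4, function(i)
    mkDe(genes, c(3, rnorm(19, 0, 0.1)), paste0("s", i)))
  sel <- selectCandidates(studies, ann, minStudies = 4, k = 2)
  expect_true("g01" %in% sel$gene)
  expect_match(sel$fc_range[sel$gene == "g01"], "~")
  ## only 3 studies: rejected ("more than 3" is strict)
  sel3 <- selectCandidates(studies[1:3], ann, minStudies = 4, k = 2)
  expect_false("g01" %in% sel3$gene)
  ## never in a top list: rejected despite presence everywhere
  flat <- lapply(1:5, function(i) {
    fc <- rep(0, 20); fc[2:3] <- c(5, -5)
    mkDe(genes, fc, paste0("s", i))
  })
  self <- selectCandidates(flat, ann, minStudies = 4, k = 2)
  expect_false("g10" %in% self$gene)
  ## annotation flag is required
  annOff <- ann; annOff["g01"] <- FALSE
  expect_false("g01" %in%
                 selectCandidates(studies, annOff, minStudies = 4,
                                  k = 2)$gene)
  ## monotone: adding a study can never remove a selected gene
  sel5 <- selectCandidates(c(studies, list(mkDe(genes,
                                                rnorm(20, 0, 0.1),
                                                "s5"))),
                           ann, minStudies = 4, k = 2)
  expect_true(all(sel$gene %in% sel5$gene))
})
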