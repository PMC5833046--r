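test_that("noise-free limits plant exact effects in studies and Ct tables", {
  cfg <- simulationConfig(nGenes = 15, nStudies = 2, effectSize = 1.0,
                          noiseSd = 1e-9, seed = 11)
  sim <- simulateStudies(cfg)
  truth <- sim$truth
  st <- sim$studies[[2]]               # has term/preterm/IUGR/PE arms
  grp <- sampleGroups(st)
  m <- SummarizedExperiment::assay(st, "exprs")
  for (i in seq_len(nrow(truth))) {
    diffIUGR <- mean(m[truth$gene[i], grp == "IUGR"]) -
      mean(m[truth$gene[i], grp %in% c("term", "preterm")])
    expect_equal(diffIUGR, truth$effect_iugr[i], tolerance = 1e-6)
  }
  qp <- simulateCtTable(cfg)
  ct <- SummarizedExperiment::assay(qp$ct, "ct")
  cgrp <- sampleGroups(qp$ct)
  g <- truth$gene[truth$class == "pe_only"][1]
  ## a +1 log2 effect lowers Ct by one cycle relative to term controls
  expect_equal(mean(ct[g, cgrp == "PE"]) - mean(ct[g, cgrp == "term"]),
               -truth$effect_pe[truth$gene == g], tolerance = 1e-6)
  ## PE+IUGR samples receive both effects summed
  ge <- truth$gene[truth$class == "equal"][1]
  expect_equal(mean(ct[ge, cgrp == "PE+IUGR"]) -
                 mean(ct[ge, cgrp == "term"]),
               -(truth$effect_iugr[truth$gene == ge] +
                   truth$effect_pe[truth$gene == ge]),
               tolerance = 1e-6)
  ## reference genes carry no group effect
  for (ref in referenceGenes(qp$ct)) {
    mu <- tapply(ct[ref, ], cgrp, mean)
    expect_true(max(mu) - min(mu) < 1e-6)
  }
})

test_that("identical config and seed give identical output, different seeds differ", {
  cfg <- simulationConfig(nGenes = 15, nStudies = 3, seed = 5)
  a <- simulateStudies(cfg)
  b <- simulateStudies(cfg)
  for (i in seq_along(a$studies))
    expect_identical(SummarizedExperiment::assay(a$studies[[i]], "exprs"),
                     SummarizedExperiment::assay(b$studies[[i]], "exprs"))
  expect_identical(SummarizedExperiment::assay(simulateCtTable(cfg)$ct),
                   SummarizedExperiment::assay(simulateCtTable(cfg)$ct))
  cfg2 <- simulationConfig(nGenes = 15, nStudies = 3, seed = 6)
  expect_false(identical(
    SummarizedExperiment::assay(a$studies[[1]], "exprs"),
    SummarizedExperiment::assay(simulateStudies(cfg2)$studies[[1]],
                                "exprs")))
})

test_that("null genes show no systematic per-study fold change", {
  ## Monte-Carlo check against Normal theory: the per-study DE log-FC of
  ## a null gene should fall within 3 SE of zero in >= 95% of replicates.
  nRep <- 400
  hits <- 0
  for (k in seq_len(nRep)) {
    cfg <- simulationConfig(nGenes = 13, nStudies = 2, noiseSd = 0.3,
                            seed = 1000 + k)
    st <- simulateStudies(cfg)$studies[[2]]
    grp <- sampleGroups(st)
    m <- SummarizedExperiment::assay(st, "exprs")
    g <- "G013"                        # a null gene under the defaults
    fc <- mean(m[g, grp == "IUGR"]) -
      mean(m[g, grp %in% c("term", "preterm")])
    se <- 0.3 * sqrt(1 / sum(grp == "IUGR") +
                       1 / sum(grp %in% c("term", "preterm")))
    if (abs(fc) <= 3 * se) hits <- hits + 1
  }
  expect_gte(hits / nRep, 0.95)
})

test_that("simulation config validation rejects degenerate settings", {
  expect_error(simulationConfig(genes = character(), seed = 1),
               "empty|explicitly")
  expect_error(simulationConfig(nGenes = 20,
                                groupSizes = c(term = 1L, preterm = 7L,
                                               IUGR = 8L, PE = 5L,
                                               "PE+IUGR" = 10L)),
               ">= 2")
  expect_error(simulationConfig(nGenes = 20, noiseSd = 0), "noiseSd")
  expect_error(simulationConfig(nGenes = 20, effectSize = -1),
               "effectSize")
  expect_error(simulationConfig(nGenes = 20, referenceGenes = "UBQ"),
               "two|reference")
})

test_that("planted truth respects the effect-class contracts", {
  truth <- plantedTruth(simulationConfig(nGenes = 50, effectSize = 1.5))
  null <- truth[truth$class == "null", ]
  expect_true(all(null$effect_iugr == 0 & null$effect_pe == 0))
  eq <- truth[truth$class == "equal", ]
  expect_true(all(eq$effect_iugr == eq$effect_pe))
  rev <- truth[truth$class == "equal_reversed", ]
  expect_true(all(rev$effect_iugr == -rev$effect_pe &
                    abs(rev$effect_iugr) == 1.5))
  expect_identical(truth$significant, truth$class != "null")
})

test_that("QC failure fraction is honoured and zero means all pass", {
  cfg0 <- simulationConfig(nGenes = 15, qcFailFraction = 0, seed = 2)
  ct0 <- simulateCtTable(cfg0)$ct
  expect_setequal(qcFilter(qcRecords(ct0)), colnames(ct0))
  cfg1 <- simulationConfig(nGenes = 15, qcFailFraction = 0.2, seed = 2)
  ct1 <- simulateCtTable(cfg1)$ct
  expect_length(qcFilter(qcRecords(ct1)),
                ncol(ct1) - floor(0.2 * ncol(ct1)))
})

test_that("fixture bundle round-trips through the plain-text formats", {
  dir <- withr::local_tempdir()
  cfg <- simulationConfig(nGenes = 14, nStudies = 2, seed = 9)
  files <- writeFixtureBundle(cfg, dir)
  cfg2 <- readSimulationConfig(files[["config"]])
  expect_identical(cfg2, cfg)
  m <- readExpressionMatrix(files[["matrix_study1"]])
  orig <- SummarizedExperiment::assay(simulateStudies(cfg)$studies[[1]],
                                      "exprs")
  expect_identical(m, orig)
  ct <- readCtTable(files[["ct"]], files[["qc"]])
  expect_identical(SummarizedExperiment::assay(ct, "ct"),
                   SummarizedExperiment::assay(simulateCtTable(cfg)$ct,
                                               "ct"))
})
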