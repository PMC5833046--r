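test_that("FC filter requires |FC| > 1.14 in at least one disease", {
  pairs <- data.frame(gene = c("below", "one_side", "boundary"),
                      x = c(0.10, log2(1.15), log2(1.14)),
                      y = c(0.05, 0.00, log2(1.14)))
  keep <- fcFilter(pairs)
  expect_identical(keep, c(FALSE, TRUE, FALSE))   # boundary is strict
  ## down-regulation counts symmetrically (FC < 1/1.14)
  expect_true(fcFilter(data.frame(gene = "dn", x = -0.25, y = 0)))
})

test_that("classification bands follow the fixed rule order", {
  pairs <- data.frame(
    gene = c("eq", "rev", "iugr", "pe", "mix", "weak"),
    x = c(0.5, 0.4, 0.6, 0.1, 0.9, 0.1),
    y = c(0.5, -0.4, 0.0, -0.8, 0.4, 0.05))
  calls <- classifySpecificity(pairs)
  got <- setNames(calls$class, calls$gene)
  expect_equal(unname(got["eq"]), "equal")
  expect_equal(unname(got["rev"]), "equal_reversed")
  expect_equal(unname(got["iugr"]), "IUGR_dominant")
  expect_equal(unname(got["pe"]), "PE_dominant")
  expect_equal(unname(got["mix"]), "mixed")
  expect_equal(unname(got["weak"]), "unclassified")
  ## rank variable r = y/x, signed infinity at x = 0
  r <- setNames(calls$r, calls$gene)
  expect_equal(unname(r["eq"]), 1)
  expect_equal(unname(r["rev"]), -1)
  expect_equal(unname(r["iugr"]), 0)
  expect_equal(unname(r["pe"]), -8)
  expect_equal(classifySpecificity(data.frame(gene = "v", x = 0,
                                              y = 0.9))$r, Inf)
  ## unclassified iff the FC filter failed
  expect_identical(calls$class == "unclassified", !calls$retained)
})

test_that("classification is symmetric and scale-consistent", {
  set.seed(61)
  pairs <- data.frame(gene = sprintf("g%02d", 1:40),
                      x = runif(40, -1.5, 1.5), y = runif(40, -1.5, 1.5))
  a <- classifySpecificity(pairs)
  swapped <- classifySpecificity(data.frame(gene = pairs$gene,
                                            x = pairs$y, y = pairs$x))
  map <- c(IUGR_dominant = "PE_dominant", PE_dominant = "IUGR_dominant",
           equal = "equal", equal_reversed = "equal_reversed",
           mixed = "mixed", unclassified = "unclassified")
  expect_identical(unname(map[a$class]), swapped$class)
  ## scaling up both coordinates never flips equal <-> equal_reversed
  for (c0 in c(1.5, 3, 10)) {
    b <- classifySpecificity(data.frame(gene = pairs$gene,
                                        x = c0 * pairs$x,
                                        y = c0 * pairs$y))
    ab <- paste(a$class, b$class)
    expect_false(any(ab %in% c("equal equal_reversed",
                               "equal_reversed equal")))
  }
})

test_that("dominance ranking orders by severity with deterministic ties", {
  calls <- classifySpecificity(data.frame(
    gene = c("a", "b", "c", "d", "e"),
    x = c(0.9, 0.5, 0.3, 0.3, 0.05),
    y = c(0.05, 0.1, 0.0, 0.0, 0.9)))
  expect_equal(rankDominant(calls, "IUGR", 3), c("a", "b", "c"))
  expect_equal(rankDominant(calls, "IUGR", 4), c("a", "b", "c", "d"))
  expect_equal(rankDominant(calls, "PE", 1), "e")
  expect_warning(rankDominant(calls, "PE", 3), "qualify")
  ## mixed genes only back-fill after every dominant gene
  calls2 <- classifySpecificity(data.frame(
    gene = c("dom", "mixbig"), x = c(0.3, 2.0), y = c(0.05, 0.8)))
  expect_equal(calls2$class, c("IUGR_dominant", "mixed"))
  expect_equal(rankDominant(calls2, "IUGR", 2), c("dom", "mixbig"))
})

test_that("final targets are significant AND dominant-or-equal", {
  calls <- classifySpecificity(data.frame(
    gene = c("sig_eq", "sig_mixed", "top_pe_ns", "sig_iugr", "sig_rev",
             "i2", "i3"),
    x = c(0.5, 0.9, 0.0, 0.7, 0.45, 0.8, 0.75),
    y = c(0.5, 0.4, 1.2, 0.05, -0.45, 0.1, 0.0)))
  ## the three IUGR_dominant genes fill the top-3 list, so the mixed
  ## gene does not back-fill into it
  sig <- c("sig_eq", "sig_mixed", "sig_iugr", "sig_rev", "i2", "i3")
  out <- intersectTargets(sig, calls)
  expect_setequal(out$gene, c("sig_eq", "sig_iugr", "sig_rev", "i2",
                              "i3"))
  expect_equal(out$class[out$gene == "sig_eq"], "equal")
  expect_true(out$top_iugr[out$gene == "sig_iugr"])
  ## top-3 PE gene without significance is excluded
  expect_false("top_pe_ns" %in% out$gene)
  ## empty significant set gives an empty table
  expect_equal(nrow(intersectTargets(character(), calls)), 0L)
})

test_that("planted classes and significance are recovered at low noise", {
  ## effect 1.0 log2 with Ct noise 0.1 cycles: band-membership
  ## probabilities exceed 0.99 per gene, so recovery should be high
  kwHit <- 0L; kwTot <- 0L
  clsHit <- 0L; clsTot <- 0L
  for (s in 1:5) {
    run <- runQpcrPipeline(simulationConfig(nGenes = 100, noiseSd = 0.1,
                                            seed = 500 + s))
    nn <- run$truth[run$truth$class != "null", ]
    kwTot <- kwTot + nrow(nn)
    kwHit <- kwHit + sum(nn$gene %in% run$significant)
    got <- setNames(run$calls$class, run$calls$gene)[nn$gene]
    clsTot <- clsTot + nrow(nn)
    clsHit <- clsHit + sum(got == PLANTED_TO_CALL[nn$class])
  }
  expect_gte(kwHit / kwTot, 0.90)
  expect_gte(clsHit / clsTot, 0.90)
})

test_that("noise-free planted effects are classified and ranked exactly", {
  cfg <- simulationConfig(nGenes = 30, noiseSd = 1e-9, seed = 62)
  run <- runQpcrPipeline(cfg)
  truth <- run$truth
  nn <- truth[truth$class != "null", ]
  got <- setNames(run$calls$class, run$calls$gene)[nn$gene]
  expect_identical(unname(got), unname(PLANTED_TO_CALL[nn$class]))
  ## the three planted IUGR-only genes are exactly the top-3 list
  expect_setequal(rankDominant(run$calls, "IUGR", 3),
                  truth$gene[truth$class == "iugr_only"])
  expect_setequal(rankDominant(run$calls, "PE", 3),
                  truth$gene[truth$class == "pe_only"])
  ## and the report equals the planted significant equal/dominant set
  expect_setequal(run$targets$gene, nn$gene)
})
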