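## Synthetic-data generator: multi-study expression matrices, qPCR Ct
## tables with stable reference genes, RNA-QC records and planted
## per-gene disease effects. All randomness flows from a single master
## seed through deterministic per-component child seeds.

DEFAULT_GROUP_SIZES <- c(term = 13L, preterm = 7L, IUGR = 8L,
                         PE = 5L, "PE+IUGR" = 10L)

## Arm structure of the seven meta-analysis studies (control split into
## term/preterm where the source cohorts mixed both; zero = arm absent).
STUDY_DESIGNS <- data.frame(
  study_id  = paste0("study", 1:7),
  n_term    = c(0L, 4L, 4L, 19L, 0L, 20L, 11L),
  n_preterm = c(3L, 4L, 4L, 18L, 11L, 20L, 11L),
  n_iugr    = c(6L, 8L, 8L, 0L, 0L, 27L, 18L),
  n_pe      = c(0L, 8L, 0L, 23L, 12L, 19L, 0L),
  stringsAsFactors = FALSE)

childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 9973) %% 2147483629 + 1)
}

defaultEffectClasses <- function(genes) {
  n <- length(genes)
  counts <- c(iugr_only = 3L, pe_only = 3L, equal = 4L, equal_reversed = 2L)
  if (n < sum(counts) + 1L)
    stop("supply 'effectClass' explicitly for panels of fewer than ",
         sum(counts) + 1L, " genes")
  cls <- rep("null", n)
  cls[seq_len(sum(counts))] <- rep(names(counts), counts)
  setNames(cls, genes)
}

#' Configure the synthetic-data generator
#'
#' The defaults describe the emulated study conditions: a 200-gene qPCR
#' panel measured on the five clinical groups with sizes term 13,
#' preterm 7, IUGR 8, PE 5, PE+IUGR 10; planted log2 disease effects of
#' 1.0 on a small set of genes (3 IUGR-specific, 3 PE-specific, 4 equally
#' affected, 2 equally-but-oppositely affected, remainder null); additive
#' Gaussian noise of 0.3 (log2 units on expression, cycles on Ct); and
#' seven expression studies whose arm structure mirrors the heterogeneous
#' designs of the meta-analysed cohorts (some lack an IUGR or PE arm).
#'
#' Planted effect signs alternate between up- and down-regulation across
#' the non-null genes; the PE+IUGR group receives the sum of both disease
#' effects.
#'
#' @param genes gene ids (default \code{G001..G200}).
#' @param nGenes panel size used when \code{genes} is NULL.
#' @param nStudies number of expression studies (1..7 arm designs,
#'   recycled beyond 7).
#' @param effectClass named character vector gene -> effect class; when
#'   NULL the default planted mix above is used.
#' @param groupSizes named integer vector for the qPCR cohort.
#' @param effectSize planted log2 effect per disease.
#' @param noiseSd additive Gaussian noise sd (> 0).
#' @param ctBaseline Ct value of a transcript at log2 abundance zero.
#' @param referenceGenes stable reference genes appended to Ct tables.
#' @param qcFailFraction fraction of qPCR samples planted to fail RNA QC.
#' @param seed master seed (integer).
#' @return a \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nGenes = 20, seed = 7)
#' cfg
#' @export
simulationConfig <- function(genes = NULL, nGenes = 200L, nStudies = 7L,
                             effectClass = NULL,
                             groupSizes = DEFAULT_GROUP_SIZES,
                             effectSize = 1.0, noiseSd = 0.3,
                             ctBaseline = 30, referenceGenes = c("UBQ",
                                                                 "YWHAZ"),
                             qcFailFraction = 0, seed = 1L) {
  if (is.null(genes))
    genes <- sprintf("G%03d", seq_len(nGenes))
  genes <- as.character(genes)
  if (is.null(effectClass)) {
    effectClass <- defaultEffectClasses(genes)
  } else {
    effectClass <- unlist(effectClass)
    if (is.null(names(effectClass)))
      names(effectClass) <- genes[seq_along(effectClass)]
  }
  gs <- as.integer(groupSizes)
  names(gs) <- names(groupSizes)
  new("SimulationConfig", nStudies = as.integer(nStudies), genes = genes,
      effectClass = effectClass[genes], groupSizes = gs,
      effectSize = as.numeric(effectSize), noiseSd = as.numeric(noiseSd),
      ctBaseline = as.numeric(ctBaseline),
      referenceGenes = as.character(referenceGenes),
      qcFailFraction = as.numeric(qcFailFraction), seed = as.integer(seed))
}

#' Ground truth of the planted effects
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return data.frame with one row per gene: \code{gene}, \code{class},
#'   \code{effect_iugr}, \code{effect_pe} (log2 units), and
#'   \code{significant} (TRUE for every non-null gene). Effect signs
#'   alternate deterministically across the non-null genes.
#' @export
plantedTruth <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  cls <- config@effectClass
  e <- config@effectSize
  nonnull <- which(cls != "null")
  sgn <- rep(1, length(cls))
  sgn[nonnull] <- ifelse(seq_along(nonnull) %% 2L == 0L, -1, 1)
  ei <- ifelse(cls %in% c("iugr_only", "equal", "equal_reversed"), e, 0) * sgn
  ep <- ifelse(cls == "pe_only", e, 0) * sgn +
    ifelse(cls == "equal", e, 0) * sgn -
    ifelse(cls == "equal_reversed", e, 0) * sgn
  data.frame(gene = config@genes, class = unname(cls),
             effect_iugr = unname(ei), effect_pe = unname(ep),
             significant = unname(cls != "null"),
             stringsAsFactors = FALSE)
}

geneBaselines <- function(config) {
  set.seed(childSeed(config@seed, 0L))
  b <- runif(length(config@genes) + length(config@referenceGenes), 6, 12)
  setNames(b, c(config@genes, config@referenceGenes))
}

sampleEffect <- function(truth, groups) {
  ## per-gene planted log2 effect for each sample, given its clinical group
  eff <- matrix(0, nrow(truth), length(groups))
  eff[, groups == "IUGR"] <- truth$effect_iugr
  eff[, groups == "PE"] <- truth$effect_pe
  eff[, groups == "PE+IUGR"] <- truth$effect_iugr + truth$effect_pe
  eff
}

#' Simulate multi-study expression matrices with planted disease effects
#'
#' Each study's log2 expression value is gene baseline + planted effect
#' (for the disease arms the study contains; PE+IUGR samples would
#' receive both effects summed, though the emulated study designs carry
#' only isolated IUGR/PE arms) + Gaussian noise. Identical
#' configurations and seeds give byte-identical output.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{studies} (list of
#'   \linkS4class{ExpressionStudy}) and \code{truth} (the
#'   \code{\link{plantedTruth}} table).
#' @examples
#' sim <- simulateStudies(simulationConfig(nGenes = 20, nStudies = 2))
#' sim$studies[[1]]
#' @export
simulateStudies <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  truth <- plantedTruth(config)
  base <- geneBaselines(config)[config@genes]
  designs <- STUDY_DESIGNS[((seq_len(config@nStudies) - 1L) %% 7L) + 1L, ]
  designs$study_id <- paste0("study", seq_len(config@nStudies))
  studies <- vector("list", config@nStudies)
  for (i in seq_len(config@nStudies)) {
    d <- designs[i, ]
    groups <- rep(c("term", "preterm", "IUGR", "PE"),
                  c(d$n_term, d$n_preterm, d$n_iugr, d$n_pe))
    arms <- c(IUGR = d$n_iugr, PE = d$n_pe)
    present <- arms[arms > 0L]
    if (any(present < 2L))
      stop("study ", d$study_id, " includes a group with fewer than 2 ",
           "samples")
    set.seed(childSeed(config@seed, i))
    m <- matrix(base, length(base), length(groups)) +
      sampleEffect(truth, groups) +
      matrix(rnorm(length(base) * length(groups), 0, config@noiseSd),
             length(base), length(groups))
    dimnames(m) <- list(config@genes,
                        sprintf("%s_S%02d", d$study_id,
                                seq_along(groups)))
    studies[[i]] <- ExpressionStudy(m, groups, d$study_id)
  }
  list(studies = studies, truth = truth)
}

#' Simulate a qPCR Ct table with stable reference genes and QC records
#'
#' Raw threshold cycles are generated as
#' \code{Ct = ctBaseline - log2 expression + noise}, so a planted +1 log2
#' effect lowers Ct by one cycle. Reference genes carry no group effect.
#' Every sample receives an RNA-QC record; a configurable fraction is
#' planted to fail the RIN criterion.
#'
#' @param config a \linkS4class{SimulationConfig} (needs >= 2 reference
#'   genes).
#' @return list with elements \code{ct} (a \linkS4class{CtExperiment})
#'   and \code{truth}.
#' @examples
#' sim <- simulateCtTable(simulationConfig(nGenes = 20))
#' sim$ct
#' @export
simulateCtTable <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (length(config@referenceGenes) < 2L)
    stop("at least two stable reference genes are required")
  truth <- plantedTruth(config)
  base <- geneBaselines(config)
  gs <- config@groupSizes[VALID_GROUPS]
  groups <- rep(VALID_GROUPS, gs)
  tag <- c(term = "T", preterm = "P", IUGR = "I", PE = "E", "PE+IUGR" = "B")
  samples <- unlist(lapply(VALID_GROUPS, function(g)
    sprintf("%s%02d", tag[[g]], seq_len(gs[[g]]))))
  allGenes <- c(config@genes, config@referenceGenes)
  expr <- matrix(base[allGenes], length(allGenes), length(samples))
  expr[seq_along(config@genes), ] <- expr[seq_along(config@genes), ] +
    sampleEffect(truth, groups)
  set.seed(childSeed(config@seed, 101L))
  ct <- config@ctBaseline - expr +
    matrix(rnorm(length(expr), 0, config@noiseSd), nrow(expr))
  dimnames(ct) <- list(allGenes, samples)
  n <- length(samples)
  nFail <- floor(config@qcFailFraction * n)
  fail <- if (nFail > 0) sample(n, nFail) else integer()
  qc <- data.frame(sample = samples,
                   rin = runif(n, 6.6, 9.8),
                   ratio_260_280 = runif(n, 2.01, 2.15),
                   ratio_260_230 = runif(n, 1.85, 2.2),
                   yield = runif(n, 10, 120))
  qc$rin[fail] <- runif(nFail, 3, 5.9)
  list(ct = CtExperiment(ct, groups, qc,
                         referenceGenes = config@referenceGenes),
       truth = truth)
}

#' Generate a planted-community interaction edge list
#'
#' Emulates a substrate-specific interaction network: dense high-score
#' edges within each community, sparse low-score (below the
#' medium-confidence cutoff) edges between communities, so the planted
#' communities are recoverable by \code{\link{mclCluster}} after
#' \code{\link{filterEdges}}.
#'
#' @param communities named list of character vectors (community ->
#'   member node ids).
#' @param seed integer seed.
#' @param pIntra probability of an intra-community edge (a spanning ring
#'   is always added to keep communities connected).
#' @param interScore range of scores for the sparse inter-community
#'   edges (kept at or below 0.4 by default so the confidence filter
#'   removes them).
#' @return data.frame with columns \code{node_a}, \code{node_b},
#'   \code{score}.
#' @export
simulateEdgeList <- function(communities, seed = 1L, pIntra = 0.8,
                             interScore = c(0.15, 0.4)) {
  set.seed(childSeed(seed, 7L))
  edges <- list()
  for (members in communities) {
    members <- sort(members, method = "radix")
    k <- length(members)
    ring <- data.frame(node_a = members,
                       node_b = members[c(2:k, 1)],
                       score = round(runif(k, 0.6, 0.95), 3))
    pairs <- t(combn(members, 2))
    keep <- runif(nrow(pairs)) < pIntra
    extra <- data.frame(node_a = pairs[keep, 1], node_b = pairs[keep, 2],
                        score = round(runif(sum(keep), 0.5, 0.95), 3))
    edges[[length(edges) + 1L]] <- rbind(ring, extra)
  }
  reps <- names(communities)
  for (i in seq_along(communities)) for (j in seq_along(communities)) {
    if (i < j) {
      a <- communities[[i]][1:2]
      b <- communities[[j]][1:2]
      edges[[length(edges) + 1L]] <-
        data.frame(node_a = a, node_b = b,
                   score = round(runif(2, interScore[1], interScore[2]), 3))
    }
  }
  out <- do.call(rbind, edges)
  key <- ifelse(out$node_a < out$node_b,
                paste(out$node_a, out$node_b),
                paste(out$node_b, out$node_a))
  out <- out[!duplicated(key), ]
  out <- out[order(out$node_a, out$node_b, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Write the full synthetic fixture bundle to disk
#'
#' Writes one tab-separated expression matrix per study, a sample
#' annotation table, the Ct and QC tables, the planted-truth table, an
#' annotation-flag table (every gene flagged, emulating the curated
#' placental-relevance input of the candidate selection), and a
#' round-trippable plain-text configuration file.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param dir output directory (created if missing).
#' @return invisibly, a named character vector of the files written.
#' @seealso \code{\link{readSimulationConfig}}
#' @export
writeFixtureBundle <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulateStudies(config)
  qpcr <- simulateCtTable(config)
  files <- c()
  ann <- list()
  for (st in sim$studies) {
    f <- file.path(dir, paste0(studyId(st), "_matrix.tsv"))
    writeExpressionMatrix(assay(st, "exprs"), f)
    files[paste0("matrix_", studyId(st))] <- f
    ann[[studyId(st)]] <- data.frame(sample = colnames(st),
                                     group = unname(sampleGroups(st)),
                                     study = studyId(st))
  }
  f <- file.path(dir, "sample_annotations.tsv")
  writeResultsTable(do.call(rbind, ann), f)
  files["annotations"] <- f
  f <- file.path(dir, "ct_table.tsv")
  writeCtTable(qpcr$ct, f)
  files["ct"] <- f
  f <- file.path(dir, "qc_table.tsv")
  writeResultsTable(qcRecords(qpcr$ct), f)
  files["qc"] <- f
  f <- file.path(dir, "truth_table.tsv")
  writeResultsTable(sim$truth, f)
  files["truth"] <- f
  f <- file.path(dir, "annotation_flags.tsv")
  writeResultsTable(data.frame(gene = config@genes, annotated = TRUE), f)
  files["flags"] <- f
  f <- file.path(dir, "sim_config.txt")
  writeSimulationConfig(config, f)
  files["config"] <- f
  invisible(files)
}

#' Serialise / deserialise a SimulationConfig as flat key=value text
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param path file path.
#' @return \code{readSimulationConfig} returns a
#'   \linkS4class{SimulationConfig} identical to the one written.
#' @export
writeSimulationConfig <- function(config, path) {
  kv <- c(n_studies = config@nStudies,
          genes = paste(config@genes, collapse = ","),
          effect_class = paste(config@effectClass[config@genes],
                               collapse = ","),
          group_sizes = paste(names(config@groupSizes),
                              config@groupSizes, sep = ":",
                              collapse = ","),
          effect_size = config@effectSize,
          noise_sd = config@noiseSd,
          ct_baseline = config@ctBaseline,
          reference_genes = paste(config@referenceGenes, collapse = ","),
          qc_fail_fraction = config@qcFailFraction,
          seed = config@seed)
  writeLines(paste(names(kv), kv, sep = "="), path)
  invisible(path)
}

#' @rdname writeSimulationConfig
#' @export
readSimulationConfig <- function(path) {
  kv <- readKeyValueFile(path)
  gs <- strsplit(strsplit(kv[["group_sizes"]], ",")[[1]], ":")
  groupSizes <- setNames(as.integer(vapply(gs, `[`, "", 2)),
                         vapply(gs, `[`, "", 1))
  genes <- strsplit(kv[["genes"]], ",")[[1]]
  simulationConfig(genes = genes,
                   nStudies = as.integer(kv[["n_studies"]]),
                   effectClass = setNames(
                     strsplit(kv[["effect_class"]], ",")[[1]], genes),
                   groupSizes = groupSizes,
                   effectSize = as.numeric(kv[["effect_size"]]),
                   noiseSd = as.numeric(kv[["noise_sd"]]),
                   ctBaseline = as.numeric(kv[["ct_baseline"]]),
                   referenceGenes = strsplit(kv[["reference_genes"]],
                                             ",")[[1]],
                   qcFailFraction = as.numeric(kv[["qc_fail_fraction"]]),
                   seed = as.integer(kv[["seed"]]))
}
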