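## Pipeline orchestration: a flat key=value configuration collecting all
## thresholds in one place, and stage runners whose only side effects
## are their declared files, so chained stage runs and the "all" runner
## are byte-identical.

PIPELINE_STAGES <- c("simulate", "screen", "qpcr", "stats", "cluster",
                     "specificity", "mcl", "report")

PIPELINE_DEFAULTS <- list(
  out_dir = "pipeline_out",
  seed = 1L,
  n_genes = 200L,
  n_studies = 7L,
  effect_size = 1.0,
  noise_sd = 0.3,
  ct_baseline = 30,
  qc_fail_fraction = 0,
  min_studies = 4L,
  top_k = 12L,
  fc_threshold = 1.14,
  epsilon = 0.2,
  alpha = 0.05,
  edge_score = 0.4,
  inflation = 2.0,
  top_n = 3L,
  edge_list = "")   # empty: use the packaged synthetic interaction fixture

#' Assemble a pipeline configuration
#'
#' Collects every tunable threshold of the pipeline (candidate-selection
#' vote count and top-list length, fold-change cutoff 1.14, error
#' threshold 0.2, significance level 0.05, interaction-confidence cutoff
#' 0.4, MCL inflation 2.0) together with the generator settings and the
#' master seed. \code{readPipelineConfig} parses the same set of keys
#' from a flat \code{key=value} text file; unknown keys are errors so
#' that a typo in a threshold cannot pass silently.
#'
#' @param ... overrides of the default keys (see
#'   \code{placentaScreen:::PIPELINE_DEFAULTS}).
#' @return named list of settings.
#' @export
pipelineConfig <- function(...) {
  over <- list(...)
  bad <- setdiff(names(over), names(PIPELINE_DEFAULTS))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  cfg <- PIPELINE_DEFAULTS
  cfg[names(over)] <- over
  for (k in c("seed", "n_genes", "n_studies", "min_studies", "top_k",
              "top_n"))
    cfg[[k]] <- as.integer(cfg[[k]])
  for (k in c("effect_size", "noise_sd", "ct_baseline", "qc_fail_fraction",
              "fc_threshold", "epsilon", "alpha", "edge_score",
              "inflation"))
    cfg[[k]] <- as.numeric(cfg[[k]])
  cfg
}

#' @rdname pipelineConfig
#' @param path path to a flat key=value configuration file.
#' @export
readPipelineConfig <- function(path) {
  kv <- readKeyValueFile(path)
  do.call(pipelineConfig, kv)
}

stagePaths <- function(cfg) {
  out <- cfg$out_dir
  fix <- file.path(out, "fixtures")
  list(
    fixtures = fix,
    de_dir = file.path(out, "de"),
    candidates = file.path(out, "candidates.tsv"),
    fold_change = file.path(out, "fold_change.tsv"),
    pairs = file.path(out, "pairs.tsv"),
    kw = file.path(out, "group_stats.tsv"),
    dunn = file.path(out, "dunn_comparisons.tsv"),
    significant = file.path(out, "significant_genes.txt"),
    cluster_dir = file.path(out, "cluster"),
    scatter = file.path(out, "scatter_table.tsv"),
    mcl_clusters = file.path(out, "mcl_clusters.tsv"),
    mcl_membership = file.path(out, "mcl_membership.tsv"),
    report = file.path(out, "final_targets.tsv"))
}

simConfigFromPipeline <- function(cfg) {
  simulationConfig(nGenes = cfg$n_genes, nStudies = cfg$n_studies,
                   effectSize = cfg$effect_size, noiseSd = cfg$noise_sd,
                   ctBaseline = cfg$ct_baseline,
                   qcFailFraction = cfg$qc_fail_fraction,
                   seed = cfg$seed)
}

pipelineLog <- function(stage, cfg, ...) {
  message(sprintf("[%s] seed=%d %s", stage, cfg$seed,
                  paste(..., collapse = " ")))
}

#' Run one pipeline stage (or all of them)
#'
#' Stages: \code{simulate} writes the synthetic fixture bundle;
#' \code{screen} quantile-normalises each study, computes per-study
#' moderated-t differential expression for both disease contrasts and
#' selects cross-study candidates; \code{qpcr} applies the RNA-QC filter
#' and comparative-Ct quantification; \code{stats} runs the five-group
#' Kruskal-Wallis/Dunn tests per gene; \code{cluster} builds the 2D
#' average-linkage clustering with newick and clustered-matrix exports;
#' \code{specificity} classifies the dual-disease scatter; \code{mcl}
#' filters and Markov-clusters the interaction edge list; \code{report}
#' intersects the significant set with the dominance/equality classes
#' into the final target table. \code{runPipeline} chains them in that
#' order. Outputs are deterministic given the configuration (identical
#' config and seed give byte-identical files).
#'
#' @param stage one of \code{simulate}, \code{screen}, \code{qpcr},
#'   \code{stats}, \code{cluster}, \code{specificity}, \code{mcl},
#'   \code{report}, \code{all}.
#' @param config a configuration from \code{\link{pipelineConfig}} or
#'   \code{\link{readPipelineConfig}}.
#' @param quiet suppress progress messages.
#' @return invisibly, the paths written by the stage (for \code{report},
#'   the final target table path).
#' @export
runStage <- function(stage, config, quiet = FALSE) {
  if (identical(stage, "all")) return(runPipeline(config, quiet = quiet))
  if (!stage %in% PIPELINE_STAGES)
    stop("unknown subcommand '", stage, "'")
  p <- stagePaths(config)
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  if (!quiet) pipelineLog(stage, config)
  switch(stage,
    simulate = {
      simCfg <- simConfigFromPipeline(config)
      invisible(writeFixtureBundle(simCfg, p$fixtures))
    },
    screen = {
      simCfg <- readSimulationConfig(file.path(p$fixtures,
                                               "sim_config.txt"))
      ann <- readAnnotationFlags(file.path(p$fixtures,
                                           "annotation_flags.tsv"))
      samples <- read.delim(file.path(p$fixtures,
                                      "sample_annotations.tsv"),
                            stringsAsFactors = FALSE)
      if (!dir.exists(p$de_dir)) dir.create(p$de_dir)
      results <- list()
      for (sid in unique(samples$study)) {
        m <- readExpressionMatrix(file.path(p$fixtures,
                                            paste0(sid, "_matrix.tsv")))
        sub <- samples[samples$study == sid, ]
        es <- ExpressionStudy(quantileNormalize(m),
                              setNames(sub$group, sub$sample)[colnames(m)],
                              sid)
        for (ctr in intersect(c("IUGR", "PE"), sampleGroups(es))) {
          de <- deStatistics(es, ctr)
          writeResultsTable(de, file.path(p$de_dir,
                                          sprintf("%s_%s.tsv", sid, ctr)))
          results[[paste(sid, ctr, sep = "_")]] <- de
        }
      }
      cand <- selectCandidates(results, ann,
                               minStudies = config$min_studies,
                               k = config$top_k)
      writeResultsTable(cand, p$candidates)
      invisible(p$candidates)
    },
    qpcr = {
      ct <- readCtTable(file.path(p$fixtures, "ct_table.tsv"),
                        file.path(p$fixtures, "qc_table.tsv"))
      pass <- qcFilter(qcRecords(ct))
      fc <- computeFoldChange(computeDeltaCt(ct, samples = pass))
      writeResultsTable(fc, p$fold_change)
      writeResultsTable(groupLogFC(fc), p$pairs)
      invisible(c(p$fold_change, p$pairs))
    },
    stats = {
      fc <- read.delim(p$fold_change, stringsAsFactors = FALSE)
      res <- testGeneExpression(fc, alpha = config$alpha)
      writeResultsTable(kwTable(res), p$kw)
      writeResultsTable(dunnTable(res), p$dunn)
      writeLines(flagSignificant(res), p$significant)
      invisible(c(p$kw, p$dunn, p$significant))
    },
    cluster = {
      fc <- read.delim(p$fold_change, stringsAsFactors = FALSE)
      m <- tapply(fc$log2_fc, list(fc$gene, fc$sample), mean)
      m <- m[sort(rownames(m), method = "radix"),
             sort(colnames(m), method = "radix")]
      gt <- averageLinkage(centeredCorrelationDistance(m, "genes"),
                           axis = "genes")
      st <- averageLinkage(centeredCorrelationDistance(m, "samples"),
                           axis = "samples")
      ann <- setNames(fc$group[!duplicated(fc$sample)],
                      fc$sample[!duplicated(fc$sample)])
      hm <- buildHeatmap(m, gt, st, annotations = ann)
      if (!dir.exists(p$cluster_dir)) dir.create(p$cluster_dir)
      writeNewick(gt, file.path(p$cluster_dir, "gene_tree.nwk"))
      writeNewick(st, file.path(p$cluster_dir, "sample_tree.nwk"))
      writeClusteredMatrix(hm, p$cluster_dir)
      invisible(p$cluster_dir)
    },
    specificity = {
      pairs <- read.delim(p$pairs, stringsAsFactors = FALSE)
      calls <- classifySpecificity(pairs,
                                   threshold = config$fc_threshold,
                                   epsilon = config$epsilon)
      writeResultsTable(calls, p$scatter)
      invisible(p$scatter)
    },
    mcl = {
      edgePath <- config$edge_list
      if (!nzchar(edgePath))
        edgePath <- system.file("extdata",
                                "synthetic_interaction_edges.tsv",
                                package = "placentaScreen")
      g <- filterEdges(readEdgeList(edgePath),
                       minScore = config$edge_score)
      res <- mclCluster(g, inflation = config$inflation)
      writeLines(vapply(clusters(res), paste, "", collapse = "\t"),
                 p$mcl_clusters)
      writeResultsTable(data.frame(node = names(membership(res)),
                                   cluster = as.integer(membership(res))),
                       p$mcl_membership)
      invisible(c(p$mcl_clusters, p$mcl_membership))
    },
    report = {
      sig <- readLines(p$significant)
      calls <- read.delim(p$scatter, stringsAsFactors = FALSE)
      targets <- intersectTargets(sig, calls, n = config$top_n)
      writeResultsTable(targets, p$report)
      invisible(p$report)
    })
}

#' @rdname runStage
#' @export
runPipeline <- function(config, quiet = FALSE) {
  for (stage in PIPELINE_STAGES)
    runStage(stage, config, quiet = quiet)
  invisible(stagePaths(config)$report)
}
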