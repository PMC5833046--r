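## RNA-QC sample filtering and comparative-Ct (2^-ddCt) relative
## quantification with multi-reference normalisation.

#' Filter samples on RNA quality criteria
#'
#' A sample passes iff all four criteria hold strictly:
#' RIN > 6, A260/280 > 2.0, A260/230 > 1.8 and RNA yield > 5 ng/ul.
#'
#' @param records data.frame with columns \code{sample}, \code{rin},
#'   \code{ratio_260_280}, \code{ratio_260_230}, \code{yield} (e.g.
#'   \code{\link{qcRecords}} of a \linkS4class{CtExperiment}).
#' @return character vector of passing sample ids.
#' @examples
#' qcFilter(data.frame(sample = c("a", "b"), rin = c(7.1, 6.0),
#'                     ratio_260_280 = 2.05, ratio_260_230 = 1.9,
#'                     yield = 8))
#' @export
qcFilter <- function(records) {
  records <- as.data.frame(records)
  if (anyDuplicated(records$sample)) stop("duplicate sample id")
  pass <- records$rin > 6 & records$ratio_260_280 > 2.0 &
    records$ratio_260_230 > 1.8 & records$yield > 5
  as.character(records$sample[pass])
}

#' Per-sample delta-Ct against the mean of the reference genes
#'
#' \code{dCt(sample, target) = Ct(target) - mean over reference genes of
#' Ct(reference)} in the same sample. With the default dual-reference
#' normalisation this is the mean of the UBQ and YWHAZ threshold cycles.
#'
#' @param ct a \linkS4class{CtExperiment}.
#' @param referenceGenes reference gene ids (default: those stored in
#'   the object). Every reference gene must be measured (non-missing) in
#'   every sample.
#' @param samples optional subset of samples to keep (e.g. the output of
#'   \code{\link{qcFilter}}).
#' @return long data.frame: \code{sample}, \code{group}, \code{gene},
#'   \code{delta_ct}.
#' @export
computeDeltaCt <- function(ct, referenceGenes = NULL, samples = NULL) {
  stopifnot(is(ct, "CtExperiment"))
  if (is.null(referenceGenes)) referenceGenes <- referenceGenes(ct)
  m <- assay(ct, "ct")
  if (!all(referenceGenes %in% rownames(m)))
    stop("reference gene(s) not measured: ",
         paste(setdiff(referenceGenes, rownames(m)), collapse = ", "))
  if (!is.null(samples)) m <- m[, colnames(m) %in% samples, drop = FALSE]
  refs <- m[referenceGenes, , drop = FALSE]
  if (anyNA(refs))
    stop("missing reference Ct in sample(s): ",
         paste(colnames(refs)[colSums(is.na(refs)) > 0], collapse = ", "))
  refMean <- colMeans(refs)
  targets <- setdiff(rownames(m), referenceGenes)
  dct <- m[targets, , drop = FALSE] -
    matrix(refMean, length(targets), ncol(m), byrow = TRUE)
  grp <- sampleGroups(ct)[colnames(m)]
  data.frame(sample = rep(colnames(m), each = length(targets)),
             group = rep(unname(grp), each = length(targets)),
             gene = rep(targets, times = ncol(m)),
             delta_ct = as.vector(dct), stringsAsFactors = FALSE)
}

#' Per-sample fold change by the comparative-Ct method
#'
#' \code{ddCt(sample, gene) = dCt(sample, gene) - mean dCt over the
#' control group}; \code{FC = 2^-ddCt}; \code{log2 FC = -ddCt}. The
#' control aggregate is the arithmetic mean of the term-control
#' delta-Ct values, so the control group's log2 fold changes average to
#' zero exactly.
#'
#' @param delta long delta-Ct table from \code{\link{computeDeltaCt}}.
#' @param controlGroup the reference clinical group (default "term").
#' @return the input with added columns \code{ddct}, \code{fc},
#'   \code{log2_fc}.
#' @export
computeFoldChange <- function(delta, controlGroup = "term") {
  ctl <- delta[delta$group == controlGroup, ]
  if (nrow(ctl) == 0L) stop("empty control group '", controlGroup, "'")
  ctlMean <- tapply(ctl$delta_ct, ctl$gene, mean)
  out <- delta
  out$ddct <- out$delta_ct - as.numeric(ctlMean[out$gene])
  out$fc <- 2^(-out$ddct)
  out$log2_fc <- -out$ddct
  out
}

#' Average log2 fold change per gene in the isolated disease groups
#'
#' Defines the coordinates of the dual-disease scatter: \code{x} is the
#' mean log2 fold change over IUGR samples and \code{y} over PE samples,
#' both relative to term controls. PE+IUGR samples are excluded from
#' both axes (the scatter contrasts the isolated diseases); they remain
#' part of the five-group statistical testing.
#'
#' @param fc fold-change table from \code{\link{computeFoldChange}}.
#' @return data.frame with one row per gene: \code{gene}, \code{x},
#'   \code{y}.
#' @export
groupLogFC <- function(fc) {
  for (g in c("IUGR", "PE"))
    if (!any(fc$group == g)) stop("group '", g, "' absent")
  iugr <- fc[fc$group == "IUGR", ]
  pe <- fc[fc$group == "PE", ]
  genes <- sort(unique(fc$gene), method = "radix")
  x <- tapply(iugr$log2_fc, iugr$gene, mean)[genes]
  y <- tapply(pe$log2_fc, pe$gene, mean)[genes]
  data.frame(gene = genes, x = as.numeric(x), y = as.numeric(y),
             stringsAsFactors = FALSE, row.names = NULL)
}
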