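## Per-study differential-expression screening and cross-study
## vote-count candidate selection. The per-study statistic is a
## moderated t with empirical-Bayes variance shrinkage estimated by the
## method of moments on the log sample variances.

#' Quantile-normalise an expression matrix
#'
#' Forces every column (sample) onto the same empirical distribution:
#' the sorted values of each column are replaced by the row-wise means
#' of the per-column sorted values; ties within a column receive the
#' mean of the normalised values they span. Delegates to
#' \code{\link[limma]{normalizeQuantiles}}. A single-column matrix is
#' returned unchanged with a warning (nothing to normalise against).
#'
#' @param mat numeric matrix, genes x samples, no missing values.
#' @return matrix of the same dimensions and dimnames.
#' @examples
#' quantileNormalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantileNormalize <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing values are not supported")
  if (ncol(mat) < 2L) {
    warning("single-column matrix returned unchanged")
    return(mat)
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Moderated variance shrinkage by method of moments
#'
#' Fits the scaled-F model for gene-wise sample variances: given
#' residual variances \code{s2} on \code{df} degrees of freedom, the
#' prior \code{(d0, s0^2)} is estimated from the first two moments of
#' \code{log(s2)} and each variance is shrunk to
#' \code{(d0*s0^2 + df*s2) / (d0 + df)}. When the moment estimate of
#' \code{d0} is non-positive or infinite it is capped at 50.
#'
#' @param s2 gene-wise sample variances.
#' @param df residual degrees of freedom (single value or per gene).
#' @param d0 optionally force the prior degrees of freedom (e.g.
#'   \code{Inf} for complete shrinkage to \code{s0^2}).
#' @return list with \code{d0}, \code{s02} and \code{s2Shrunk}.
#' @export
squeezeVariances <- function(s2, df, d0 = NULL) {
  df <- rep_len(df, length(s2))
  ok <- s2 > 0 & is.finite(s2)
  e <- log(s2[ok]) - digamma(df[ok] / 2) + log(df[ok] / 2)
  if (is.null(d0)) {
    evar <- var(e) - mean(trigamma(df[ok] / 2))
    if (!is.finite(evar) || evar <= 0) {
      d0 <- 50
    } else {
      d0 <- 2 * trigammaInverse(evar)
      if (!is.finite(d0) || d0 <= 0) d0 <- 50
    }
  }
  if (is.finite(d0)) {
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    s2Shrunk <- (d0 * s02 + df * s2) / (d0 + df)
  } else {
    s02 <- exp(mean(e))
    s2Shrunk <- rep_len(s02, length(s2))
  }
  list(d0 = d0, s02 = s02, s2Shrunk = s2Shrunk)
}

trigammaInverse <- function(x) {
  ## solve trigamma(y) = x by Newton iteration (x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

#' Per-study differential expression for one disease contrast
#'
#' For every gene: log2 fold change = mean(disease) - mean(control),
#' a moderated t statistic using the shrunken variance from
#' \code{\link{squeezeVariances}} (pooled two-group variance, df =
#' n1 + n2 - 2), and a two-sided p value from a t distribution on
#' df + d0 degrees of freedom. Genes are ranked 1-based among
#' up-regulated (largest fold change first) and among down-regulated
#' (smallest first); ties are broken by smaller p, then gene id.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param contrast disease group to contrast ("IUGR" or "PE").
#' @param controlGroups groups pooled as control (default term and
#'   preterm).
#' @param d0 optionally force the prior degrees of freedom.
#' @return data.frame with columns \code{gene}, \code{log2_fc},
#'   \code{t}, \code{p}, \code{rank_up}, \code{rank_down} and
#'   attributes \code{studyId}, \code{contrast}, \code{d0}.
#' @export
deStatistics <- function(study, contrast,
                         controlGroups = CONTROL_GROUPS, d0 = NULL) {
  stopifnot(is(study, "ExpressionStudy"))
  grp <- sampleGroups(study)
  dis <- grp == contrast
  ctl <- grp %in% controlGroups
  if (sum(dis) == 0L)
    stop("contrast group '", contrast, "' absent from study ",
         studyId(study))
  if (sum(dis) < 2L || sum(ctl) < 2L)
    stop("need >= 2 samples in both the contrast and control groups")
  m <- assay(study, "exprs")
  x1 <- m[, dis, drop = FALSE]
  x0 <- m[, ctl, drop = FALSE]
  n1 <- ncol(x1); n0 <- ncol(x0)
  fc <- rowMeans(x1) - rowMeans(x0)
  dg <- n1 + n0 - 2
  s2 <- (rowSums((x1 - rowMeans(x1))^2) +
           rowSums((x0 - rowMeans(x0))^2)) / dg
  sq <- squeezeVariances(s2, dg, d0 = d0)
  se <- sqrt(sq$s2Shrunk * (1 / n1 + 1 / n0))
  t <- ifelse(fc == 0, 0, fc / se)
  t[se == 0 & fc != 0] <- sign(fc[se == 0 & fc != 0]) * Inf
  dfTotal <- dg + sq$d0
  p <- ifelse(fc == 0, 1, 2 * pt(-abs(t), df = dfTotal))
  genes <- rownames(m)
  rankUp <- integer(length(fc))
  rankUp[order(-fc, p, genes, method = "radix")] <- seq_along(fc)
  rankDown <- integer(length(fc))
  rankDown[order(fc, p, genes, method = "radix")] <- seq_along(fc)
  out <- data.frame(gene = genes, log2_fc = unname(fc), t = unname(t),
                    p = unname(p), rank_up = rankUp,
                    rank_down = rankDown, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "studyId") <- studyId(study)
  attr(out, "contrast") <- contrast
  attr(out, "d0") <- sq$d0
  out
}

#' Top-k up- and down-regulated genes of a study contrast
#'
#' @param de a result from \code{\link{deStatistics}}.
#' @param k list length (default 12).
#' @return list with character vectors \code{up} and \code{down}, each
#'   ordered by rank.
#' @export
rankTopK <- function(de, k = 12L) {
  if (k > nrow(de)) stop("k exceeds the number of genes")
  list(up = de$gene[order(de$rank_up)][seq_len(k)],
       down = de$gene[order(de$rank_down)][seq_len(k)])
}

#' Cross-study vote-count candidate selection
#'
#' A gene is selected iff it (i) is measured in more than
#' \code{minStudies - 1} studies (strict "more than 3" reading: at least
#' 4 by default), (ii) appears in the top-\code{k} up- or down-regulated
#' list of at least one study contrast, and (iii) carries a curated
#' annotation flag (an input, not computed). The cross-study log2
#' fold-change range over all contrasts where the gene was measured is
#' reported per selected gene.
#'
#' @param results list of \code{\link{deStatistics}} results (typically
#'   one per study x contrast).
#' @param annotations named logical vector gene -> flag (see
#'   \code{\link{readAnnotationFlags}}).
#' @param minStudies minimum number of distinct studies a gene must be
#'   measured in.
#' @param k top-list length.
#' @return data.frame of selected genes with columns \code{gene},
#'   \code{n_studies}, \code{best_up_rank}, \code{best_down_rank},
#'   \code{annotated}, \code{fc_min}, \code{fc_max}, \code{fc_range}
#'   (a "min~max" display string).
#' @export
selectCandidates <- function(results, annotations, minStudies = 4L,
                             k = 12L) {
  if (!length(results)) stop("at least one study result is required")
  recs <- lapply(results, function(de) {
    top <- rankTopK(de, k = min(k, nrow(de)))
    data.frame(gene = de$gene, study = attr(de, "studyId"),
               log2_fc = de$log2_fc,
               in_top = de$gene %in% c(top$up, top$down),
               rank_up = de$rank_up, rank_down = de$rank_down,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, recs)
  genes <- sort(unique(all$gene), method = "radix")
  nStudies <- vapply(genes, function(g)
    length(unique(all$study[all$gene == g])), integer(1))
  anyTop <- vapply(genes, function(g) any(all$in_top[all$gene == g]),
                   logical(1))
  flag <- vapply(genes, function(g) isTRUE(annotations[[g]]), logical(1))
  sel <- nStudies >= minStudies & anyTop & flag
  out <- lapply(genes[sel], function(g) {
    sub <- all[all$gene == g, ]
    data.frame(gene = g, n_studies = length(unique(sub$study)),
               best_up_rank = min(sub$rank_up),
               best_down_rank = min(sub$rank_down),
               annotated = TRUE,
               fc_min = min(sub$log2_fc), fc_max = max(sub$log2_fc),
               stringsAsFactors = FALSE)
  })
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(gene = character(), n_studies = integer(),
               best_up_rank = integer(), best_down_rank = integer(),
               annotated = logical(), fc_min = numeric(),
               fc_max = numeric())
  out$fc_range <- if (nrow(out))
    sprintf("%.2f~%.2f", out$fc_min, out$fc_max) else character()
  rownames(out) <- NULL
  out
}
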