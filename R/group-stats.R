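## Tie-corrected Kruskal-Wallis test and Dunn's multiple-comparison
## post-hoc, implemented from the rank formulas (mid-ranks throughout).

#' Tie-corrected Kruskal-Wallis test
#'
#' Mid-ranks are assigned across all observations and
#' \deqn{H = \left[\frac{12}{N(N+1)} \sum_j R_j^2/n_j - 3(N+1)\right] / C,
#'   \quad C = 1 - \sum_t (t^3 - t)/(N^3 - N)}
#' with the sum over tie groups of size \eqn{t}. The p value comes from
#' a chi-square distribution on (groups - 1) degrees of freedom, the
#' approximation used by the usual statistical software; an exact
#' permutation mode enumerating all group assignments is available for
#' small samples. When all observations are identical, H is defined as 0
#' and p as 1.
#'
#' @param values numeric observations.
#' @param groups group label per observation (>= 2 groups, each
#'   non-empty).
#' @param exact if TRUE (only allowed for <= 12 observations in total),
#'   the p value is the exact permutation tail probability
#'   \eqn{P(H \ge H_{obs})} over all distinct assignments of the
#'   observations to the groups.
#' @return list with \code{H}, \code{df}, \code{p}.
#' @examples
#' kruskalWallis(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
#'               rep(c("a", "b", "c"), each = 3))  # H = 7.2
#' @export
kruskalWallis <- function(values, groups, exact = FALSE) {
  groups <- as.character(groups)
  if (length(values) != length(groups))
    stop("'values' and 'groups' lengths differ")
  g <- unique(groups)
  if (length(g) < 2L) stop("at least two groups are required")
  N <- length(values)
  df <- length(g) - 1L
  r <- rank(values)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C <= 0) return(list(H = 0, df = df, p = 1))
  Rj <- tapply(r, groups, sum)
  nj <- tabulate(factor(groups, levels = names(Rj)))
  H <- (12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)) / C
  H <- max(H, 0)
  if (exact) {
    if (N > 12L) stop("exact mode is limited to 12 observations")
    p <- exactKWPValue(r, groups, H, C)
  } else {
    p <- pchisq(H, df, lower.tail = FALSE)
  }
  list(H = H, df = df, p = p)
}

exactKWPValue <- function(r, groups, Hobs, C) {
  ## enumerate all distinct assignments of the mid-ranks to the groups
  N <- length(r)
  lev <- unique(groups)
  nj <- tabulate(factor(groups, levels = lev))
  const <- 12 / (N * (N + 1))
  hFor <- function(rankSets) {
    (const * sum(vapply(rankSets, sum, 0)^2 / nj) - 3 * (N + 1)) / C
  }
  count <- 0
  total <- 0
  recurse <- function(remaining, gi, acc) {
    if (gi == length(nj)) {
      h <- hFor(c(acc, list(remaining)))
      total <<- total + 1
      if (h >= Hobs - 1e-12) count <<- count + 1
      return(invisible())
    }
    sel <- combn(length(remaining), nj[gi])
    for (k in seq_len(ncol(sel))) {
      idx <- sel[, k]
      recurse(remaining[-idx], gi + 1L, c(acc, list(remaining[idx])))
    }
  }
  recurse(r, 1L, list())
  count / total
}

#' Dunn's multiple comparisons against a control group
#'
#' For each non-control group j,
#' \deqn{z_j = \frac{\bar R_c - \bar R_j}{\sqrt{\left[\frac{N(N+1)}{12} -
#'   \frac{\sum_t (t^3 - t)}{12(N-1)}\right]\left(\frac{1}{n_c} +
#'   \frac{1}{n_j}\right)}}}
#' on the mid-ranks of the pooled data, with a two-sided p from the
#' standard normal and a Bonferroni-style adjustment over the number of
#' comparisons (\code{p_adj = min(1, p * m)}). Raw p values are always
#' reported alongside.
#'
#' @param values numeric observations.
#' @param groups group label per observation.
#' @param control the control group (default "term").
#' @return data.frame with one row per comparison: \code{comparison},
#'   \code{z}, \code{p}, \code{p_adj}.
#' @export
dunnPosthoc <- function(values, groups, control = "term") {
  groups <- as.character(groups)
  if (!any(groups == control))
    stop("control group '", control, "' is empty")
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  sigma2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  meanRank <- tapply(r, groups, mean)
  nj <- tapply(r, groups, length)
  others <- setdiff(names(meanRank), control)
  m <- length(others)
  z <- vapply(others, function(g) {
    se <- sqrt(sigma2 * (1 / nj[[control]] + 1 / nj[[g]]))
    if (se == 0) return(0)
    (meanRank[[control]] - meanRank[[g]]) / se
  }, numeric(1))
  p <- 2 * pnorm(-abs(z))
  data.frame(comparison = others, z = unname(z), p = unname(p),
             p_adj = pmin(1, unname(p) * m), stringsAsFactors = FALSE,
             row.names = NULL)
}

pStars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "ns")))
}

#' Five-group testing of every gene in a fold-change table
#'
#' Runs the tie-corrected Kruskal-Wallis test across the clinical groups
#' on each gene's per-sample values (log2 fold changes by default; any
#' strictly monotone transform of them, e.g. raw delta-Ct, gives
#' identical results) and Dunn's post-hoc comparisons of every disease
#' group against the term control.
#'
#' @param fc long table with columns \code{gene}, \code{group} and the
#'   value column (see \code{\link{computeFoldChange}}).
#' @param valueColumn which column to test (default \code{log2_fc}).
#' @param control control group for Dunn's comparisons.
#' @param alpha significance level for flagging (default 0.05; a gene is
#'   flagged iff its Kruskal-Wallis p is strictly below it).
#' @return a \linkS4class{GroupTestResult}; the per-gene table carries
#'   the usual star notation (*, **, *** for p < 0.05, 0.01, 0.001).
#' @export
testGeneExpression <- function(fc, valueColumn = "log2_fc",
                               control = "term", alpha = 0.05) {
  stopifnot(valueColumn %in% colnames(fc))
  genes <- sort(unique(fc$gene), method = "radix")
  kwRows <- vector("list", length(genes))
  dunnRows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    sub <- fc[fc$gene == genes[i], ]
    kw <- kruskalWallis(sub[[valueColumn]], sub$group)
    kwRows[[i]] <- data.frame(gene = genes[i], H = kw$H, df = kw$df,
                              p = kw$p, stringsAsFactors = FALSE)
    dn <- dunnPosthoc(sub[[valueColumn]], sub$group, control = control)
    dunnRows[[i]] <- data.frame(gene = genes[i], dn,
                                stringsAsFactors = FALSE)
  }
  kwTab <- do.call(rbind, kwRows)
  kwTab$stars <- pStars(kwTab$p)
  kwTab$significant <- kwTab$p < alpha
  new("GroupTestResult", kw = kwTab, dunn = do.call(rbind, dunnRows),
      alpha = alpha)
}

#' Genes significant at the Kruskal-Wallis level
#'
#' @param results a \linkS4class{GroupTestResult}.
#' @param alpha significance level (strict inequality; default the
#'   level stored in the result).
#' @return character vector of significant gene ids.
#' @export
flagSignificant <- function(results, alpha = NULL) {
  if (is.null(alpha)) alpha <- results@alpha
  results@kw$gene[results@kw$p < alpha]
}
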