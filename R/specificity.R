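## Dual-disease fold-change "diagramming": FC filtering, y/x ratio
## classification into disease-dominance classes, top-3 dominance
## ranking and intersection with the significant gene set.

#' Fold-change filter on the dual-disease scatter
#'
#' A gene is retained iff its expression is modulated by an absolute
#' linear fold change strictly larger than \code{threshold} (i.e.
#' above 114\% or below 86\% of the term-control level by default) in
#' at least one disease: \code{max(|x|, |y|) > log2(threshold)}.
#'
#' @param pairs data.frame with columns \code{gene}, \code{x} (mean
#'   log2 FC in IUGR), \code{y} (mean log2 FC in PE); see
#'   \code{\link{groupLogFC}}.
#' @param threshold linear fold-change cutoff (default 1.14).
#' @return logical vector, one flag per row of \code{pairs}.
#' @export
fcFilter <- function(pairs, threshold = 1.14) {
  pmax(abs(pairs$x), abs(pairs$y)) > log2(threshold)
}

#' Classify genes by disease dominance on the (x, y) scatter
#'
#' For every gene retained by the fold-change filter the rule bands are
#' evaluated in fixed order with error threshold \code{epsilon} (log2
#' units), so each point receives exactly one class:
#' \enumerate{
#'   \item \code{|y| <= eps} and \code{|x| > eps}: \code{IUGR_dominant}
#'     (the point hugs the x axis, the ratio r = y/x is near 0);
#'   \item \code{|x| <= eps} and \code{|y| > eps}: \code{PE_dominant}
#'     (r diverges);
#'   \item \code{|y - x| <= eps}: \code{equal} (on the y = x diagonal,
#'     r near 1);
#'   \item \code{|y + x| <= eps}: \code{equal_reversed} (y = -x,
#'     r near -1);
#'   \item otherwise \code{mixed}.
#' }
#' Genes failing the filter are \code{unclassified}. The rank variable
#' \code{r = y/x} is always reported (signed infinity when x = 0).
#'
#' @param pairs data.frame with columns \code{gene}, \code{x}, \code{y}.
#' @param threshold linear FC cutoff handed to \code{\link{fcFilter}}.
#' @param epsilon error threshold on the log2 scale (default 0.2,
#'   consistent with log2(1.14) = 0.189).
#' @return data.frame: \code{gene}, \code{x}, \code{y}, \code{r},
#'   \code{retained}, \code{class}.
#' @examples
#' classifySpecificity(data.frame(gene = c("a", "b", "c"),
#'                                x = c(0.5, 0.4, 0.6),
#'                                y = c(0.5, -0.4, 0.0)))
#' @export
classifySpecificity <- function(pairs, threshold = 1.14, epsilon = 0.2) {
  retained <- fcFilter(pairs, threshold = threshold)
  x <- pairs$x; y <- pairs$y
  r <- ifelse(x == 0, sign(y) * Inf, y / x)
  cls <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    cls[i] <- if (!retained[i]) "unclassified"
    else if (abs(y[i]) <= epsilon && abs(x[i]) > epsilon) "IUGR_dominant"
    else if (abs(x[i]) <= epsilon && abs(y[i]) > epsilon) "PE_dominant"
    else if (abs(y[i] - x[i]) <= epsilon) "equal"
    else if (abs(y[i] + x[i]) <= epsilon) "equal_reversed"
    else "mixed"
  }
  data.frame(gene = pairs$gene, x = x, y = y, r = r,
             retained = retained, class = cls, stringsAsFactors = FALSE)
}

#' Top-n genes dominantly influenced by one disease
#'
#' For IUGR: the dominance list ranks the \code{IUGR_dominant} genes by
#' decreasing \code{|x|}, then (should fewer than n exist) \code{mixed}
#' genes with \code{|x| > |y|} by decreasing \code{|x|}; symmetric on
#' \code{|y|} for PE. Ties break by gene id.
#'
#' @param calls classification table from
#'   \code{\link{classifySpecificity}}.
#' @param disease "IUGR" or "PE".
#' @param n list length (default 3). If fewer genes qualify, all are
#'   returned with a warning.
#' @return character vector of gene ids, most dominant first.
#' @export
rankDominant <- function(calls, disease = c("IUGR", "PE"), n = 3L) {
  disease <- match.arg(disease)
  if (disease == "IUGR") {
    primary <- calls[calls$class == "IUGR_dominant", ]
    backup <- calls[calls$class == "mixed" & abs(calls$x) > abs(calls$y), ]
    keyCol <- "x"
  } else {
    primary <- calls[calls$class == "PE_dominant", ]
    backup <- calls[calls$class == "mixed" & abs(calls$y) > abs(calls$x), ]
    keyCol <- "y"
  }
  primary$tier <- rep(1L, nrow(primary))
  backup$tier <- rep(2L, nrow(backup))
  pool <- rbind(primary, backup)
  pool <- pool[order(pool$tier, -abs(pool[[keyCol]]), pool$gene,
                     method = "radix"), ]
  if (nrow(pool) < n) {
    warning("only ", nrow(pool), " genes qualify for the ", disease,
            " dominance list (requested ", n, ")")
    n <- nrow(pool)
  }
  pool$gene[seq_len(n)]
}

#' Intersect the significant and disease-specific gene sets
#'
#' The final targets are the Kruskal-Wallis-significant genes that are
#' additionally either (a) in a top-n dominance list for IUGR or PE, or
#' (b) classed \code{equal} / \code{equal_reversed} (equally affected by
#' both diseases). Each target is annotated with its class and
#' dominance-list membership.
#'
#' @param significant character vector of significant gene ids (see
#'   \code{\link{flagSignificant}}).
#' @param calls classification table from
#'   \code{\link{classifySpecificity}}.
#' @param n dominance-list length (default 3).
#' @return data.frame: \code{gene}, \code{class}, \code{x}, \code{y},
#'   \code{top_iugr}, \code{top_pe}.
#' @export
intersectTargets <- function(significant, calls, n = 3L) {
  topI <- tryCatch(suppressWarnings(rankDominant(calls, "IUGR", n)),
                   error = function(e) character())
  topP <- tryCatch(suppressWarnings(rankDominant(calls, "PE", n)),
                   error = function(e) character())
  eligible <- calls$gene %in% c(topI, topP) |
    calls$class %in% c("equal", "equal_reversed")
  hit <- calls[eligible & calls$gene %in% significant, , drop = FALSE]
  out <- data.frame(gene = hit$gene, class = hit$class,
                    x = hit$x, y = hit$y,
                    top_iugr = hit$gene %in% topI,
                    top_pe = hit$gene %in% topP,
                    stringsAsFactors = FALSE)
  out[order(out$gene, method = "radix"), , drop = FALSE]
}
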