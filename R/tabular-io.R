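## Readers and writers for every on-disk format the pipeline touches.
## All readers validate and reject malformed input instead of coercing;
## all writers are deterministic (stable column order, fixed float
## formatting: full 17-digit precision for matrices so round trips are
## exact, 6 significant digits for derived results tables).

fmtFull <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

fmtResult <- function(x) {
  out <- sprintf("%.6g", x)
  out[is.na(x)] <- "NA"
  out
}

readKeyValueFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  hit <- regexpr("=", lines, fixed = TRUE)
  if (any(hit < 0)) stop("malformed key=value line in ", path)
  keys <- trimws(substr(lines, 1, hit - 1))
  vals <- trimws(substr(lines, hit + 1, nchar(lines)))
  if (anyDuplicated(keys)) stop("duplicate key in ", path)
  setNames(as.list(vals), keys)
}

#' Read the study-metadata table (microarray databank information)
#'
#' Expects a tab-separated file with header columns \code{study_id},
#' \code{accession}, \code{platform}, \code{tissue}, \code{n_control},
#' \code{n_iugr}, \code{n_pe}. A blank or missing count records an absent
#' arm and is stored as 0; negative or non-numeric counts and duplicate
#' study ids are rejected. A transcription of the seven-study
#' meta-analysis table ships with the package
#' (\code{system.file("extdata", "study_metadata.tsv",
#' package = "placentaScreen")}).
#'
#' @param path file path.
#' @return data.frame with one row per study.
#' @export
readStudyMetadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("empty study-metadata file: ", path)
  need <- c("study_id", "accession", "platform", "tissue",
            "n_control", "n_iugr", "n_pe")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("study metadata is missing column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$study_id)) stop("duplicate study id")
  for (cc in c("n_control", "n_iugr", "n_pe")) {
    raw <- trimws(df[[cc]])
    raw[raw == ""] <- "0"
    val <- suppressWarnings(as.integer(raw))
    if (anyNA(val)) stop("malformed count in column ", cc)
    if (any(val < 0)) stop("negative count in column ", cc)
    df[[cc]] <- val
  }
  df[, need]
}

#' Sum the per-study sample counts
#'
#' @param metas data.frame from \code{\link{readStudyMetadata}}.
#' @return named numeric vector with \code{n_total}, \code{n_control},
#'   \code{n_iugr}, \code{n_pe}; \code{n_total} is the sum of the three
#'   arm totals.
#' @examples
#' meta <- readStudyMetadata(system.file("extdata", "study_metadata.tsv",
#'                                       package = "placentaScreen"))
#' sampleAccounting(meta)   # 258 samples in total
#' @export
sampleAccounting <- function(metas) {
  if (nrow(metas) < 1L) stop("at least one study record is required")
  out <- c(n_control = sum(metas$n_control),
           n_iugr = sum(metas$n_iugr),
           n_pe = sum(metas$n_pe))
  c(n_total = unname(sum(out)), out)
}

#' Read / write a tab-separated numeric matrix (genes x samples)
#'
#' The writer stores full double precision so that a write-then-read
#' round trip reproduces the values exactly. The reader rejects
#' duplicate ids and non-numeric cells.
#'
#' @param path file path.
#' @return \code{readExpressionMatrix} returns a numeric matrix with
#'   gene row names and sample column names.
#' @export
readExpressionMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L) stop("matrix file needs an id column plus values")
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate gene ids in ", path)
  if (anyDuplicated(colnames(df)[-1])) stop("duplicate sample ids in ", path)
  m <- suppressWarnings(vapply(df[-1], as.numeric, numeric(nrow(df))))
  m <- matrix(m, nrow = nrow(df),
              dimnames = list(ids, colnames(df)[-1]))
  if (anyNA(m)) stop("non-numeric cell in ", path)
  m
}

#' @rdname readExpressionMatrix
#' @param mat numeric matrix with dimnames.
#' @export
writeExpressionMatrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat),
                   matrix(fmtFull(mat), nrow(mat),
                          dimnames = list(NULL, colnames(mat))),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Ct table and its QC table into a CtExperiment
#'
#' The Ct file is tab-separated with samples in rows: columns
#' \code{sample}, \code{group}, then one column per gene. Rows sharing a
#' sample id are treated as technical replicates and averaged per gene
#' before anything else. The QC file has columns \code{sample},
#' \code{rin}, \code{ratio_260_280}, \code{ratio_260_230}, \code{yield}.
#'
#' @param ctPath path to the Ct table.
#' @param qcPath path to the QC table.
#' @param referenceGenes reference gene ids (must be among the gene
#'   columns).
#' @return a \linkS4class{CtExperiment}.
#' @export
readCtTable <- function(ctPath, qcPath,
                        referenceGenes = c("UBQ", "YWHAZ")) {
  df <- read.delim(ctPath, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% colnames(df)))
    stop("Ct table needs 'sample' and 'group' columns")
  geneCols <- setdiff(colnames(df), c("sample", "group"))
  if (!length(geneCols)) stop("Ct table contains no gene columns")
  for (g in geneCols)
    if (!is.numeric(df[[g]])) stop("non-numeric Ct value in column ", g)
  grp <- tapply(df$group, df$sample, function(x) unique(x))
  if (any(lengths(grp) != 1L))
    stop("conflicting group labels for replicated sample")
  ## average technical replicates per sample
  agg <- stats::aggregate(df[geneCols], by = list(sample = df$sample),
                          FUN = mean)
  agg <- agg[match(unique(df$sample), agg$sample), , drop = FALSE]
  ct <- t(as.matrix(agg[geneCols]))
  colnames(ct) <- agg$sample
  qc <- read.delim(qcPath, stringsAsFactors = FALSE)
  CtExperiment(ct, setNames(unlist(grp)[colnames(ct)], colnames(ct)),
               qc, referenceGenes = referenceGenes)
}

#' @rdname readCtTable
#' @param ct a \linkS4class{CtExperiment}.
#' @param path output path.
#' @export
writeCtTable <- function(ct, path) {
  m <- assay(ct, "ct")
  df <- data.frame(sample = colnames(m),
                   group = unname(sampleGroups(ct)),
                   matrix(fmtFull(t(m)), ncol(m),
                          dimnames = list(NULL, rownames(m))),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a confidence-weighted interaction edge list
#'
#' Tab-separated, three columns: \code{node_a}, \code{node_b},
#' \code{score} (a header is detected and allowed). Scores outside
#' [0, 1], self loops and non-numeric cells are rejected.
#'
#' @param path file path.
#' @param nodes optional node universe to preserve isolated nodes.
#' @return an \linkS4class{InteractionGraph}.
#' @export
readEdgeList <- function(path, nodes = NULL) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  hasHeader <- suppressWarnings(is.na(as.numeric(first[3])))
  df <- read.delim(path, header = hasHeader, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("edge list needs three columns")
  colnames(df)[1:3] <- c("node_a", "node_b", "score")
  score <- suppressWarnings(as.numeric(df$score))
  if (anyNA(score)) stop("non-numeric score in ", path)
  if (any(score < 0 | score > 1)) stop("edge score outside [0, 1]")
  InteractionGraph(data.frame(node_a = as.character(df$node_a),
                              node_b = as.character(df$node_b),
                              score = score), nodes = nodes)
}

#' Write a results table with fixed 6-significant-digit float formatting
#'
#' @param df data.frame.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeResultsTable <- function(df, path) {
  out <- df
  for (cc in colnames(out))
    if (is.double(out[[cc]])) out[[cc]] <- fmtResult(out[[cc]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a dendrogram in newick format
#'
#' Branch lengths are derived from the merge heights (each edge spans the
#' height difference between its child and parent nodes, so leaf-to-root
#' path lengths are ultrametric).
#'
#' @param dend a \linkS4class{Dendrogram}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeNewick <- function(dend, path) {
  phy <- ape::as.phylo(as.hclust.Dendrogram(dend))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write a clustered-matrix export (reordered matrix plus order files)
#'
#' Stands in for the classic clustering-software output triplet: the
#' value matrix reordered by both dendrogram leaf orders, plus one file
#' per axis listing the leaf order.
#'
#' @param export a clustered export from \code{\link{buildHeatmap}}.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the files written.
#' @export
writeClusteredMatrix <- function(export, dir, prefix = "clustered") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fm <- file.path(dir, paste0(prefix, "_matrix.tsv"))
  writeExpressionMatrix(export$matrix, fm)
  fr <- file.path(dir, paste0(prefix, "_gene_order.txt"))
  writeLines(rownames(export$matrix), fr)
  fc <- file.path(dir, paste0(prefix, "_sample_order.txt"))
  writeLines(colnames(export$matrix), fc)
  invisible(c(matrix = fm, gene_order = fr, sample_order = fc))
}

#' Read a two-column annotation-flag table
#'
#' Columns \code{gene} and \code{annotated} (logical or 0/1); the flag
#' encodes the curated "biological significance in placenta" criterion
#' of the candidate selection, which is an expert input, not computed.
#'
#' @param path file path.
#' @return named logical vector gene -> flag.
#' @export
readAnnotationFlags <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "annotated") %in% colnames(df)))
    stop("annotation table needs columns 'gene' and 'annotated'")
  if (anyDuplicated(df$gene)) stop("duplicate gene in annotation table")
  setNames(as.logical(df$annotated), df$gene)
}
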