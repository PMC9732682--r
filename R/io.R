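# Readers and writers for the pipeline's tab-separated interchange formats.
# All tables are TSV with a header row; gene lists are newline-delimited;
# networks are exchanged as edge TSVs and Cytoscape-compatible SIF files.
# Every writer/reader pair round-trips bit-exactly.

# Strict TSV scan: every row must have the header's field count; a ragged
# row is an error naming the file and line.
checkRectangular <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  counts <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(counts != counts[1L])
  if (length(bad))
    stop("malformed TSV ", path, ": row ", bad[1L], " has ", counts[bad[1L]],
         " fields, expected ", counts[1L])
  invisible(TRUE)
}

readTSV <- function(path) {
  checkRectangular(path)
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}

writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write expression matrices with sample metadata
#'
#' The expression TSV has a `gene_id` first column and one column per
#' sample; the metadata TSV has columns sample_id, variety, n_level,
#' w_level, replicate. Numbers are serialized at full precision so the
#' round-trip is bit-exact.
#'
#' @param exprPath,metaPath file paths
#' @return [readExpression()] returns a SummarizedExperiment
#' @export
readExpression <- function(exprPath, metaPath) {
  tab <- readTSV(exprPath)
  if (names(tab)[1L] != "gene_id")
    stop("expression TSV must have a 'gene_id' first column: ", exprPath)
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(mat) <- tab$gene_id
  meta <- readTSV(metaPath)
  need <- c("sample_id", "variety", "n_level", "w_level")
  if (!all(need %in% names(meta)))
    stop("metadata TSV must have columns ", paste(need, collapse = ", "))
  if (!setequal(meta$sample_id, colnames(mat)))
    stop("metadata sample_ids do not match expression columns")
  meta <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
  if (is.null(meta$condition))
    meta$condition <- conditionCode(meta$n_level, meta$w_level)
  if (is.null(meta$replicate)) meta$replicate <- 1L
  rownames(meta) <- meta$sample_id
  SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = mat), colData = S4Vectors::DataFrame(meta))
}

#' @rdname readExpression
#' @param se a SummarizedExperiment
#' @export
writeExpression <- function(se, exprPath, metaPath) {
  mat <- exprMatrix(se)
  df <- data.frame(gene_id = rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(mat))
  writeTSV(df, exprPath)
  writeTSV(as.data.frame(SummarizedExperiment::colData(se)), metaPath)
  invisible(exprPath)
}

#' Read or write a newline-delimited gene list
#' @param path file path
#' @return character vector of identifiers
#' @export
readGeneList <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' @rdname readGeneList
#' @param genes character vector
#' @export
writeGeneList <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Read and write ranked edge lists
#'
#' Edge TSVs have columns regulator, target, weight and are stored in rank
#' order.
#'
#' @param path file path
#' @return a [GRNEdgeList-class]
#' @export
readEdgeList <- function(path) {
  grnEdgeList(readTSV(path))
}

#' @rdname readEdgeList
#' @param edgeList a [GRNEdgeList-class]
#' @export
writeEdgeList <- function(edgeList, path) {
  e <- edges(edgeList)
  e$weight <- format(e$weight, digits = 17, trim = TRUE, scientific = FALSE)
  writeTSV(e, path)
  invisible(path)
}

#' Read a gold-standard TSV (tf, target[, dataset, evidence_type])
#' @param path file path
#' @param assayedTfs optional explicit assayed TF set
#' @return a [GoldStandard-class]
#' @export
readGoldStandard <- function(path, assayedTfs = NULL) {
  tab <- readTSV(path)
  goldStandard(tab, assayedTfs = assayedTfs)
}

#' @rdname readGoldStandard
#' @param gold a [GoldStandard-class]
#' @export
writeGoldStandard <- function(gold, path) {
  writeTSV(validatedEdges(gold), path)
  invisible(path)
}

#' Write a network in SIF format (node TAB interaction TAB node)
#' @param edgeDf data.frame with regulator and target columns
#' @param path file path
#' @param interaction interaction label (default "regulates")
#' @export
writeSIF <- function(edgeDf, path, interaction = "regulates") {
  writeLines(paste(edgeDf$regulator, interaction, edgeDf$target, sep = "\t"),
             path)
  invisible(path)
}

#' Read a flat annotation file (term TAB gene) into a term -> genes map
#' @param path file path
#' @return named list of gene sets
#' @export
readAnnotation <- function(path) {
  tab <- readTSV(path)
  if (!all(c("term", "gene") %in% names(tab)))
    stop("annotation TSV must have columns term and gene: ", path)
  lapply(split(tab$gene, tab$term), unique)
}
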