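#' Prioritize TFs by overlap significance with a trait-correlated gene set
#'
#' For each regulator in the pruned network, its target set is overlapped
#' with the trait-correlated gene set inside an explicit universe and scored
#' with the analytic hypergeometric z and upper-tail p from
#' [overlapZScore()]. TFs passing the gate (default z >= 10 and p <= 0.001)
#' are ranked by decreasing z, ties broken by TF identifier. The count of
#' secondary TFs (overlapping targets that are themselves TFs) is reported
#' per record.
#'
#' @param prune a [PruneResult-class]
#' @param traitGeneSet trait-correlated genes (subset of `universe`)
#' @param universe background gene set (targets outside it are dropped with
#'   a warning)
#' @param tfs full TF list used to count secondary TFs; defaults to the
#'   pruned network's regulators
#' @param zMin,pMax gate thresholds (set zMin = -Inf, pMax = 1 to keep all)
#' @return data.frame (tf, nPrunedTargets, overlapCount, tf2Count, z, p,
#'   rank) with attribute `overlapGenes`, a named list of the overlapping
#'   genes per retained TF
#' @export
prioritizeTFs <- function(prune, traitGeneSet, universe, tfs = NULL,
                          zMin = 10, pMax = 0.001) {
  e <- edges(prune)
  empty <- data.frame(tf = character(0), nPrunedTargets = integer(0),
                      overlapCount = integer(0), tf2Count = integer(0),
                      z = numeric(0), p = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(e)) {
    warning("empty pruned network: nothing to prioritize")
    attr(empty, "overlapGenes") <- list()
    return(empty)
  }
  traitGeneSet <- unique(traitGeneSet)
  if (!all(traitGeneSet %in% universe))
    stop("traitGeneSet must be a subset of the universe")
  if (is.null(tfs)) tfs <- unique(e$regulator)
  dropped <- setdiff(unique(e$target), universe)
  if (length(dropped))
    warning(length(dropped), " pruned target(s) outside the universe dropped")
  targetsByTf <- split(e$target, e$regulator)
  rows <- lapply(names(targetsByTf), function(tf) {
    tg <- intersect(unique(targetsByTf[[tf]]), universe)
    if (!length(tg)) return(NULL)
    ov <- overlapZScore(tg, traitGeneSet, universe, method = "analytic")
    og <- intersect(tg, traitGeneSet)
    data.frame(tf = tf, nPrunedTargets = length(tg),
               overlapCount = length(og),
               tf2Count = countTF2(og, tfs),
               z = ov$z, p = ov$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  overlapGenes <- lapply(names(targetsByTf), function(tf)
    sort(intersect(intersect(unique(targetsByTf[[tf]]), universe),
                   traitGeneSet)))
  names(overlapGenes) <- names(targetsByTf)
  if (is.null(out)) {
    attr(empty, "overlapGenes") <- list()
    return(empty)
  }
  keep <- out$z >= zMin & out$p <= pMax
  out <- out[keep, , drop = FALSE]
  out <- out[order(-out$z, out$tf), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "overlapGenes") <- overlapGenes[out$tf]
  out
}

#' Count secondary TFs among overlapping target genes
#'
#' @param overlapGenes genes in a TF's target/trait overlap
#' @param tfs the TF list
#' @return number of overlap genes that are themselves TFs
#' @export
countTF2 <- function(overlapGenes, tfs) length(intersect(overlapGenes, tfs))

#' Local GO-style term enrichment with BH correction
#'
#' Hypergeometric upper-tail enrichment of each annotation term in a gene
#' set against a universe, with Benjamini-Hochberg adjustment across all
#' tested terms. The annotation is a local flat map (term -> genes), taken
#' as already propagated; genes outside the universe are dropped with a
#' warning.
#'
#' @param geneSet genes of interest
#' @param annotation named list term -> gene set, or data.frame (term, gene)
#' @param universe background gene set
#' @param alpha FDR threshold for reported terms (default 0.05)
#' @return data.frame (term, annotatedInSet, annotatedInUniverse, p, fdr)
#'   sorted by fdr then term, restricted to fdr <= alpha
#' @export
goEnrichment <- function(geneSet, annotation, universe, alpha = 0.05) {
  if (is.data.frame(annotation)) {
    if (!all(c("term", "gene") %in% names(annotation)))
      stop("annotation data.frame must have columns term and gene")
    annotation <- split(annotation$gene, annotation$term)
  }
  if (!length(annotation)) stop("annotation must be nonempty")
  annotation <- lapply(annotation, unique)
  universe <- unique(universe)
  geneSet <- intersect(unique(geneSet), universe)
  pruned <- lapply(annotation, intersect, universe)
  nd <- sum(lengths(annotation)) - sum(lengths(pruned))
  if (nd > 0)
    warning(nd, " annotation gene(s) outside the universe dropped")
  N <- length(universe); n <- length(geneSet)
  res <- data.frame(
    term = names(pruned),
    annotatedInSet = vapply(pruned, function(g)
      length(intersect(g, geneSet)), 0L),
    annotatedInUniverse = lengths(pruned),
    row.names = NULL, stringsAsFactors = FALSE)
  res$p <- stats::phyper(res$annotatedInSet - 1, res$annotatedInUniverse,
                         N - res$annotatedInUniverse, n, lower.tail = FALSE)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res <- res[res$fdr <= alpha, , drop = FALSE]
  res <- res[order(res$fdr, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract the term-filtered subnetwork of prioritized TFs
#'
#' Keeps the targets annotated to any term of interest, the prioritized TFs
#' with at least one pruned edge into them, and the TF-to-TF edges among the
#' kept nodes. Nodes are annotated with their matched terms. Output ordering
#' is deterministic (regulator, then target).
#'
#' @param prune a [PruneResult-class]
#' @param prioritized output of [prioritizeTFs()]
#' @param termGeneMap named list term -> gene set
#' @param termsOfInterest terms to keep (must exist in `termGeneMap`)
#' @return list(edges, nodes) where nodes has columns node, type
#'   ("tf"/"target") and terms (";"-collapsed)
#' @export
extractSubnetwork <- function(prune, prioritized, termGeneMap,
                              termsOfInterest) {
  if (!all(termsOfInterest %in% names(termGeneMap)))
    stop("unknown term(s): ",
         paste(setdiff(termsOfInterest, names(termGeneMap)), collapse = ", "))
  e <- edges(prune)
  e <- e[e$regulator %in% prioritized$tf, , drop = FALSE]
  annotated <- unique(unlist(termGeneMap[termsOfInterest]))
  keepE <- e[e$target %in% annotated, , drop = FALSE]
  keptTfs <- sort(unique(keepE$regulator))
  keptTargets <- sort(unique(keepE$target))
  tfEdges <- e[e$regulator %in% keptTfs &
                 e$target %in% setdiff(keptTfs, keptTargets), , drop = FALSE]
  out <- rbind(keepE, tfEdges)
  out <- out[order(out$regulator, out$target), , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) {
    warning("no node survives the term filter; empty subnetwork")
    return(list(edges = out,
                nodes = data.frame(node = character(0), type = character(0),
                                   terms = character(0),
                                   stringsAsFactors = FALSE)))
  }
  nodes <- sort(unique(c(out$regulator, out$target)))
  termOf <- vapply(nodes, function(g) {
    hit <- termsOfInterest[vapply(termsOfInterest, function(tm)
      g %in% termGeneMap[[tm]], TRUE)]
    paste(hit, collapse = ";")
  }, "")
  nodeTab <- data.frame(
    node = nodes,
    type = ifelse(nodes %in% keptTfs, "tf", "target"),
    terms = termOf, row.names = NULL, stringsAsFactors = FALSE)
  list(edges = out, nodes = nodeTab)
}
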