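#' Average replicate samples within each variety x condition cell
#'
#' Collapses the expression matrix to one column per variety x condition
#' (e.g. 19 varieties x 4 treatments = 76 columns), each the arithmetic mean
#' of that cell's replicate columns, matching the averaged phenotype table
#' used for module-trait correlation.
#'
#' @param se a SummarizedExperiment with colData columns variety, n_level,
#'   w_level, replicate
#' @return a SummarizedExperiment with one column per cell and colData
#'   (sample_id, variety, n_level, w_level, condition)
#' @export
averageReplicates <- function(se) {
  mat <- exprMatrix(se)
  cd <- sampleMetadata(se)
  cond <- conditionCode(cd$n_level, cd$w_level)
  key <- paste(cd$variety, cond, sep = "|")
  cells <- unique(key)
  out <- vapply(cells, function(k)
    rowMeans(mat[, key == k, drop = FALSE]), numeric(nrow(mat)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(mat))  # single gene
  rownames(out) <- rownames(mat)
  parts <- strsplit(cells, "|", fixed = TRUE)
  variety <- vapply(parts, `[`, "", 1L)
  condition <- vapply(parts, `[`, "", 2L)
  ids <- paste(variety, condition, sep = "_")
  colnames(out) <- ids
  first <- match(cells, key)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = out),
    colData = S4Vectors::DataFrame(
      sample_id = ids, variety = variety,
      n_level = cd$n_level[first], w_level = cd$w_level[first],
      condition = condition, row.names = ids))
}

#' Choose a soft-thresholding power by scale-free topology fit
#'
#' For each candidate power beta the weighted connectivity
#' k_i = sum_j |cor(x_i, x_j)|^beta is computed, binned, and
#' log10(frequency) regressed on log10(mean k per bin). The signed R^2 is
#' the fit R^2 with the sign of minus the slope, so that only decreasing
#' (scale-free-like) degree distributions score positively. The smallest
#' power reaching `r2Target` is returned; if none does, the best-fitting
#' power is returned with a warning.
#'
#' @param se expression (SummarizedExperiment or genes x samples matrix)
#' @param candidatePowers positive integers to scan
#' @param r2Target signed R^2 to reach (default 0.8)
#' @param nBins connectivity histogram bins
#' @return list(power, fitTable with columns power, signedR2, slope, meanK)
#' @export
pickSoftPower <- function(se, candidatePowers = 1:12, r2Target = 0.8,
                          nBins = 10) {
  mat <- exprMatrix(se)
  if (!length(candidatePowers) || any(candidatePowers < 1))
    stop("candidatePowers must be nonempty positive integers")
  ac <- abs(stats::cor(t(mat)))
  fit <- lapply(candidatePowers, function(beta) {
    k <- colSums(ac^beta) - 1
    scaleFreeFit(k, nBins)
  })
  tab <- data.frame(power = candidatePowers,
                    signedR2 = vapply(fit, `[[`, 0, "signedR2"),
                    slope = vapply(fit, `[[`, 0, "slope"),
                    meanK = vapply(fit, `[[`, 0, "meanK"))
  hit <- which(tab$signedR2 >= r2Target)
  if (length(hit)) {
    power <- tab$power[hit[1L]]
  } else {
    power <- tab$power[which.max(tab$signedR2)]
    warning("no candidate power reached signed R^2 ", r2Target,
            "; returning best fit (power ", power, ", R^2 ",
            round(max(tab$signedR2), 3), ")")
  }
  list(power = power, fitTable = tab)
}

# Scale-free fit of a connectivity vector: equal-width bins over k, then
# log-frequency regressed on log mean-k. Degenerate binning (under 3 usable
# bins) is an error.
scaleFreeFit <- function(k, nBins = 10) {
  br <- unique(seq(min(k), max(k), length.out = nBins + 1))
  if (length(br) < 4L)
    stop("scale-free fit failed: fewer than 3 usable connectivity bins")
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  meank <- tapply(k, bin, mean)
  use <- !is.na(freq) & freq > 0 & meank > 0
  if (sum(use) < 3L)
    stop("scale-free fit failed: fewer than 3 usable connectivity bins")
  x <- log10(meank[use]); y <- log10(freq[use])
  fit <- stats::lm(y ~ x)
  # R^2 computed directly (summary.lm warns on near-perfect fits)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot == 0) 0 else 1 - sum(stats::resid(fit)^2) / ssTot
  slope <- stats::coef(fit)[[2L]]
  list(signedR2 = -sign(slope) * r2, slope = slope, meanK = mean(k))
}

#' Soft-thresholded (unsigned) adjacency matrix
#'
#' a_ij = |cor(x_i, x_j)|^power with unit diagonal; the unsigned weighted
#' co-expression network convention.
#'
#' @param se expression (SummarizedExperiment or genes x samples matrix)
#' @param power soft-thresholding power (>= 1)
#' @return symmetric genes x genes matrix with entries in [0, 1]
#' @export
adjacencyMatrix <- function(se, power) {
  if (power < 1) stop("power must be >= 1")
  mat <- exprMatrix(se)
  s <- apply(mat, 1L, stats::sd)
  if (any(s == 0))
    stop("zero-variance gene(s): ",
         paste(head(rownames(mat)[s == 0], 5L), collapse = ", "))
  a <- abs(stats::cor(t(mat)))^power
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)
#' with k_i = sum_{u != i} a_iu; TOM_ii = 1. Shared-neighbour smoothing of
#' the adjacency, used as the clustering similarity.
#'
#' @param adj symmetric adjacency with unit diagonal, entries in [0, 1]
#' @return symmetric genes x genes TOM matrix in [0, 1]
#' @export
tomSimilarity <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-10))
    stop("adjacency must be symmetric")
  if (any(adj < 0 | adj > 1 + 1e-12)) stop("adjacency entries must lie in [0, 1]")
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a                      # sum_u a_iu a_uj over u != i, j
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect co-expression modules by average-linkage clustering of 1 - TOM
#'
#' Genes are clustered on the topological-overlap dissimilarity with
#' average linkage; the tree is cut at a static dissimilarity height
#' (default 0.95, a deterministic simplification of dynamic tree cut), and
#' clusters below `minModuleSize` are assigned to "grey". Labels are
#' "module_1", "module_2", ... in decreasing size order.
#'
#' @param tom TOM similarity matrix
#' @param minModuleSize smallest retained module (default 30)
#' @param cutHeight absolute cut height in (0, 1), default 0.95
#' @return a [ModuleSet-class] with empty eigengenes (fill with
#'   [moduleEigengenes()])
#' @export
detectModules <- function(tom, minModuleSize = 30, cutHeight = 0.95) {
  diss <- 1 - tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  if (cutHeight <= 0 || cutHeight >= 1)
    stop("cutHeight must lie strictly between 0 and 1")
  cl <- stats::cutree(hc, h = cutHeight)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= minModuleSize]
  labels <- rep("grey", length(cl))
  names(labels) <- rownames(tom)
  if (!length(keep)) {
    warning("all genes assigned to grey (no cluster reached minModuleSize)")
  } else {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(ord))
      labels[cl == as.integer(ord[i])] <- paste0("module_", i)
  }
  methods::new("ModuleSet", labels = labels,
               eigengenes = matrix(0, 0, 0), mergeLog = emptyMergeLog())
}

emptyMergeLog <- function()
  data.frame(absorbed = character(0), surviving = character(0),
             dissimilarity = numeric(0), stringsAsFactors = FALSE)

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' gene-standardized expression (each gene centered and scaled to unit
#' variance), itself rescaled to unit variance over samples. The sign is
#' fixed so the mean correlation between the eigengene and the module's
#' genes is non-negative; an exact tie is broken toward the first gene's
#' sign.
#'
#' @param se expression (SummarizedExperiment or genes x samples matrix)
#' @param labels named gene -> module map ("grey" skipped)
#' @return samples x modules matrix
#' @export
moduleEigengenes <- function(se, labels) {
  mat <- exprMatrix(se)
  mods <- setdiff(unique(labels), "grey")
  mods <- mods[order(mods)]
  if (!length(mods)) stop("no non-grey modules to summarize")
  me <- matrix(0, ncol(mat), length(mods),
               dimnames = list(colnames(mat), mods))
  for (m in mods) {
    genes <- names(labels)[labels == m]
    if (length(genes) < 2L)
      stop("module ", m, " has fewer than 2 genes")
    x <- standardizeGenes(mat[genes, , drop = FALSE])
    sv <- svd(x, nu = 0L, nv = 1L)
    v <- sv$v[, 1L]
    v <- v / stats::sd(v)
    cors <- as.vector(stats::cor(t(x), v))
    mc <- mean(cors)
    # exact ties (balanced anti-correlated halves) break toward gene 1
    if (mc < -1e-10 || (abs(mc) <= 1e-10 && cors[1L] < 0)) v <- -v
    me[, m] <- v
  }
  me
}

#' Merge modules with correlated eigengenes
#'
#' While any pair of module eigengenes has dissimilarity
#' 1 - cor(ME_a, ME_b) below `meDissThres`, the closest pair is merged (the
#' smaller module is absorbed into the larger; ties by label order) and
#' eigengenes are recomputed. Every merge is recorded. The default threshold
#' 0.5 combines modules whose eigengenes correlate above 0.5.
#'
#' @param se expression used to recompute eigengenes
#' @param moduleSet a [ModuleSet-class] (eigengenes may be empty)
#' @param meDissThres eigengene dissimilarity below which modules merge
#' @return a [ModuleSet-class] with merged labels, final eigengenes and the
#'   merge log
#' @export
mergeModules <- function(se, moduleSet, meDissThres = 0.5) {
  labels <- moduleLabels(moduleSet)
  if (!length(setdiff(unique(labels), "grey")))
    stop("mergeModules requires at least one non-grey module")
  log <- emptyMergeLog()
  repeat {
    mods <- setdiff(unique(labels), "grey")
    me <- moduleEigengenes(se, labels)
    if (length(mods) < 2L) break
    cm <- stats::cor(me)
    diss <- 1 - cm
    diag(diss) <- Inf
    if (min(diss) >= meDissThres) break
    idx <- which(diss == min(diss), arr.ind = TRUE)[1L, ]
    a <- colnames(me)[idx[1L]]; b <- colnames(me)[idx[2L]]
    na <- sum(labels == a); nb <- sum(labels == b)
    if (na > nb || (na == nb && a < b)) {
      surviving <- a; absorbed <- b
    } else {
      surviving <- b; absorbed <- a
    }
    labels[labels == absorbed] <- surviving
    log <- rbind(log, data.frame(absorbed = absorbed, surviving = surviving,
                                 dissimilarity = min(diss),
                                 stringsAsFactors = FALSE))
  }
  methods::new("ModuleSet", labels = labels,
               eigengenes = moduleEigengenes(se, labels), mergeLog = log)
}

#' Module-trait Pearson correlation with Student p-values
#'
#' Correlates each module eigengene with each trait over samples; two-sided
#' p-values use the Student approximation t = r sqrt(n-2) / sqrt(1-r^2)
#' with n - 2 degrees of freedom. No multiplicity correction is applied at
#' this stage.
#'
#' @param me samples x modules eigengene matrix
#' @param traits samples x traits matrix, same sample order
#' @return a [CorrelationStats-class] with the module-trait slots filled
#' @export
moduleTraitCorrelation <- function(me, traits) {
  traits <- as.matrix(traits)
  n <- nrow(me)
  if (n != nrow(traits)) stop("me and traits must share the sample ordering")
  if (n < 3L) stop("need at least 3 samples for correlation p-values")
  r <- stats::cor(me, traits)
  p <- corPvalueStudent(r, n)
  methods::new("CorrelationStats", moduleTraitCor = r, moduleTraitP = p,
               gs = matrix(0, 0, 0), mm = matrix(0, 0, 0))
}

# Two-sided p for a Pearson correlation under the t approximation.
corPvalueStudent <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
  p[abs(r) == 1] <- 0
  array(p, dim = dim(r), dimnames = dimnames(r))
}

#' Per-gene trait and module correlations (GS and MM)
#'
#' Gene significance gs[g, t] is the signed Pearson correlation between gene
#' g's expression and trait t; module membership mm[g, m] is the signed
#' correlation between the gene and module m's eigengene. Constant genes or
#' traits yield NA (flagged by warning) and are excluded from downstream
#' averages.
#'
#' @param se expression (SummarizedExperiment or genes x samples matrix)
#' @param me samples x modules eigengene matrix
#' @param traits samples x traits matrix
#' @return a [CorrelationStats-class] with gs and mm filled
#' @export
geneTraitStats <- function(se, me, traits) {
  mat <- exprMatrix(se)
  traits <- as.matrix(traits)
  if (ncol(mat) != nrow(traits) || ncol(mat) != nrow(me))
    stop("samples must be aligned across expression, eigengenes and traits")
  sg <- apply(mat, 1L, stats::sd)
  st <- apply(traits, 2L, stats::sd)
  if (any(sg == 0) || any(st == 0))
    warning("constant gene(s) or trait(s) flagged as NA: ",
            paste(c(rownames(mat)[sg == 0], colnames(traits)[st == 0]),
                  collapse = ", "))
  gs <- suppressWarnings(stats::cor(t(mat), traits))
  mm <- suppressWarnings(stats::cor(t(mat), me))
  methods::new("CorrelationStats",
               moduleTraitCor = matrix(0, 0, 0), moduleTraitP = matrix(0, 0, 0),
               gs = gs, mm = mm)
}

#' Select hub genes of a module by above-average |GS| and |MM|
#'
#' Within the module, the cut-offs are the module means of |GS| for the
#' trait and |MM| for the module's own eigengene; genes at or above both
#' means (inclusive) are returned. NA statistics are excluded from the
#' means and never pass the filter.
#'
#' @param moduleLabel which module to filter
#' @param labels named gene -> module map
#' @param stats a [CorrelationStats-class] with gs and mm filled
#' @param trait trait column name in gs
#' @return character vector of hub genes (a subset of the module)
#' @export
filterHubGenes <- function(moduleLabel, labels, stats, trait) {
  genes <- names(labels)[labels == moduleLabel]
  if (!length(genes)) stop("module ", moduleLabel, " is empty")
  gs <- abs(stats@gs[genes, trait])
  mm <- abs(stats@mm[genes, moduleLabel])
  gsBar <- mean(gs, na.rm = TRUE)
  mmBar <- mean(mm, na.rm = TRUE)
  genes[!is.na(gs) & !is.na(mm) & gs >= gsBar & mm >= mmBar]
}
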