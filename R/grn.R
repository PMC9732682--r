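#' Infer a TF-to-target regulatory network by per-target random forests
#'
#' For every target gene, an ensemble of regression trees predicts its
#' (standardized) expression from the standardized expression of the
#' candidate regulators, excluding the target itself when it is a TF. The
#' weight of edge f -> t is regulator f's total variance-reduction
#' (impurity) importance divided by the number of trees. All weights are
#' assembled into one globally ranked list sorted by decreasing weight, ties
#' broken by (regulator, target) lexicographic order so the ranking is total
#' and precision/recall downstream is reproducible. With `nTfs` regulators
#' and `nTargets` candidate targets the list has
#' `nTfs * nTargets - |TFs intersect targets|` edges.
#'
#' @param se expression (SummarizedExperiment or genes x samples matrix)
#' @param tfs candidate regulators (rows of the expression matrix; >= 2)
#' @param targets candidate targets (rows of the expression matrix)
#' @param nTrees trees per target ensemble (default 1000)
#' @param mtry regulators tried per split: "sqrt" (default, the random
#'   forest convention), "all", or a fixed integer
#' @param seed master seed; per-target seeds derive from it, so results are
#'   bitwise reproducible
#' @return a [GRNEdgeList-class]
#' @export
inferGRN <- function(se, tfs, targets, nTrees = 1000, mtry = "sqrt",
                     seed = 1) {
  mat <- exprMatrix(se)
  tfs <- unique(as.character(tfs)); targets <- unique(as.character(targets))
  if (!all(tfs %in% rownames(mat)))
    stop("all TFs must be rows of the expression matrix")
  if (!all(targets %in% rownames(mat)))
    stop("all targets must be rows of the expression matrix")
  if (length(tfs) < 2L)
    stop("at least 2 TFs are required (no split candidates otherwise)")
  sds <- apply(mat[union(tfs, targets), , drop = FALSE], 1L, stats::sd)
  dead <- names(sds)[sds == 0]
  if (length(intersect(dead, tfs)))
    stop("zero-variance TF(s): ", paste(intersect(dead, tfs), collapse = ", "))
  if (length(intersect(dead, targets))) {
    warning("excluding zero-variance target(s): ",
            paste(intersect(dead, targets), collapse = ", "))
    targets <- setdiff(targets, dead)
  }
  x <- standardizeGenes(mat[union(tfs, targets), , drop = FALSE])
  xt <- t(x[tfs, , drop = FALSE])        # samples x TFs

  res <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    tg <- targets[i]
    regs <- setdiff(tfs, tg)
    p <- length(regs)
    m <- switch(as.character(mtry),
                sqrt = max(1L, floor(sqrt(p))),
                all = p,
                {mi <- suppressWarnings(as.integer(mtry))
                 if (is.na(mi) || mi < 1L) stop("invalid mtry: ", mtry)
                 min(mi, p)})
    fit <- ranger::ranger(
      x = xt[, regs, drop = FALSE], y = x[tg, ],
      num.trees = nTrees, mtry = m, importance = "impurity",
      num.threads = 1L, seed = deriveSeed(seed, tg), verbose = FALSE)
    w <- fit$variable.importance / nTrees
    res[[i]] <- data.frame(regulator = regs, target = tg,
                           weight = pmax(as.numeric(w[regs]), 0),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[order(-out$weight, out$regulator, out$target), , drop = FALSE]
  rownames(out) <- NULL
  methods::new("GRNEdgeList", edges = out)
}

#' Construct a ranked edge list from a data.frame
#'
#' Validates, removes self-edges if requested, and applies the canonical
#' ordering (decreasing weight, ties by regulator then target).
#'
#' @param df data.frame with columns regulator, target, weight
#' @param dropSelf drop rows with regulator == target (default FALSE: they
#'   are an error)
#' @return a [GRNEdgeList-class]
#' @export
grnEdgeList <- function(df, dropSelf = FALSE) {
  need <- c("regulator", "target", "weight")
  if (!all(need %in% names(df)))
    stop("edge table must have columns ", paste(need, collapse = ", "))
  if (dropSelf) df <- df[df$regulator != df$target, , drop = FALSE]
  df <- df[order(-df$weight, df$regulator, df$target),
           c("regulator", "target", "weight"), drop = FALSE]
  rownames(df) <- NULL
  methods::new("GRNEdgeList", edges = df)
}
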