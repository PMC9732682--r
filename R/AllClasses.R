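#' @import methods
#' @importFrom stats cor cutree dist hclust p.adjust phyper pt rnorm runif sd setNames var
#' @importFrom utils head read.delim write.table
NULL

#' Simulation configuration for the synthetic field-trial generator
#'
#' Describes a multi-variety 2x2 nitrogen-by-water factorial design with
#' planted co-expression modules, module-driven phenotypes and a planted
#' TF-to-target edge structure. Build instances with [simulationConfig()],
#' which supplies field-realistic defaults and validates every field.
#'
#' @slot nVarieties number of varieties (default 19, a typical diversity panel)
#' @slot conditions data.frame with columns `n_level`, `w_level` (low/high)
#' @slot nReplicates replicate samples per variety x condition cell
#' @slot nGenes,nTfs,nModules problem dimensions
#' @slot moduleSizes genes per planted module; the remainder are unassigned
#'   background ("grey") genes
#' @slot latentMeans,latentEffects per-module baseline and (N, W, N:W) effect
#'   sizes on the module latent activity, in expression units
#' @slot varietySd sd of per-variety x module random effects
#' @slot loadingRange gene loadings are drawn uniformly from this range
#' @slot tfOutDegree planted targets per TF
#' @slot edgeFunction "linear" or "quadratic" TF-to-target transfer
#' @slot edgeCoef scale of the planted edge effect
#' @slot targetPool "own" restricts planted targets to the TF's module plus
#'   background genes (keeps the zero-noise affine identity exact), "module"
#'   to the TF's module only; "any" allows any gene
#' @slot noiseSd latent and gene-level Gaussian noise sd
#' @slot backgroundSd sd of unassigned background genes
#' @slot phenotypeLoadings module x trait coefficient matrix
#' @slot phenotypeNoiseSd trait-level noise sd
#' @slot goldFpRate,goldFnRate default error rates for the synthetic gold
#'   standard
#' @slot seed master seed; all component streams derive from it
#' @export
setClass("SimulationConfig", representation(
  nVarieties = "integer", conditions = "data.frame", nReplicates = "integer",
  nGenes = "integer", nTfs = "integer", nModules = "integer",
  moduleSizes = "integer", latentMeans = "numeric", latentEffects = "matrix",
  varietySd = "numeric", loadingRange = "numeric", tfOutDegree = "integer",
  edgeFunction = "character", edgeCoef = "numeric", targetPool = "character",
  noiseSd = "numeric", backgroundSd = "numeric",
  phenotypeLoadings = "matrix", phenotypeNoiseSd = "numeric",
  goldFpRate = "numeric", goldFnRate = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  chk <- function(cond, m) if (!cond) msg <<- c(msg, m)
  chk(object@nVarieties >= 1L, "nVarieties must be >= 1")
  chk(all(c("n_level", "w_level") %in% names(object@conditions)),
      "conditions must have columns n_level and w_level")
  chk(all(unlist(object@conditions[c("n_level", "w_level")]) %in%
            c("low", "high")), "condition levels must be 'low' or 'high'")
  chk(object@nReplicates >= 1L, "nReplicates must be >= 1")
  chk(sum(object@moduleSizes) <= object@nGenes,
      "sum(moduleSizes) must not exceed nGenes")
  chk(length(object@moduleSizes) == object@nModules,
      "moduleSizes must have one entry per module")
  chk(object@nTfs <= sum(object@moduleSizes),
      "nTfs must not exceed the number of module member genes")
  chk(object@nTfs <= object@nGenes, "nTfs must not exceed nGenes")
  chk(object@noiseSd >= 0, "noiseSd must be >= 0")
  chk(object@backgroundSd >= 0, "backgroundSd must be >= 0")
  chk(object@phenotypeNoiseSd >= 0, "phenotypeNoiseSd must be >= 0")
  chk(object@goldFpRate >= 0 && object@goldFpRate <= 1,
      "goldFpRate must lie in [0, 1]")
  chk(object@goldFnRate >= 0 && object@goldFnRate <= 1,
      "goldFnRate must lie in [0, 1]")
  chk(object@edgeFunction %in% c("linear", "quadratic"),
      "edgeFunction must be 'linear' or 'quadratic'")
  chk(object@targetPool %in% c("own", "module", "any"),
      "targetPool must be 'own', 'module' or 'any'")
  chk(nrow(object@latentEffects) == object@nModules &&
        ncol(object@latentEffects) == 3L,
      "latentEffects must be an nModules x 3 matrix (N, W, N:W)")
  chk(nrow(object@phenotypeLoadings) == object@nModules,
      "phenotypeLoadings must have one row per module")
  if (length(msg)) msg else TRUE
})

#' Synthetic dataset bundling expression, phenotypes and planted truth
#'
#' @slot expression a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"expr"` (genes x samples) and colData columns sample_id, variety,
#'   n_level, w_level, condition, replicate
#' @slot phenotypes data.frame, one row per variety x condition
#' @slot trueModuleLabels named character vector, gene -> planted module
#'   ("grey" for background genes)
#' @slot trueEdges data.frame (tf, target) of planted regulatory edges
#' @slot trueDeClasses named list, gene -> subset of c("N","W","N:W")
#' @slot tfList genes designated as transcription factors
#' @slot config the generating [SimulationConfig-class]
#' @export
setClass("SyntheticDataset", representation(
  expression = "ANY", phenotypes = "data.frame",
  trueModuleLabels = "character", trueEdges = "data.frame",
  trueDeClasses = "list", tfList = "character", config = "SimulationConfig"))

setValidity("SyntheticDataset", function(object) {
  genes <- rownames(SummarizedExperiment::assay(object@expression))
  msg <- character()
  if (!all(object@tfList %in% genes))
    msg <- c(msg, "every TF must be a row of the expression matrix")
  if (nrow(object@trueEdges) &&
      !all(c(object@trueEdges$tf, object@trueEdges$target) %in% genes))
    msg <- c(msg, "planted edges must reference existing genes")
  cd <- SummarizedExperiment::colData(object@expression)
  reps <- table(paste(cd$variety, cd$condition))
  if (length(unique(reps)) > 1L ||
      (length(reps) && reps[[1L]] != object@config@nReplicates))
    msg <- c(msg, "replicate count per variety x condition must equal nReplicates")
  if (length(msg)) msg else TRUE
})

#' Co-expression module assignment with eigengenes
#'
#' @slot labels named character vector gene -> module label; "grey" marks
#'   unassigned genes
#' @slot eigengenes samples x modules matrix of module eigengenes, each
#'   scaled to unit variance
#' @slot mergeLog data.frame (absorbed, surviving, dissimilarity) recording
#'   eigengene-based merges
#' @export
setClass("ModuleSet", representation(
  labels = "character", eigengenes = "matrix", mergeLog = "data.frame"))

setValidity("ModuleSet", function(object) {
  msg <- character()
  if (is.null(names(object@labels)) || anyNA(names(object@labels)))
    msg <- c(msg, "labels must be a named vector (gene -> module)")
  mods <- setdiff(unique(object@labels), "grey")
  if (ncol(object@eigengenes) &&
      !setequal(colnames(object@eigengenes), mods))
    msg <- c(msg, "eigengene columns must match the non-grey module labels")
  if (ncol(object@eigengenes)) {
    v <- apply(object@eigengenes, 2L, stats::var)
    if (any(abs(v - 1) > 1e-6))
      msg <- c(msg, "each eigengene must have unit variance over samples")
  }
  if (length(msg)) msg else TRUE
})

#' Module- and gene-level trait correlation statistics
#'
#' @slot moduleTraitCor,moduleTraitP modules x traits Pearson correlations
#'   and Student-approximation p-values
#' @slot gs genes x traits signed gene-significance correlations
#' @slot mm genes x modules signed module-membership correlations
#' @export
setClass("CorrelationStats", representation(
  moduleTraitCor = "matrix", moduleTraitP = "matrix",
  gs = "matrix", mm = "matrix"))

setValidity("CorrelationStats", function(object) {
  ok <- function(m) !length(m) || all(is.na(m) | (m >= -1 - 1e-12 & m <= 1 + 1e-12))
  msg <- character()
  if (!ok(object@moduleTraitCor) || !ok(object@gs) || !ok(object@mm))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  p <- object@moduleTraitP
  if (length(p) && !all(is.na(p) | (p >= 0 & p <= 1)))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Ranked regulator-to-target edge list
#'
#' Edges are sorted by decreasing weight; ties are broken by (regulator,
#' target) lexicographic order so the ranking is total and reproducible.
#'
#' @slot edges data.frame with columns regulator, target, weight
#' @export
setClass("GRNEdgeList", representation(edges = "data.frame"))

setValidity("GRNEdgeList", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("regulator", "target", "weight") %in% names(e)))
    return("edges must have columns regulator, target, weight")
  if (any(e$regulator == e$target)) msg <- c(msg, "self-edges are not allowed")
  if (any(e$weight < 0)) msg <- c(msg, "weights must be >= 0")
  if (nrow(e) > 1L && is.unsorted(rev(e$weight)))
    msg <- c(msg, "edges must be sorted by decreasing weight")
  if (length(msg)) msg else TRUE
})

#' Gold standard of validated TF-to-target edges
#'
#' @slot validatedEdges data.frame (tf, target, dataset) of validated edges
#' @slot assayedTfs TFs whose targets were assayed
#' @slot assayedUniverse data.frame (tf, target) of testable pairs; when
#'   empty, evaluation defaults to assayedTfs x all targets of the predicted
#'   network
#' @export
setClass("GoldStandard", representation(
  validatedEdges = "data.frame", assayedTfs = "character",
  assayedUniverse = "data.frame"))

setValidity("GoldStandard", function(object) {
  msg <- character()
  if (!length(object@assayedTfs)) msg <- c(msg, "assayedTfs must be nonempty")
  if (!all(c("tf", "target") %in% names(object@validatedEdges)))
    msg <- c(msg, "validatedEdges must have columns tf and target")
  if (nrow(object@assayedUniverse)) {
    ukeys <- edgeKey(object@assayedUniverse$tf, object@assayedUniverse$target)
    vkeys <- edgeKey(object@validatedEdges$tf, object@validatedEdges$target)
    if (!all(vkeys %in% ukeys))
      msg <- c(msg, "validatedEdges must lie inside assayedUniverse")
  }
  if (length(msg)) msg else TRUE
})

#' Precision/recall curve over a ranked edge list
#'
#' @slot points data.frame (rank, weight, tp, precision, recall), one row
#'   per rank of the restricted edge list
#' @slot nValidated number of gold-standard edges in the assayed universe
#' @slot nUniverse size of the assayed universe
#' @export
setClass("PRCurve", representation(
  points = "data.frame", nValidated = "integer", nUniverse = "integer"))

setValidity("PRCurve", function(object) {
  p <- object@points
  msg <- character()
  if (!all(c("rank", "weight", "tp", "precision", "recall") %in% names(p)))
    return("points must have columns rank, weight, tp, precision, recall")
  if (nrow(p)) {
    if (is.unsorted(p$tp)) msg <- c(msg, "tp must be non-decreasing")
    if (is.unsorted(p$recall)) msg <- c(msg, "recall must be non-decreasing")
    if (any(abs(p$precision - p$tp / p$rank) > 1e-12))
      msg <- c(msg, "precision must equal tp / rank")
  }
  if (length(msg)) msg else TRUE
})

#' Result of pruning a network at a weight threshold
#'
#' @slot precisionTarget the precision level that selected the threshold
#'   (NA when the threshold was supplied directly)
#' @slot weightThreshold minimum edge weight retained
#' @slot edges surviving [GRNEdgeList-class]
#' @slot nEdges,nTfs,nTargets counts of surviving edges, distinct regulators
#'   and distinct targets
#' @export
setClass("PruneResult", representation(
  precisionTarget = "numeric", weightThreshold = "numeric",
  edges = "GRNEdgeList", nEdges = "integer", nTfs = "integer",
  nTargets = "integer"))

setValidity("PruneResult", function(object) {
  e <- edges(object@edges)
  msg <- character()
  if (nrow(e) && any(e$weight < object@weightThreshold))
    msg <- c(msg, "every pruned edge must have weight >= weightThreshold")
  if (object@nEdges != nrow(e) ||
      object@nTfs != length(unique(e$regulator)) ||
      object@nTargets != length(unique(e$target)))
    msg <- c(msg, "counts must be consistent with the edge list")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nVarieties, "varieties x",
      nrow(object@conditions), "conditions x", object@nReplicates,
      "replicates;", object@nGenes, "genes (", object@nTfs, "TFs,",
      object@nModules, "modules ), seed", object@seed, "\n")
})

setMethod("show", "SyntheticDataset", function(object) {
  a <- SummarizedExperiment::assay(object@expression)
  cat("SyntheticDataset:", nrow(a), "genes x", ncol(a), "samples;",
      nrow(object@trueEdges), "planted edges;", length(object@tfList),
      "TFs\n")
})

setMethod("show", "ModuleSet", function(object) {
  mods <- setdiff(unique(object@labels), "grey")
  cat("ModuleSet:", length(mods), "modules over", length(object@labels),
      "genes (", sum(object@labels == "grey"), "grey );",
      nrow(object@mergeLog), "merges\n")
})

setMethod("show", "GRNEdgeList", function(object) {
  cat("GRNEdgeList:", nrow(object@edges), "ranked edges,",
      length(unique(object@edges$regulator)), "regulators,",
      length(unique(object@edges$target)), "targets\n")
})

setMethod("show", "GoldStandard", function(object) {
  cat("GoldStandard:", nrow(object@validatedEdges), "validated edges for",
      length(object@assayedTfs), "assayed TFs\n")
})

setMethod("show", "PRCurve", function(object) {
  cat("PRCurve:", nrow(object@points), "ranks,", object@nValidated,
      "validated edges in a universe of", object@nUniverse, "\n")
})

setMethod("show", "PruneResult", function(object) {
  cat("PruneResult:", object@nEdges, "edges (", object@nTfs, "TFs,",
      object@nTargets, "targets ) at weight >=",
      format(object@weightThreshold, digits = 4), "\n")
})
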