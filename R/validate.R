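#' Construct a gold standard of validated edges
#'
#' @param validatedEdges data.frame with columns tf, target and optionally
#'   dataset (per-edge provenance)
#' @param assayedTfs TFs whose targets were assayed; defaults to the TFs
#'   appearing in `validatedEdges`
#' @param assayedUniverse optional data.frame (tf, target) of testable
#'   pairs; when omitted, evaluation uses assayedTfs x all targets of the
#'   predicted network
#' @return a [GoldStandard-class]
#' @export
goldStandard <- function(validatedEdges, assayedTfs = NULL,
                         assayedUniverse = NULL) {
  if (!all(c("tf", "target") %in% names(validatedEdges)))
    stop("validatedEdges must have columns tf and target")
  if (is.null(validatedEdges$dataset)) validatedEdges$dataset <- "default"
  if (is.null(assayedTfs)) assayedTfs <- unique(validatedEdges$tf)
  if (is.null(assayedUniverse))
    assayedUniverse <- data.frame(tf = character(0), target = character(0),
                                  stringsAsFactors = FALSE)
  methods::new("GoldStandard", validatedEdges = validatedEdges,
               assayedTfs = as.character(assayedTfs),
               assayedUniverse = assayedUniverse)
}

# Resolve the assayed universe keys for a prediction/gold pair and return
# the restricted, still-ranked predicted edges plus label bookkeeping.
restrictToUniverse <- function(edgeList, gold) {
  pred <- edges(edgeList)
  if (nrow(gold@assayedUniverse)) {
    ukeys <- edgeKey(gold@assayedUniverse$tf, gold@assayedUniverse$target)
  } else {
    ukeys <- edgeKey(rep(gold@assayedTfs, each = length(unique(pred$target))),
                     rep(unique(pred$target), times = length(gold@assayedTfs)))
    ukeys <- setdiff(ukeys, edgeKey(gold@assayedTfs, gold@assayedTfs))
  }
  vkeys <- intersect(edgeKey(validatedEdges(gold)$tf,
                             validatedEdges(gold)$target), ukeys)
  pkeys <- edgeKey(pred$regulator, pred$target)
  inU <- pkeys %in% ukeys
  if (!any(inU))
    stop("no predicted edge lies in the assayed universe")
  list(pred = pred[inU, , drop = FALSE],
       labels = pkeys[inU] %in% vkeys,
       nValidated = length(vkeys), nUniverse = length(ukeys))
}

#' Precision/recall curve of a ranked edge list against a gold standard
#'
#' Predictions are restricted to the assayed universe and walked in rank
#' order; at rank k, tp_k is the number of validated edges among the top k,
#' precision = tp_k / k and recall = tp_k / number of validated edges in
#' the universe. Validated edges absent from the ranked list cap the final
#' recall below 1.
#'
#' @param edgeList a [GRNEdgeList-class]
#' @param gold a [GoldStandard-class]
#' @return a [PRCurve-class]
#' @export
precisionRecallCurve <- function(edgeList, gold) {
  r <- restrictToUniverse(edgeList, gold)
  if (r$nValidated < 1L)
    stop("the gold standard has no validated edges inside the assayed universe")
  tp <- cumsum(r$labels)
  k <- seq_along(r$labels)
  pts <- data.frame(rank = k, weight = r$pred$weight, tp = tp,
                    precision = tp / k, recall = tp / r$nValidated)
  methods::new("PRCurve", points = pts,
               nValidated = as.integer(r$nValidated),
               nUniverse = as.integer(r$nUniverse))
}

#' Area under the precision/recall curve
#'
#' Rectangular (step-function) integration of precision over recall:
#' contributions precision_k * delta(recall) at the ranks where recall
#' increases. Conservative relative to trapezoidal interpolation and exactly
#' reproducible.
#'
#' @param curve a [PRCurve-class]
#' @return AUPR in [0, 1]
#' @export
aupr <- function(curve) {
  p <- curvePoints(curve)
  if (!nrow(p)) stop("empty precision/recall curve")
  dr <- diff(c(0, p$recall))
  sum(p$precision * dr)
}

#' Permutation significance of an observed AUPR
#'
#' The validated labels are reassigned uniformly at random over the assayed
#' universe (preserving their count) and the AUPR recomputed; the p-value is
#' the add-one estimator (1 + #{AUPR_perm >= AUPR_obs}) / (1 + nPerm). The
#' extremes of the permuted AUPRs are also reported, mirroring the
#' random-validation envelope drawn on published curves.
#'
#' @param edgeList a [GRNEdgeList-class]
#' @param gold a [GoldStandard-class]
#' @param nPerm number of permutations
#' @param seed integer seed
#' @return list(p, observed, randomAuprMin, randomAuprMax, nPerm)
#' @export
permutationTestAUPR <- function(edgeList, gold, nPerm = 1000, seed = 1) {
  if (nPerm < 1L) stop("nPerm must be >= 1")
  r <- restrictToUniverse(edgeList, gold)
  m <- nrow(r$pred); v <- r$nValidated; U <- r$nUniverse
  obs <- auprFromLabels(r$labels, v)
  set.seed(deriveSeed(seed, "aupr-perm"))
  perm <- vapply(seq_len(nPerm), function(i) {
    hit <- sample.int(U, v)
    lab <- logical(m)
    lab[hit[hit <= m]] <- TRUE          # ranked edges occupy slots 1..m
    auprFromLabels(lab, v)
  }, 0)
  list(p = (1 + sum(perm >= obs)) / (1 + nPerm), observed = obs,
       randomAuprMin = min(perm), randomAuprMax = max(perm),
       nPerm = as.integer(nPerm))
}

auprFromLabels <- function(labels, nValidated) {
  tp <- cumsum(labels)
  prec <- tp / seq_along(labels)
  sum(prec * (labels / nValidated))
}

#' Select the pruning weight from a precision target
#'
#' Scans the curve for the deepest rank whose precision still meets the
#' target and returns the edge weight at that rank, so that pruning at the
#' returned weight keeps the largest network consistent with the requested
#' precision. Unattainable targets are an explicit error reporting the
#' maximum achievable precision.
#'
#' @param curve a [PRCurve-class]
#' @param precisionTarget required precision in (0, 1]
#' @return list(weightThreshold, rank, precision, recall)
#' @export
selectThreshold <- function(curve, precisionTarget) {
  if (precisionTarget <= 0 || precisionTarget > 1)
    stop("precisionTarget must lie in (0, 1]")
  p <- curvePoints(curve)
  ok <- which(p$precision >= precisionTarget)
  if (!length(ok))
    stop("precision target ", precisionTarget,
         " unattainable; maximum achievable precision is ",
         format(max(p$precision), digits = 4))
  k <- max(ok)
  list(weightThreshold = p$weight[k], rank = p$rank[k],
       precision = p$precision[k], recall = p$recall[k])
}

#' Prune a full network at a weight threshold
#'
#' Keeps every edge with weight at or above the threshold, for validated and
#' unvalidated regulators alike: the threshold learned on the assayed TFs is
#' applied network-wide.
#'
#' @param edgeList the full ranked [GRNEdgeList-class]
#' @param weightThreshold minimum retained weight (>= 0)
#' @param precisionTarget optional precision level that produced the
#'   threshold, recorded in the result
#' @return a [PruneResult-class]
#' @export
pruneNetwork <- function(edgeList, weightThreshold, precisionTarget = NA_real_) {
  if (weightThreshold < 0) stop("weightThreshold must be >= 0")
  e <- edges(edgeList)
  keep <- e[e$weight >= weightThreshold, , drop = FALSE]
  rownames(keep) <- NULL
  methods::new("PruneResult",
               precisionTarget = as.numeric(precisionTarget),
               weightThreshold = as.numeric(weightThreshold),
               edges = methods::new("GRNEdgeList", edges = keep),
               nEdges = nrow(keep),
               nTfs = length(unique(keep$regulator)),
               nTargets = length(unique(keep$target)))
}

#' Set-level precision, recall and F-score
#'
#' precision = |P intersect R| / |P|, recall = |P intersect R| / |R|,
#' F = 2PR / (P + R), with F = 0 when both are zero. An empty prediction has
#' undefined precision, reported as 0 with a warning flag.
#'
#' @param predicted,reference sets (character vectors); edge sets should be
#'   encoded as "tf->target" strings or any unique key
#' @return named numeric c(precision, recall, f_score)
#' @export
prfScores <- function(predicted, reference) {
  predicted <- unique(predicted); reference <- unique(reference)
  if (!length(reference)) stop("reference set must be nonempty")
  if (!length(predicted)) {
    warning("empty prediction: precision undefined, reported as 0")
    return(c(precision = 0, recall = 0, f_score = 0))
  }
  tp <- length(intersect(predicted, reference))
  prec <- tp / length(predicted)
  rec <- tp / length(reference)
  f <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(precision = prec, recall = rec, f_score = f)
}
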