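#' Build a simulation configuration
#'
#' Defaults emulate a field diversity panel: 19 varieties grown under the
#' four combinations of low/high nitrogen and low/high water, three replicate
#' samples per cell, four planted co-expression modules whose latent
#' activities respond to N, W, or their interaction, and module-driven
#' phenotypes (an NUE-for-grain-like trait, a WUE-like trait and a yield-like
#' trait). Transcription factors are themselves module members and each
#' drives a planted set of targets.
#'
#' @param nVarieties,nReplicates design dimensions (default 19 varieties,
#'   3 replicates, as in a typical multi-variety field RNA-seq design)
#' @param conditions data.frame of n_level/w_level combinations; defaults to
#'   the full 2x2 matrix
#' @param nGenes,nTfs,nModules,moduleSizes gene-space dimensions; genes not
#'   claimed by a module are unassigned background ("grey") genes
#' @param latentMeans per-module baseline activity
#' @param latentEffects nModules x 3 matrix of (N, W, N:W) effect sizes; the
#'   default cycles through N-responsive, W-responsive, interaction-responsive
#'   and unresponsive modules
#' @param varietySd sd of per-variety x module random effects (drawn once)
#' @param loadingRange positive range for per-gene loadings on the module
#'   latent activity
#' @param tfOutDegree planted targets per TF
#' @param edgeFunction,edgeCoef transfer function and scale of the planted
#'   TF-to-target effect
#' @param targetPool "own" (default) draws targets from the TF's module and
#'   the background genes; "module" from the TF's module only; "any" from
#'   all genes
#' @param noiseSd Gaussian noise sd on latent activities and gene expression
#' @param backgroundSd sd of background-gene expression
#' @param phenotypeLoadings module x trait coefficient matrix (named columns)
#' @param phenotypeNoiseSd trait-level noise sd
#' @param goldFpRate,goldFnRate default error rates for
#'   [simulateGoldStandard()]
#' @param seed master seed
#' @return a validated [SimulationConfig-class]
#' @export
simulationConfig <- function(nVarieties = 19, nReplicates = 3,
                             conditions = NULL,
                             nGenes = 400, nTfs = 20, nModules = 4,
                             moduleSizes = NULL,
                             latentMeans = NULL, latentEffects = NULL,
                             varietySd = 1, loadingRange = c(0.5, 1.5),
                             tfOutDegree = 10,
                             edgeFunction = "linear", edgeCoef = 0.8,
                             targetPool = "own",
                             noiseSd = 0.1, backgroundSd = 1,
                             phenotypeLoadings = NULL,
                             phenotypeNoiseSd = 0.1,
                             goldFpRate = 0.1, goldFnRate = 0.1, seed = 1) {
  if (is.null(conditions))
    conditions <- expand.grid(n_level = c("low", "high"),
                              w_level = c("low", "high"),
                              stringsAsFactors = FALSE)
  if (is.null(moduleSizes))
    moduleSizes <- rep(floor(0.7 * nGenes / nModules), nModules)
  if (is.null(latentMeans)) latentMeans <- rep(0, nModules)
  if (is.null(latentEffects)) {
    pattern <- rbind(N = c(2, 0, 0), W = c(0, 2, 0),
                     NW = c(0, 0, 2), none = c(0, 0, 0))
    latentEffects <- pattern[rep_len(seq_len(4L), nModules), , drop = FALSE]
    rownames(latentEffects) <- paste0("module_", seq_len(nModules))
  }
  latentEffects <- as.matrix(latentEffects)
  dimnames(latentEffects) <- list(paste0("module_", seq_len(nrow(latentEffects))),
                                  c("N", "W", "N:W"))
  if (is.null(phenotypeLoadings)) {
    phenotypeLoadings <- matrix(0, nModules, 3,
                                dimnames = list(paste0("module_", seq_len(nModules)),
                                                c("nueg", "wue", "grain_yield")))
    phenotypeLoadings[1L, "nueg"] <- 1
    if (nModules >= 2L) phenotypeLoadings[2L, "wue"] <- 1
    if (nModules >= 3L) phenotypeLoadings[3L, "grain_yield"] <- 0.8
  }
  phenotypeLoadings <- as.matrix(phenotypeLoadings)
  rownames(phenotypeLoadings) <- paste0("module_",
                                        seq_len(nrow(phenotypeLoadings)))
  if (is.null(colnames(phenotypeLoadings)))
    colnames(phenotypeLoadings) <- paste0("trait_",
                                          seq_len(ncol(phenotypeLoadings)))
  assertThat(length(loadingRange) == 2L && all(loadingRange > 0) &&
               diff(loadingRange) >= 0, "loadingRange",
             "must be a positive increasing range")
  obj <- methods::new("SimulationConfig",
    nVarieties = as.integer(nVarieties), conditions = conditions,
    nReplicates = as.integer(nReplicates), nGenes = as.integer(nGenes),
    nTfs = as.integer(nTfs), nModules = as.integer(nModules),
    moduleSizes = as.integer(moduleSizes), latentMeans = latentMeans,
    latentEffects = latentEffects, varietySd = varietySd,
    loadingRange = loadingRange, tfOutDegree = as.integer(tfOutDegree),
    edgeFunction = edgeFunction, edgeCoef = edgeCoef,
    targetPool = targetPool, noiseSd = noiseSd, backgroundSd = backgroundSd,
    phenotypeLoadings = phenotypeLoadings,
    phenotypeNoiseSd = phenotypeNoiseSd,
    goldFpRate = goldFpRate, goldFnRate = goldFnRate,
    seed = as.integer(seed))
  methods::validObject(obj)
  obj
}

#' Simulate a synthetic field-trial dataset
#'
#' Generates expression, phenotypes and planted truth under the model: each
#' module's latent activity per sample is
#' `mu_m + bN [N=high] + bW [W=high] + bNW [both] + varietyEffect + noise`;
#' a member gene's expression is `loading * activity + noise` with loadings
#' drawn once per gene from `loadingRange`; planted targets additionally
#' receive `edgeCoef * f(TF expression)`; per variety x condition, each
#' phenotype is the loading-weighted sum of replicate-averaged module
#' activities plus noise. DE classes record which latent effect coefficients
#' are nonzero for a gene's driving module. The same configuration (seed
#' included) always yields an identical dataset.
#'
#' @param config a [SimulationConfig-class]
#' @return a [SyntheticDataset-class]
#' @export
simulateDataset <- function(config) {
  methods::validObject(config)
  nV <- config@nVarieties; nR <- config@nReplicates
  conds <- config@conditions
  nC <- nrow(conds)
  condCodes <- conditionCode(conds$n_level, conds$w_level)

  varieties <- sprintf("v%02d", seq_len(nV))
  design <- expand.grid(replicate = seq_len(nR), cond = seq_len(nC),
                        variety = seq_len(nV))
  nS <- nrow(design)
  sampleIds <- sprintf("%s_%s_r%d", varieties[design$variety],
                       condCodes[design$cond], design$replicate)

  genes <- sprintf("g%04d", seq_len(config@nGenes))
  modLabels <- rep("grey", config@nGenes)
  modNames <- paste0("module_", seq_along(config@moduleSizes))
  idx <- 1L
  for (m in seq_along(config@moduleSizes)) {
    modLabels[idx:(idx + config@moduleSizes[m] - 1L)] <- modNames[m]
    idx <- idx + config@moduleSizes[m]
  }
  names(modLabels) <- genes

  # TFs are module members, spread round-robin across modules
  tfs <- character(config@nTfs)
  perModule <- split(genes[modLabels != "grey"], modLabels[modLabels != "grey"])
  taken <- setNames(rep(0L, length(perModule)), names(perModule))
  for (i in seq_len(config@nTfs)) {
    m <- modNames[(i - 1L) %% config@nModules + 1L]
    if (taken[m] >= length(perModule[[m]]))
      m <- names(which(taken < lengths(perModule)))[1L]
    taken[m] <- taken[m] + 1L
    tfs[i] <- perModule[[m]][taken[m]]
  }

  # per-variety x module random effects
  set.seed(deriveSeed(config@seed, "variety"))
  varEff <- matrix(rnorm(nV * config@nModules, 0, config@varietySd),
                   nV, config@nModules)

  # latent activities per module x sample
  set.seed(deriveSeed(config@seed, "latent"))
  isHN <- conds$n_level[design$cond] == "high"
  isHW <- conds$w_level[design$cond] == "high"
  activity <- matrix(0, config@nModules, nS,
                     dimnames = list(modNames, sampleIds))
  for (m in seq_len(config@nModules)) {
    fixed <- config@latentMeans[m] +
      config@latentEffects[m, 1L] * isHN +
      config@latentEffects[m, 2L] * isHW +
      config@latentEffects[m, 3L] * (isHN & isHW)
    activity[m, ] <- fixed + varEff[design$variety, m] +
      rnorm(nS, 0, config@noiseSd)
  }

  set.seed(deriveSeed(config@seed, "loadings"))
  loadings <- runif(config@nGenes, config@loadingRange[1L],
                    config@loadingRange[2L])
  names(loadings) <- genes

  set.seed(deriveSeed(config@seed, "expression"))
  expr <- matrix(0, config@nGenes, nS, dimnames = list(genes, sampleIds))
  for (g in seq_len(config@nGenes)) {
    lab <- modLabels[g]
    expr[g, ] <- if (lab == "grey") rnorm(nS, 0, config@backgroundSd) else
      loadings[g] * activity[lab, ] + rnorm(nS, 0, config@noiseSd)
  }

  # planted regulatory edges
  set.seed(deriveSeed(config@seed, "edges"))
  # each gene is targeted by at most one TF, so that with noise off every
  # target is an exact affine function of its single planted regulator
  edgeTf <- edgeTarget <- character(0)
  for (tf in tfs) {
    pool <- switch(config@targetPool,
      own = genes[modLabels == modLabels[tf] | modLabels == "grey"],
      module = genes[modLabels == modLabels[tf]],
      genes)
    pool <- setdiff(pool, c(tf, edgeTarget))
    k <- min(config@tfOutDegree, length(pool))
    tg <- sample(pool, k)
    edgeTf <- c(edgeTf, rep(tf, k)); edgeTarget <- c(edgeTarget, tg)
  }
  f <- if (config@edgeFunction == "linear") identity else function(x) x^2
  # effects applied in TF order; a cascade uses the upstream TF's value as of
  # application time
  for (i in seq_along(edgeTf))
    expr[edgeTarget[i], ] <- expr[edgeTarget[i], ] +
      config@edgeCoef * f(expr[edgeTf[i], ])
  trueEdges <- data.frame(tf = edgeTf, target = edgeTarget,
                          stringsAsFactors = FALSE)

  # phenotypes per variety x condition from replicate-averaged activities
  set.seed(deriveSeed(config@seed, "phenotype"))
  cellKey <- paste(varieties[design$variety], condCodes[design$cond], sep = "|")
  cells <- unique(cellKey)
  actMean <- sapply(cells, function(k)
    rowMeans(activity[, cellKey == k, drop = FALSE]))
  if (config@nModules == 1L) actMean <- matrix(actMean, nrow = 1L)
  traitVals <- t(config@phenotypeLoadings) %*% actMean +
    matrix(rnorm(ncol(config@phenotypeLoadings) * length(cells),
                 0, config@phenotypeNoiseSd),
           ncol(config@phenotypeLoadings), length(cells))
  parts <- strsplit(cells, "|", fixed = TRUE)
  pheno <- data.frame(variety = vapply(parts, `[`, "", 1L),
                      condition = vapply(parts, `[`, "", 2L),
                      t(traitVals), stringsAsFactors = FALSE)

  declass <- lapply(genes, function(g) {
    lab <- modLabels[g]
    if (lab == "grey") return(character(0))
    c("N", "W", "N:W")[config@latentEffects[lab, ] != 0]
  })
  names(declass) <- genes

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = expr),
    colData = S4Vectors::DataFrame(
      sample_id = sampleIds, variety = varieties[design$variety],
      n_level = conds$n_level[design$cond],
      w_level = conds$w_level[design$cond],
      condition = condCodes[design$cond],
      replicate = design$replicate, row.names = sampleIds))

  methods::new("SyntheticDataset", expression = se, phenotypes = pheno,
               trueModuleLabels = modLabels, trueEdges = trueEdges,
               trueDeClasses = declass, tfList = tfs, config = config)
}

#' Simulate a noisy gold standard from planted edges
#'
#' Emulates experimentally validated TF-target data over an assayed universe
#' (the cross of the assayed TFs with the candidate targets, self-pairs
#' excluded): each true edge of an assayed TF is dropped with probability
#' `fnRate`, and each non-edge is spuriously validated with probability
#' `fpRate`.
#'
#' @param trueEdges data.frame (tf, target) of planted edges
#' @param assayedTfs TFs whose targets were assayed (must be nonempty)
#' @param fpRate,fnRate false-positive and false-negative probabilities
#' @param candidateTargets genes testable by the assay
#' @param seed integer seed
#' @return a [GoldStandard-class]
#' @export
simulateGoldStandard <- function(trueEdges, assayedTfs, fpRate, fnRate,
                                 candidateTargets, seed = 1) {
  if (!length(assayedTfs)) stop("assayedTfs must be nonempty")
  assertThat(fpRate >= 0 && fpRate <= 1, "fpRate", "must lie in [0, 1]")
  assertThat(fnRate >= 0 && fnRate <= 1, "fnRate", "must lie in [0, 1]")
  universe <- expand.grid(tf = assayedTfs, target = candidateTargets,
                          stringsAsFactors = FALSE)
  universe <- universe[universe$tf != universe$target, , drop = FALSE]
  ukeys <- edgeKey(universe$tf, universe$target)
  tkeys <- edgeKey(trueEdges$tf, trueEdges$target)
  isTrue <- ukeys %in% tkeys
  set.seed(deriveSeed(seed, "gold"))
  u <- runif(nrow(universe))
  keep <- ifelse(isTrue, u >= fnRate, u < fpRate)
  validated <- universe[keep, , drop = FALSE]
  validated$dataset <- "synthetic"
  rownames(validated) <- NULL
  rownames(universe) <- NULL
  methods::new("GoldStandard", validatedEdges = validated,
               assayedTfs = as.character(assayedTfs),
               assayedUniverse = universe)
}

#' Count of TF-to-target edges excluding self-regulation
#'
#' The ranked network over `tfs` regulators and `targets` candidate target
#' genes contains one edge per ordered pair except self-edges, i.e.
#' `|tfs| * |targets| - |tfs intersect targets|`.
#'
#' @param tfs,targets character vectors of gene identifiers
#' @return integer edge count
#' @export
grnEdgeCount <- function(tfs, targets) {
  tfs <- unique(tfs); targets <- unique(targets)
  length(tfs) * length(targets) - length(intersect(tfs, targets))
}
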