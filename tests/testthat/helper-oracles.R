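# Shared fixtures and independent oracles used across the suite.
# Oracles are deliberately naive (double loops, pmf summation, closed-form
# moments) and never call the code paths they check.

suppressPackageStartupMessages(library(SummarizedExperiment))

assayOf <- function(ds) assay(expressionData(ds))

# Study configurations -------------------------------------------------------

# Module-recovery study: the fully partitioned 4-module design
# (200 genes, 50 per module, noise sd 0.1).
moduleStudyConfig <- function(seed)
  simulationConfig(nGenes = 200, nModules = 4, moduleSizes = rep(50, 4),
                   nTfs = 8, tfOutDegree = 5, noiseSd = 0.1, seed = seed)

# Network-inference study: one TF per regulon module, 20 TFs, 500 targets.
grnStudyConfig <- function(seed)
  simulationConfig(nGenes = 520, nTfs = 20, nModules = 20,
                   moduleSizes = rep(6, 20), tfOutDegree = 10,
                   noiseSd = 0.1, seed = seed)

# Prioritization study: a master TF whose 40 targets all sit in the
# trait-loaded module, and a decoy TF whose 40 targets sit in an
# unresponsive, trait-neutral module.
priorityStudyConfig <- function(seed) {
  loadings <- matrix(c(1, 0), 2, 1, dimnames = list(NULL, "nueg"))
  simulationConfig(nGenes = 500, nModules = 2, moduleSizes = c(50, 50),
                   nTfs = 2, tfOutDegree = 40, targetPool = "module",
                   noiseSd = 0.1, phenotypeLoadings = loadings, seed = seed)
}

# Brute-force oracles --------------------------------------------------------

# TOM by direct double-loop evaluation of the formula.
bruteTOM <- function(a) {
  n <- nrow(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- a[i, j]
    for (u in seq_len(n)) if (u != i && u != j) num <- num + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    out[i, j] <- num / (min(ki, kj) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}

# AUPR by independent enumeration: at each validated rank k, add
# precision(k) / nValidated.
bruteAUPR <- function(labels, nValidated) {
  total <- 0
  tp <- 0
  for (k in seq_along(labels)) {
    if (labels[k]) {
      tp <- tp + 1
      total <- total + (tp / k) / nValidated
    }
  }
  total
}

# Hypergeometric overlap moments, written out from first principles.
bruteOverlapMoments <- function(n, K, N) {
  e <- n * K / N
  v <- n * K * (N - K) * (N - n) / (N^2 * (N - 1))
  list(expected = e, sd = sqrt(v))
}

# Upper-tail hypergeometric p by pmf summation (choose() arithmetic).
brutePHyperUpper <- function(x, n, K, N) {
  ks <- x:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Benjamini-Hochberg step-up, direct from the definition:
# fdr_i = min_{j >= i} (m * p_(j) / j), clipped at 1, in original order.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * sorted[i] / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)

# Build a gold standard from a dataset's planted truth restricted to targets.
plantedGold <- function(ds, targets) {
  te <- trueEdges(ds)
  te <- te[te$target %in% targets, , drop = FALSE]
  goldStandard(te[, c("tf", "target")], assayedTfs = tfList(ds))
}
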