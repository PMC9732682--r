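makeSE <- function(mat, variety, n_level, w_level, replicate) {
  SummarizedExperiment(assays = list(expr = mat),
                       colData = S4Vectors::DataFrame(
                         sample_id = colnames(mat), variety = variety,
                         n_level = n_level, w_level = w_level,
                         replicate = replicate, row.names = colnames(mat)))
}

test_that("averageReplicates collapses cells to their arithmetic mean", {
  # two replicates per each of two variety cells; the identical pair is a
  # fixed point and the [1, 3] pair averages to 2
  mat2 <- matrix(c(1, 1, 1, 3), nrow = 1,
                 dimnames = list("g1", paste0("s", 1:4)))
  se2 <- makeSE(mat2, variety = rep(c("v1", "v2"), each = 2),
                n_level = "low", w_level = "low", replicate = rep(1:2, 2))
  avg <- averageReplicates(se2)
  expect_equal(ncol(avg), 2)
  expect_equal(as.numeric(assay(avg)), c(1, 2))  # idempotent + mean(1,3)=2
})

test_that("a 19x4x3 design averages to 76 columns", {
  ds <- simulateDataset(simulationConfig(nGenes = 50, nModules = 1,
                                         moduleSizes = 30, nTfs = 2, seed = 1))
  avg <- averageReplicates(expressionData(ds))
  expect_equal(ncol(avg), 76)
  # every averaged column is the mean of its three replicate columns
  full <- assayOf(ds)
  cd <- colData(expressionData(ds))
  key <- paste(cd$variety, cd$condition, sep = "_")
  for (cell in colnames(avg)[c(1, 40, 76)])
    expect_equal(assay(avg)[, cell],
                 rowMeans(full[, key == cell, drop = FALSE]))
})

test_that("adjacency is |cor|^power with unit diagonal", {
  set.seed(4)
  mat <- matrix(rnorm(200), 20, 10,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  a <- adjacencyMatrix(mat, 6)
  expect_equal(a, abs(cor(t(mat)))^6 + diag(20) * 0, ignore_attr = FALSE,
               tolerance = 1e-12)
  expect_true(isSymmetric(a))
  expect_equal(unname(diag(a)), rep(1, 20))
  expect_true(all(a >= 0 & a <= 1))
  # anti-correlated pair still gets adjacency 1 in the unsigned network
  m2 <- rbind(g1 = 1:10, g2 = -(1:10) * 2 + 3)
  colnames(m2) <- paste0("s", 1:10)
  expect_equal(adjacencyMatrix(m2, 5)["g1", "g2"], 1)
  # cor 0.5 at power 6
  m3 <- rbind(g1 = c(1, 0, -1), g2 = c(0, 1, -1))
  colnames(m3) <- paste0("s", 1:3)
  stopifnot(abs(cor(m3["g1", ], m3["g2", ]) - 0.5) < 1e-12)
  expect_equal(adjacencyMatrix(m3, 6)["g1", "g2"], 0.5^6)
  # zero-variance gene is an error naming the gene
  m4 <- rbind(g1 = 1:5, flatgene = rep(2, 5))
  colnames(m4) <- paste0("s", 1:5)
  expect_error(adjacencyMatrix(m4, 2), "flatgene")
})

test_that("TOM matches its closed forms and the double-loop oracle", {
  # 2-gene network: TOM equals the adjacency itself
  for (c12 in c(0.2, 0.5, 0.9)) {
    a <- matrix(c(1, c12, c12, 1), 2)
    expect_equal(tomSimilarity(a)[1, 2], c12)
  }
  # no off-diagonal adjacency: no overlap
  expect_equal(tomSimilarity(diag(4)), diag(4))
  # random matrices against the brute-force oracle
  for (s in 1:5) {
    set.seed(s)
    n <- sample(4:8, 1)
    a <- matrix(runif(n * n, 0, 0.9), n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    tom <- tomSimilarity(a)
    expect_equal(tom, bruteTOM(a), tolerance = 1e-12)
    expect_true(isSymmetric(tom))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
  expect_error(tomSimilarity(matrix(c(1, 0.2, 0.8, 1), 2)), "symmetric")
})

test_that("module detection recovers planted blocks and handles edge cases", {
  # two near-perfect blocks of 50
  set.seed(2)
  p1 <- rnorm(20); p2 <- rnorm(20)
  mat <- rbind(t(replicate(50, p1 + rnorm(20, 0, 0.05))),
               t(replicate(50, p2 + rnorm(20, 0, 0.05))))
  dimnames(mat) <- list(paste0("g", 1:100), paste0("s", 1:20))
  tom <- tomSimilarity(adjacencyMatrix(mat, 6))
  ms <- detectModules(tom, minModuleSize = 30)
  labs <- moduleLabels(ms)
  expect_equal(length(setdiff(unique(labs), "grey")), 2)
  expect_equal(length(unique(labs[1:50])), 1)
  expect_equal(length(unique(labs[51:100])), 1)
  expect_false(unique(labs[1:50]) == unique(labs[51:100]))
  # min size larger than gene count forces all grey, with a warning
  expect_warning(ms2 <- detectModules(tom, minModuleSize = 200), "grey")
  expect_true(all(moduleLabels(ms2) == "grey"))
})

test_that("detected modules match planted modules on synthetic data", {
  ds <- simulateDataset(moduleStudyConfig(1))
  avg <- averageReplicates(expressionData(ds))
  tom <- tomSimilarity(adjacencyMatrix(avg, 6))
  ms <- detectModules(tom, minModuleSize = 30)
  expect_gte(adjustedRand(moduleLabels(ms), moduleLabels(ds)), 0.8)
})

test_that("soft-power selection reports the scale-free fit honestly", {
  # pure noise never fits a scale-free topology: falls back with a warning
  set.seed(10)
  noise <- matrix(rnorm(60 * 30), 60, 30,
                  dimnames = list(paste0("g", 1:60), paste0("s", 1:30)))
  expect_warning(res <- pickSoftPower(noise, candidatePowers = 1:6),
                 "no candidate power")
  expect_true(all(res$fitTable$signedR2 < 0.8))
  # a perfectly coherent matrix has identical connectivities: degenerate bins
  coh <- matrix(rep(1:10, each = 5), 5, 10,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  expect_error(pickSoftPower(coh, candidatePowers = 2), "bins")
})

test_that("a regulon-structured dataset admits a power passing the fit target", {
  # many small regulon modules over a large background give the decaying
  # connectivity distribution the scale-free criterion expects; compact
  # equal-size module designs do not and fall back with a warning instead
  ds <- simulateDataset(grnStudyConfig(2))
  avg <- averageReplicates(expressionData(ds))
  res <- pickSoftPower(avg, candidatePowers = c(2, 4, 6, 8, 10, 12))
  row <- res$fitTable[res$fitTable$power == res$power, ]
  expect_gte(row$signedR2, 0.8)
  # recompute the fit at the returned power, independently
  ac <- abs(cor(t(assay(avg))))^res$power
  k <- colSums(ac) - 1
  br <- seq(min(k), max(k), length.out = 11)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tapply(k, bin, length); meank <- tapply(k, bin, mean)
  use <- !is.na(freq) & freq > 0 & meank > 0
  fit <- lm(log10(freq[use]) ~ log10(meank[use]))
  signedR2 <- -sign(coef(fit)[2]) * summary(fit)$r.squared
  expect_equal(row$signedR2, unname(signedR2), tolerance = 1e-10)
})

test_that("eigengenes summarize their module as the leading component", {
  # identical genes: the eigengene is the standardized common profile
  p <- rnorm(12)
  mat <- t(replicate(5, p))
  dimnames(mat) <- list(paste0("g", 1:5), paste0("s", 1:12))
  labels <- setNames(rep("module_1", 5), rownames(mat))
  me <- moduleEigengenes(mat, labels)
  expect_equal(sd(me[, 1]), 1, tolerance = 1e-12)
  expect_equal(cor(me[, 1], p), 1, tolerance = 1e-12)
  # genes g and -g: full variance explained, tie broken toward gene 1
  mat2 <- rbind(g1 = p, g2 = -p)
  colnames(mat2) <- paste0("s", 1:12)
  labels2 <- setNames(rep("module_1", 2), rownames(mat2))
  me2 <- moduleEigengenes(mat2, labels2)
  expect_gt(cor(me2[, 1], p), 0)
  expect_lt(abs(mean(cor(t(mat2), me2[, 1]))), 1e-12)
  # random module: |cor| with the leading eigenvector of the gene-gene
  # correlation matrix is 1
  set.seed(3)
  mat3 <- matrix(rnorm(30 * 15), 30, 15,
                 dimnames = list(paste0("g", 1:30), paste0("s", 1:15)))
  labels3 <- setNames(rep("module_1", 30), rownames(mat3))
  me3 <- moduleEigengenes(mat3, labels3)
  z <- t(scale(t(mat3)))
  ev <- eigen(cor(t(mat3)))$vectors[, 1]
  proj <- as.numeric(ev %*% z)   # sample-space image of the top eigenvector
  expect_equal(abs(cor(me3[, 1], proj)), 1, tolerance = 1e-10)
  # constant gene is an error
  mat4 <- rbind(g1 = p, g2 = rep(1, 12))
  colnames(mat4) <- paste0("s", 1:12)
  expect_error(moduleEigengenes(mat4, setNames(rep("module_1", 2),
                                               rownames(mat4))),
               "zero-variance")
})

test_that("module merging follows the iterative closest-pair rule", {
  set.seed(8)
  n <- 40
  base <- rnorm(n)
  mkmod <- function(profile, size, noise)
    t(replicate(size, profile + rnorm(n, 0, noise)))
  # modules 1 and 2 share a latent (high ME correlation), module 3 does not
  m1 <- mkmod(base, 12, 0.3)
  m2 <- mkmod(base, 8, 0.4)
  m3 <- mkmod(rnorm(n), 10, 0.3)
  mat <- rbind(m1, m2, m3)
  dimnames(mat) <- list(paste0("g", 1:30), paste0("s", 1:n))
  labels <- setNames(rep(c("module_1", "module_2", "module_3"), c(12, 8, 10)),
                     rownames(mat))
  ms0 <- new("ModuleSet", labels = labels, eigengenes = matrix(0, 0, 0),
             mergeLog = data.frame(absorbed = character(0),
                                   surviving = character(0),
                                   dissimilarity = numeric(0)))
  merged <- mergeModules(mat, ms0, meDissThres = 0.5)
  labs <- moduleLabels(merged)
  # modules 1 and 2 merged (absorbed into the larger, module_1)
  expect_equal(unname(unique(labs[1:20])), "module_1")
  expect_equal(unname(unique(labs[21:30])), "module_3")
  expect_equal(nrow(mergeLog(merged)), 1)
  expect_equal(mergeLog(merged)$absorbed, "module_2")
  expect_equal(mergeLog(merged)$surviving, "module_1")
  # an uncorrelated pair below threshold stays unmerged
  merged2 <- mergeModules(mat[c(1:12, 21:30), ],
                          new("ModuleSet",
                              labels = labels[c(1:12, 21:30)],
                              eigengenes = matrix(0, 0, 0),
                              mergeLog = mergeLog(ms0)),
                          meDissThres = 0.5)
  expect_equal(nrow(mergeLog(merged2)), 0)
  # merge log dissimilarities reflect the recorded eigengene distance
  expect_lt(mergeLog(merged)$dissimilarity, 0.5)
})

test_that("three-module merging matches an independently traced run", {
  set.seed(21)
  n <- 50
  a <- rnorm(n); b <- 0.9 * a + sqrt(1 - 0.81) * rnorm(n); c0 <- rnorm(n)
  mat <- rbind(t(replicate(10, a + rnorm(n, 0, 0.2))),
               t(replicate(14, b + rnorm(n, 0, 0.2))),
               t(replicate(12, c0 + rnorm(n, 0, 0.2))))
  dimnames(mat) <- list(paste0("g", 1:36), paste0("s", 1:n))
  labels <- setNames(rep(c("module_1", "module_2", "module_3"), c(10, 14, 12)),
                     rownames(mat))
  ms0 <- new("ModuleSet", labels = labels, eigengenes = matrix(0, 0, 0),
             mergeLog = data.frame(absorbed = character(0),
                                   surviving = character(0),
                                   dissimilarity = numeric(0)))
  merged <- mergeModules(mat, ms0, meDissThres = 0.5)
  # independent trace of the rule on the same inputs
  trace <- labels
  repeat {
    mods <- unique(trace)
    if (length(mods) < 2) break
    me <- moduleEigengenes(mat, trace)
    d <- 1 - cor(me); diag(d) <- Inf
    if (min(d) >= 0.5) break
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    pair <- colnames(me)[ij]
    sizes <- table(trace)[pair]
    surv <- if (sizes[1] > sizes[2] ||
                (sizes[1] == sizes[2] && pair[1] < pair[2])) pair[1] else pair[2]
    trace[trace %in% pair] <- surv
  }
  expect_identical(moduleLabels(merged), trace)
})

test_that("module-trait correlation uses the Student approximation", {
  set.seed(5)
  me <- matrix(rnorm(76 * 2), 76, 2, dimnames = list(NULL, c("m1", "m2")))
  me <- scale(me)
  traits <- cbind(t1 = me[, 1], t2 = rnorm(76))
  cs <- moduleTraitCorrelation(me, traits)
  expect_equal(moduleTraitCor(cs)["m1", "t1"], 1, tolerance = 1e-12)
  expect_equal(moduleTraitP(cs)["m1", "t1"], 0)
  # r = 0 exactly gives p = 1
  x <- c(-1, 0, 1, 0); y <- c(0, 1, 0, 1)
  stopifnot(abs(cor(x, y)) < 1e-12)
  cs0 <- moduleTraitCorrelation(cbind(m = x), cbind(t = y))
  expect_equal(unname(moduleTraitP(cs0)[1, 1]), 1)
  # the published magnitude: r = 0.73 at n = 76
  r <- 0.73; n <- 76
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  pref <- 2 * pt(tstat, df = n - 2, lower.tail = FALSE)
  u <- scale(resid(lm(rnorm(76) ~ me[, 1])))
  y73 <- as.numeric(r * scale(me[, 1]) + sqrt(1 - r^2) * u)
  stopifnot(abs(cor(me[, 1], y73) - 0.73) < 1e-10)
  cs73 <- moduleTraitCorrelation(me[, 1, drop = FALSE], cbind(t = y73))
  expect_equal(unname(moduleTraitP(cs73)[1, 1]), pref, tolerance = 1e-10)
  expect_error(moduleTraitCorrelation(me[1:2, ], traits[1:2, ]), "3 samples")
})

test_that("gene significance and membership are plain signed correlations", {
  # a variant of the module study with 40 unassigned background genes so
  # the grey-vs-module comparison is defined
  ds <- simulateDataset(simulationConfig(nGenes = 200, nModules = 4,
                                         moduleSizes = rep(40, 4), nTfs = 8,
                                         tfOutDegree = 5, noiseSd = 0.1,
                                         seed = 3))
  avg <- averageReplicates(expressionData(ds))
  labels <- moduleLabels(ds)
  me <- moduleEigengenes(avg, labels)
  ph <- phenotypes(ds)
  cd <- colData(avg)
  traits <- as.matrix(ph[match(paste(cd$variety, cd$condition),
                               paste(ph$variety, ph$condition)),
                         c("nueg", "wue", "grain_yield")])
  cs <- geneTraitStats(avg, me, traits)
  mat <- assay(avg)
  # agreement with direct recomputation
  g <- rownames(mat)[5]
  expect_equal(geneSignificance(cs)[g, "nueg"],
               cor(mat[g, ], traits[, "nueg"]), tolerance = 1e-10)
  expect_equal(moduleMembership(cs)[g, "module_1"],
               cor(mat[g, ], me[, "module_1"]), tolerance = 1e-10)
  # genes of the trait-loaded module out-correlate background genes
  m1 <- names(labels)[labels == "module_1"]
  grey <- names(labels)[labels == "grey"]
  expect_gt(mean(abs(geneSignificance(cs)[m1, "nueg"])),
            mean(abs(geneSignificance(cs)[grey, "nueg"])))
  # a gene equal to the trait has gs exactly 1
  mat2 <- rbind(mat[1:3, ], traitgene = traits[, "nueg"])
  cs2 <- geneTraitStats(mat2, me, traits)
  expect_equal(geneSignificance(cs2)["traitgene", "nueg"], 1,
               tolerance = 1e-12)
})

test_that("hub-gene filtering applies the above-average GS and MM rule", {
  mkStats <- function(gs, mm, genes, module = "module_1", trait = "nueg") {
    new("CorrelationStats",
        moduleTraitCor = matrix(0, 0, 0), moduleTraitP = matrix(0, 0, 0),
        gs = matrix(gs, ncol = 1, dimnames = list(genes, trait)),
        mm = matrix(mm, ncol = 1, dimnames = list(genes, module)))
  }
  genes <- c("g1", "g2")
  labels <- setNames(rep("module_1", 2), genes)
  # identical scores: the inclusive boundary keeps every gene
  s1 <- mkStats(c(0.5, 0.5), c(0.4, 0.4), genes)
  expect_setequal(filterHubGenes("module_1", labels, s1, "nueg"), genes)
  # only the gene above both means survives
  s2 <- mkStats(c(0.9, 0.1), c(0.9, 0.1), genes)
  expect_equal(filterHubGenes("module_1", labels, s2, "nueg"), "g1")
  # brute-force scan over a random 100-gene module
  set.seed(12)
  genes100 <- paste0("g", 1:100)
  labels100 <- setNames(rep("module_1", 100), genes100)
  gs <- runif(100, -1, 1); mm <- runif(100, -1, 1)
  s3 <- mkStats(gs, mm, genes100)
  got <- filterHubGenes("module_1", labels100, s3, "nueg")
  want <- genes100[abs(gs) >= mean(abs(gs)) & abs(mm) >= mean(abs(mm))]
  expect_identical(got, want)
  # order invariance
  perm <- sample(100)
  s4 <- mkStats(gs[perm], mm[perm], genes100[perm])
  got2 <- filterHubGenes("module_1",
                         setNames(rep("module_1", 100), genes100[perm]),
                         s4, "nueg")
  expect_setequal(got2, want)
})
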