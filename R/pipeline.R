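#' Run one pipeline stage from a configuration
#'
#' Orchestrates the stages of the gene-to-NUE-phenotype pipeline on files in
#' a working directory, appending a manifest entry (stage, config hash,
#' seed, input and output checksums, timestamp) after each run so any stage
#' can be re-executed identically. Stage names:
#' `simulate` (synthetic dataset + gold standard), `phenotypes` (derived NUE
#' metrics), `modules` (co-expression modules, eigengenes, trait stats),
#' `filter` (hub genes), `infer` (random-forest network), `validate`
#' (precision/recall, AUPR, permutation p), `prune` (threshold + pruned
#' network), `prioritize` (overlap z-ranked TFs), `enrich` (term
#' enrichment), `subnetwork` (term-filtered subnetwork export).
#'
#' File names default to fixed locations under `outDir` and may be
#' overridden through `config$paths`. Parameters live under documented
#' config keys; defaults follow the pipeline conventions (eigengene
#' dissimilarity 0.5, precision target 0.31, z >= 10, p <= 0.001, BH alpha
#' 0.05). Rerunning a stage with identical inputs and config reproduces
#' identical outputs.
#'
#' @param stage stage name (see above)
#' @param config named list of parameters (e.g. from [yaml::read_yaml()])
#' @param outDir working directory for inputs/outputs
#' @param seed overrides `config$seed` when non-NULL
#' @return invisibly, a named list of the stage's outputs
#' @export
runStage <- function(stage, config = list(), outDir = ".", seed = NULL) {
  stages <- c("simulate", "phenotypes", "modules", "filter", "infer",
              "validate", "prune", "prioritize", "enrich", "subnetwork")
  if (!stage %in% stages)
    stop("unknown stage '", stage, "'; expected one of: ",
         paste(stages, collapse = ", "))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$seed)) config$seed <- 1L
  fn <- get(paste0("stage_", stage), envir = asNamespace("nuegrn"))
  res <- fn(config, outDir)
  appendManifest(stage, config, outDir, res$inputs, res$outputs)
  invisible(res$value)
}

pathOf <- function(config, outDir, name, default)
  file.path(outDir, if (!is.null(config$paths[[name]]))
    config$paths[[name]] else default)

cfg <- function(config, name, default) {
  if (is.null(config[[name]])) default else config[[name]]
}

appendManifest <- function(stage, config, outDir, inputs, outputs) {
  hashOf <- function(paths) {
    paths <- paths[file.exists(paths)]
    as.list(setNames(unname(tools::md5sum(paths)), basename(paths)))
  }
  tmp <- tempfile(); on.exit(unlink(tmp))
  saveRDS(config, tmp)
  entry <- list(stage = stage, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                seed = config$seed,
                config_hash = unname(tools::md5sum(tmp)),
                inputs = hashOf(inputs), outputs = hashOf(outputs))
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE),
      file = file.path(outDir, "manifest.jsonl"), sep = "\n", append = TRUE)
}

stage_simulate <- function(config, outDir) {
  args <- cfg(config, "simulation", list())
  args$seed <- config$seed
  sc <- do.call(simulationConfig, args)
  ds <- simulateDataset(sc)
  p <- list(expr = pathOf(config, outDir, "expression", "expression.tsv"),
            meta = pathOf(config, outDir, "metadata", "metadata.tsv"),
            pheno = pathOf(config, outDir, "phenotypes", "phenotypes.tsv"),
            tfs = pathOf(config, outDir, "tf_list", "tf_list.txt"),
            edges = pathOf(config, outDir, "true_edges", "true_edges.tsv"),
            mods = pathOf(config, outDir, "true_modules", "true_modules.tsv"),
            gold = pathOf(config, outDir, "gold_standard", "gold_standard.tsv"))
  writeExpression(expressionData(ds), p$expr, p$meta)
  writeTSV(phenotypes(ds), p$pheno)
  writeGeneList(tfList(ds), p$tfs)
  writeTSV(trueEdges(ds), p$edges)
  writeTSV(data.frame(gene = names(moduleLabels(ds)),
                      module = unname(moduleLabels(ds))), p$mods)
  for (cl in c("N", "W", "N:W")) {
    genes <- names(Filter(function(x) cl %in% x, deClasses(ds)))
    writeGeneList(genes, pathOf(config, outDir, paste0("de_", cl),
                                paste0("de_", sub(":", "", cl), ".txt")))
  }
  nAssayed <- cfg(config, "nAssayedTfs", min(3L, length(tfList(ds))))
  gold <- simulateGoldStandard(trueEdges(ds), tfList(ds)[seq_len(nAssayed)],
                               sc@goldFpRate, sc@goldFnRate,
                               rownames(exprMatrix(expressionData(ds))),
                               seed = config$seed)
  writeGoldStandard(gold, p$gold)
  list(value = ds, inputs = character(0), outputs = unlist(p))
}

stage_phenotypes <- function(config, outDir) {
  inp <- pathOf(config, outDir, "field_phenotypes", "field_phenotypes.tsv")
  out <- pathOf(config, outDir, "derived_phenotypes", "derived_phenotypes.tsv")
  tab <- derivePhenotypes(readTSV(inp),
                          ipoTraits = cfg(config, "ipoTraits", "nueg"))
  writeTSV(tab, out)
  list(value = tab, inputs = inp, outputs = out)
}

stage_modules <- function(config, outDir) {
  pe <- pathOf(config, outDir, "expression", "expression.tsv")
  pm <- pathOf(config, outDir, "metadata", "metadata.tsv")
  pp <- pathOf(config, outDir, "phenotypes", "phenotypes.tsv")
  se <- readExpression(pe, pm)
  avg <- averageReplicates(se)
  power <- cfg(config, "softPower", NULL)
  if (is.null(power))
    power <- suppressWarnings(
      pickSoftPower(avg, r2Target = cfg(config, "r2Target", 0.8)))$power
  tom <- tomSimilarity(adjacencyMatrix(avg, power))
  ms <- detectModules(tom, minModuleSize = cfg(config, "minModuleSize", 30),
                      cutHeight = cfg(config, "cutHeight", 0.95))
  ms <- mergeModules(avg, ms, meDissThres = cfg(config, "meDissThres", 0.5))
  pheno <- readTSV(pp)
  cd <- as.data.frame(SummarizedExperiment::colData(avg))
  key <- paste(cd$variety, cd$condition)
  pk <- paste(pheno$variety, pheno$condition)
  traits <- as.matrix(pheno[match(key, pk),
                            setdiff(names(pheno), c("variety", "condition")),
                            drop = FALSE])
  rownames(traits) <- colnames(exprMatrix(avg))
  mt <- moduleTraitCorrelation(eigengenes(ms), traits)
  gstats <- geneTraitStats(avg, eigengenes(ms), traits)
  outs <- list(
    labels = pathOf(config, outDir, "module_labels", "module_labels.tsv"),
    me = pathOf(config, outDir, "eigengenes", "eigengenes.tsv"),
    cor = pathOf(config, outDir, "module_trait_cor", "module_trait_cor.tsv"),
    pv = pathOf(config, outDir, "module_trait_p", "module_trait_p.tsv"),
    gs = pathOf(config, outDir, "gene_stats", "gene_stats.tsv"))
  writeTSV(data.frame(gene = names(moduleLabels(ms)),
                      module = unname(moduleLabels(ms))), outs$labels)
  writeTSV(data.frame(sample_id = rownames(eigengenes(ms)),
                      eigengenes(ms), check.names = FALSE), outs$me)
  writeTSV(data.frame(module = rownames(moduleTraitCor(mt)),
                      moduleTraitCor(mt), check.names = FALSE), outs$cor)
  writeTSV(data.frame(module = rownames(moduleTraitP(mt)),
                      moduleTraitP(mt), check.names = FALSE), outs$pv)
  gsm <- geneSignificance(gstats); mmm <- moduleMembership(gstats)
  colnames(gsm) <- paste0("gs_", colnames(gsm))
  colnames(mmm) <- paste0("mm_", colnames(mmm))
  writeTSV(data.frame(gene = rownames(gsm),
                      module = unname(moduleLabels(ms)[rownames(gsm)]),
                      gsm, mmm, check.names = FALSE), outs$gs)
  list(value = list(modules = ms, traitStats = mt, geneStats = gstats),
       inputs = c(pe, pm, pp), outputs = unlist(outs))
}

stage_filter <- function(config, outDir) {
  pl <- pathOf(config, outDir, "module_labels", "module_labels.tsv")
  pg <- pathOf(config, outDir, "gene_stats", "gene_stats.tsv")
  trait <- cfg(config, "trait", "nueg")
  labTab <- readTSV(pl)
  labels <- setNames(labTab$module, labTab$gene)
  gtab <- readTSV(pg)
  gs <- as.matrix(gtab[, grep("^gs_", names(gtab)), drop = FALSE])
  mm <- as.matrix(gtab[, grep("^mm_", names(gtab)), drop = FALSE])
  colnames(gs) <- sub("^gs_", "", colnames(gs))
  colnames(mm) <- sub("^mm_", "", colnames(mm))
  rownames(gs) <- rownames(mm) <- gtab$gene
  stats <- methods::new("CorrelationStats", moduleTraitCor = matrix(0, 0, 0),
                        moduleTraitP = matrix(0, 0, 0), gs = gs, mm = mm)
  mods <- cfg(config, "modules", setdiff(unique(labels), "grey"))
  hubs <- lapply(mods, function(m) filterHubGenes(m, labels, stats, trait))
  names(hubs) <- mods
  out <- pathOf(config, outDir, "hub_genes", "hub_genes.tsv")
  writeTSV(data.frame(gene = unlist(hubs, use.names = FALSE),
                      module = rep(mods, lengths(hubs))), out)
  list(value = hubs, inputs = c(pl, pg), outputs = out)
}

stage_infer <- function(config, outDir) {
  pe <- pathOf(config, outDir, "expression", "expression.tsv")
  pm <- pathOf(config, outDir, "metadata", "metadata.tsv")
  pt <- pathOf(config, outDir, "tf_list", "tf_list.txt")
  ptg <- pathOf(config, outDir, "target_list", "target_list.txt")
  se <- readExpression(pe, pm)
  tfs <- readGeneList(pt)
  targets <- if (file.exists(ptg)) readGeneList(ptg) else
    rownames(exprMatrix(se))
  el <- inferGRN(se, tfs, targets, nTrees = cfg(config, "nTrees", 1000),
                 mtry = cfg(config, "mtry", "sqrt"), seed = config$seed)
  topK <- cfg(config, "topK", NULL)
  if (!is.null(topK))
    el <- grnEdgeList(head(edges(el), topK))
  out <- pathOf(config, outDir, "edges", "edges.tsv")
  writeEdgeList(el, out)
  list(value = el, inputs = c(pe, pm, pt), outputs = out)
}

stage_validate <- function(config, outDir) {
  pe <- pathOf(config, outDir, "edges", "edges.tsv")
  pg <- pathOf(config, outDir, "gold_standard", "gold_standard.tsv")
  el <- readEdgeList(pe)
  gold <- readGoldStandard(pg)
  curve <- precisionRecallCurve(el, gold)
  perm <- permutationTestAUPR(el, gold, nPerm = cfg(config, "nPerm", 1000),
                              seed = config$seed)
  oc <- pathOf(config, outDir, "pr_curve", "pr_curve.tsv")
  oj <- pathOf(config, outDir, "validation", "validation.json")
  writeTSV(curvePoints(curve), oc)
  jsonlite::write_json(list(aupr = aupr(curve), p = perm$p,
                            randomAuprMin = perm$randomAuprMin,
                            randomAuprMax = perm$randomAuprMax,
                            nValidated = curve@nValidated,
                            nUniverse = curve@nUniverse),
                       oj, auto_unbox = TRUE, digits = NA)
  list(value = list(curve = curve, permutation = perm),
       inputs = c(pe, pg), outputs = c(oc, oj))
}

stage_prune <- function(config, outDir) {
  pe <- pathOf(config, outDir, "edges", "edges.tsv")
  pg <- pathOf(config, outDir, "gold_standard", "gold_standard.tsv")
  el <- readEdgeList(pe)
  thr <- cfg(config, "weightThreshold", NULL)
  ptarget <- cfg(config, "precisionTarget", 0.31)
  if (is.null(thr)) {
    curve <- precisionRecallCurve(el, readGoldStandard(pg))
    thr <- selectThreshold(curve, ptarget)$weightThreshold
    inputs <- c(pe, pg)
  } else {
    ptarget <- NA_real_
    inputs <- pe
  }
  pr <- pruneNetwork(el, thr, precisionTarget = ptarget)
  oe <- pathOf(config, outDir, "pruned_edges", "pruned_edges.tsv")
  orp <- pathOf(config, outDir, "prune_report", "prune_report.tsv")
  writeEdgeList(pr@edges, oe)
  writeTSV(data.frame(precision_target = pr@precisionTarget,
                      weight_threshold = pr@weightThreshold,
                      n_edges = pr@nEdges, n_tfs = pr@nTfs,
                      n_targets = pr@nTargets), orp)
  list(value = pr, inputs = inputs, outputs = c(oe, orp))
}

stage_prioritize <- function(config, outDir) {
  pe <- pathOf(config, outDir, "pruned_edges", "pruned_edges.tsv")
  ps <- pathOf(config, outDir, "trait_gene_set", "trait_gene_set.txt")
  pu <- pathOf(config, outDir, "universe", "universe.txt")
  pt <- pathOf(config, outDir, "tf_list", "tf_list.txt")
  el <- readEdgeList(pe)
  pr <- pruneNetwork(el, min(edges(el)$weight))
  tfs <- if (file.exists(pt)) readGeneList(pt) else NULL
  out <- prioritizeTFs(pr, readGeneList(ps), readGeneList(pu), tfs = tfs,
                       zMin = cfg(config, "zMin", 10),
                       pMax = cfg(config, "pMax", 0.001))
  op <- pathOf(config, outDir, "priority", "priority.tsv")
  writeTSV(out, op)
  list(value = out, inputs = c(pe, ps, pu), outputs = op)
}

stage_enrich <- function(config, outDir) {
  pgs <- pathOf(config, outDir, "gene_set", "gene_set.txt")
  pa <- pathOf(config, outDir, "annotation", "annotation.tsv")
  pu <- pathOf(config, outDir, "universe", "universe.txt")
  res <- goEnrichment(readGeneList(pgs), readAnnotation(pa),
                      readGeneList(pu), alpha = cfg(config, "alpha", 0.05))
  out <- pathOf(config, outDir, "enrichment", "enrichment.tsv")
  writeTSV(res, out)
  list(value = res, inputs = c(pgs, pa, pu), outputs = out)
}

stage_subnetwork <- function(config, outDir) {
  pe <- pathOf(config, outDir, "pruned_edges", "pruned_edges.tsv")
  pp <- pathOf(config, outDir, "priority", "priority.tsv")
  pa <- pathOf(config, outDir, "annotation", "annotation.tsv")
  el <- readEdgeList(pe)
  pr <- pruneNetwork(el, min(edges(el)$weight))
  prio <- readTSV(pp)
  ann <- readAnnotation(pa)
  terms <- cfg(config, "terms", names(ann))
  sub <- extractSubnetwork(pr, prio, ann, terms)
  os <- pathOf(config, outDir, "subnetwork_sif", "subnetwork.sif")
  on <- pathOf(config, outDir, "subnetwork_nodes", "subnetwork_nodes.tsv")
  oe <- pathOf(config, outDir, "subnetwork_edges", "subnetwork_edges.tsv")
  writeSIF(sub$edges, os)
  writeTSV(sub$nodes, on)
  writeTSV(sub$edges, oe)
  list(value = sub, inputs = c(pe, pp, pa), outputs = c(os, on, oe))
}
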