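# Internal helpers shared across modules.

# Canonical key for a (regulator, target) pair. Tab never occurs in gene ids
# produced or accepted by the readers, so the key is collision-free.
edgeKey <- function(tf, target) paste(tf, target, sep = "\t")

# Deterministic 32-bit sub-seed derived from a master seed and a component
# tag, so each stochastic component draws from its own stream.
deriveSeed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  # keep everything in doubles until after the modulus: the product exceeds
  # 32-bit range for large master seeds but stays well inside 2^53
  v <- ((as.double(seed) %% 2147483647) * 48271 + h * 7919) %% 2147483629
  as.integer(v) + 1L
}

# Extract a genes x samples matrix from a SummarizedExperiment or a plain
# matrix; errors if gene names are missing.
exprMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x)
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(rownames(x))) stop("expression matrix must have gene row names")
  if (is.null(colnames(x))) stop("expression matrix must have sample column names")
  if (anyNA(x)) stop("expression matrix must not contain missing values")
  x
}

sampleMetadata <- function(x) {
  if (!methods::is(x, "SummarizedExperiment"))
    stop("sample metadata is required; supply a SummarizedExperiment with ",
         "colData columns variety, n_level, w_level, replicate")
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  need <- c("variety", "n_level", "w_level", "replicate")
  miss <- setdiff(need, names(cd))
  if (length(miss))
    stop("missing sample metadata column(s): ", paste(miss, collapse = ", "))
  cd
}

# Row-standardize: each gene to zero mean, unit variance across samples.
standardizeGenes <- function(mat) {
  mu <- rowMeans(mat)
  s <- apply(mat, 1L, stats::sd)
  if (any(s == 0))
    stop("zero-variance gene(s): ",
         paste(head(rownames(mat)[s == 0], 5L), collapse = ", "))
  (mat - mu) / s
}

conditionCode <- function(n_level, w_level) {
  paste0(ifelse(w_level == "high", "HW", "LW"),
         ifelse(n_level == "high", "HN", "LN"))
}

# Stop with a configuration error naming the offending field.
assertThat <- function(cond, field, what) {
  if (!cond) stop("invalid configuration field '", field, "': ", what,
                  call. = FALSE)
  invisible(TRUE)
}
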