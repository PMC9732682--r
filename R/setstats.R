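#' Significance of the overlap between two gene sets
#'
#' Observed overlap x = |A intersect B| against the null of a random size-n
#' subset of the universe. The analytic method uses the hypergeometric
#' moments, expected = nK/N and var = nK(N-K)(N-n) / (N^2 (N-1)), giving
#' z = (x - expected) / sqrt(var) and the upper-tail p = P(X >= x). The
#' permutation method resamples size-n subsets of the universe (one-set
#' resampling), takes z from the empirical mean/sd of their overlaps with B,
#' and uses the add-one p estimator (1 + #{overlap >= x}) / (1 + nPerm).
#'
#' The universe is an explicit required argument: the z-score depends
#' strongly on N, and different analyses legitimately use different
#' backgrounds (all network genes vs. differentially expressed genes).
#'
#' @param setA,setB gene sets (subsets of `universe`)
#' @param universe background gene set
#' @param method "analytic" (default), "permutation", or "both"
#' @param nPerm permutations for the resampling null
#' @param seed seed for the permutation null
#' @return data.frame with one row per method: observed, expected, sd, z, p,
#'   method, nPerm, seed
#' @export
overlapZScore <- function(setA, setB, universe,
                          method = c("analytic", "permutation", "both"),
                          nPerm = 1000, seed = 1) {
  method <- match.arg(method)
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (!all(setA %in% universe)) stop("setA must be a subset of the universe")
  if (!all(setB %in% universe)) stop("setB must be a subset of the universe")
  # doubles: the moment products overflow 32-bit integers at realistic sizes
  n <- as.double(length(setA)); K <- as.double(length(setB))
  N <- as.double(length(universe))
  if (n < 1L || K < 1L) stop("both sets must be nonempty")
  if (N <= max(n, K))
    stop("degenerate null: the universe must be strictly larger than both sets")
  x <- length(intersect(setA, setB))
  rows <- list()
  if (method %in% c("analytic", "both")) {
    expected <- n * K / N
    v <- n * K * (N - K) * (N - n) / (N^2 * (N - 1))
    if (v == 0) stop("degenerate null: zero overlap variance")
    rows$analytic <- data.frame(
      observed = x, expected = expected, sd = sqrt(v),
      z = (x - expected) / sqrt(v),
      p = stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE),
      method = "analytic", nPerm = NA_integer_, seed = NA_integer_,
      stringsAsFactors = FALSE)
  }
  if (method %in% c("permutation", "both")) {
    set.seed(deriveSeed(seed, "overlap"))
    inB <- universe %in% setB
    ov <- vapply(seq_len(nPerm),
                 function(i) sum(inB[sample.int(length(universe),
                                               length(setA))]), 0L)
    s <- stats::sd(ov)
    if (s == 0) stop("degenerate permutation null: zero overlap variance")
    rows$permutation <- data.frame(
      observed = x, expected = mean(ov), sd = s, z = (x - mean(ov)) / s,
      p = (1 + sum(ov >= x)) / (1 + nPerm),
      method = "permutation", nPerm = as.integer(nPerm),
      seed = as.integer(seed), stringsAsFactors = FALSE)
  }
  do.call(rbind, unname(rows))
}

#' Pairwise and overall intersections and unions of named gene sets
#'
#' @param sets named list of at least two gene sets
#' @return list with `pairwise` (data.frame set_a, set_b, nA, nB,
#'   nIntersection, nUnion), `intersection` and `union` (sorted overall
#'   results), and their counts
#' @export
setOps <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || is.null(names(sets)))
    stop("sets must be a named list of at least two gene sets")
  sets <- lapply(sets, unique)
  nm <- names(sets)
  pairs <- utils::combn(nm, 2L)
  pw <- data.frame(
    set_a = pairs[1L, ], set_b = pairs[2L, ],
    nA = lengths(sets)[pairs[1L, ]], nB = lengths(sets)[pairs[2L, ]],
    nIntersection = apply(pairs, 2L, function(p)
      length(intersect(sets[[p[1L]]], sets[[p[2L]]]))),
    nUnion = apply(pairs, 2L, function(p)
      length(union(sets[[p[1L]]], sets[[p[2L]]]))),
    row.names = NULL, stringsAsFactors = FALSE)
  inter <- sort(Reduce(intersect, sets))
  uni <- sort(Reduce(union, sets))
  list(pairwise = pw, intersection = inter, union = uni,
       nIntersection = length(inter), nUnion = length(uni))
}
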