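#' Nitrogen uptake from Kjeldahl N, shoot dry weight and plant density
#'
#' N uptake (g/m^2) = (Kjeldahl N fraction x shoot dry weight per plant) x
#' plants per m^2. `kjNPercent` is a percentage and is divided by 100, so the
#' product is in grams of N per square metre.
#'
#' @param kjNPercent Kjeldahl N percentage of leaf mass, in [0, 100]
#' @param sdw vegetative shoot dry weight, g/plant
#' @param plantsPerM2 planting density, plants/m^2
#' @return N uptake in g/m^2 (vectorized)
#' @examples
#' computeNUptake(1, 10, 25)   # 2.5 g/m^2
#' @export
computeNUptake <- function(kjNPercent, sdw, plantsPerM2) {
  if (any(kjNPercent < 0) || any(sdw < 0) || any(plantsPerM2 < 0))
    stop("computeNUptake: all inputs must be non-negative")
  if (any(kjNPercent > 100))
    stop("computeNUptake: kjNPercent must be a percentage in [0, 100]")
  (kjNPercent / 100) * sdw * plantsPerM2
}

#' Nitrogen use efficiency as yield per unit N uptake
#'
#' NUEg is grain yield (g/m^2) divided by N uptake (g/m^2); NUEb is the same
#' ratio with total biomass in the numerator. The ratio is undefined at zero
#' uptake: scalar zero/negative uptake raises an error, and in vector input
#' the offending records are returned as NA with a `flagged` attribute rather
#' than being silently dropped.
#'
#' @param yieldValue grain yield or biomass, g/m^2
#' @param nUptake N uptake, g/m^2 (must be positive)
#' @param basis "grain" or "biomass"; informational only, the arithmetic is
#'   identical
#' @return the dimensionless ratio, with attribute `flagged` giving indices
#'   of undefined records when vector input contained nonpositive uptake
#' @export
computeNUE <- function(yieldValue, nUptake, basis = c("grain", "biomass")) {
  basis <- match.arg(basis)
  if (any(yieldValue < 0)) stop("computeNUE: yield must be non-negative")
  bad <- which(nUptake <= 0)
  if (length(nUptake) == 1L && length(bad))
    stop("computeNUE: undefined ratio, n_uptake must be > 0")
  out <- yieldValue / nUptake
  if (length(bad)) {
    out[bad] <- NA_real_
    attr(out, "flagged") <- bad
    warning(length(bad), " record(s) with nonpositive N uptake flagged as NA")
  }
  out
}

#' Potential index of varieties within one condition
#'
#' For varieties measured under the same condition j, the potential index of
#' variety i is (Y_ij - Ybar_j) / Ybar_j, the relative deviation from the
#' conditional mean over all varieties. Positive values mark varieties that
#' outperform the panel mean under that condition. The index sums to zero
#' over varieties by construction. NA entries are flagged, excluded from the
#' mean and returned as NA.
#'
#' @param values per-variety trait values (e.g. NUEg) within one condition
#' @return per-variety index, same length and names as `values`
#' @examples
#' computeIPO(c(3, 1, 2))  # 0.5, -0.5, 0
#' @export
computeIPO <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L)
    stop("computeIPO: need at least 2 varieties with defined values")
  m <- mean(values[ok])
  if (m == 0) stop("computeIPO: undefined index, conditional mean is zero")
  (values - m) / m
}

#' Derive N uptake, NUE and potential-index columns for a phenotype table
#'
#' Expects one row per variety x condition with columns `variety`,
#' `condition`, `grain_yield`, `biomass`, `kj_n_percent`, `sdw`,
#' `plants_per_m2`. Adds `n_uptake`, `nueg`, `nueb` and, per condition, the
#' potential index `ipo` of each requested trait (default NUEg). Records with
#' zero N uptake are flagged (NA) and excluded from the conditional means
#' rather than failing the whole table.
#'
#' @param pheno phenotype data.frame
#' @param ipoTraits derived or raw trait columns to index (default "nueg")
#' @return the table with derived columns appended
#' @export
derivePhenotypes <- function(pheno, ipoTraits = "nueg") {
  need <- c("variety", "condition", "grain_yield", "biomass",
            "kj_n_percent", "sdw", "plants_per_m2")
  miss <- setdiff(need, names(pheno))
  if (length(miss))
    stop("phenotype table is missing column(s): ", paste(miss, collapse = ", "))
  pheno$n_uptake <- computeNUptake(pheno$kj_n_percent, pheno$sdw,
                                   pheno$plants_per_m2)
  pheno$nueg <- suppressWarnings(computeNUE(pheno$grain_yield, pheno$n_uptake))
  pheno$nueb <- suppressWarnings(
    computeNUE(pheno$biomass, pheno$n_uptake, basis = "biomass"))
  attr(pheno$nueg, "flagged") <- NULL
  attr(pheno$nueb, "flagged") <- NULL
  for (tr in ipoTraits) {
    col <- paste0("ipo_", tr)
    pheno[[col]] <- NA_real_
    for (cond in unique(pheno$condition)) {
      i <- pheno$condition == cond
      pheno[[col]][i] <- computeIPO(pheno[[tr]][i])
    }
  }
  pheno
}
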