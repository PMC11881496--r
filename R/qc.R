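#' Hardy-Weinberg equilibrium chi-square test
#'
#' Plain 1-df chi-square test of observed genotype counts against
#' Hardy-Weinberg expectations, without continuity correction. A
#' monomorphic input (one allele absent) returns p = 1 by convention with
#' the `monomorphic` attribute set.
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts (total > 0).
#' @return p-value (numeric scalar) with attributes `chisq` and
#'   `monomorphic`.
#' @examples
#' hwe_test(25, 50, 25)   # exact HW proportions -> p = 1
#' hwe_test(0, 100, 0)    # all heterozygous -> chisq = 100
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop("total genotype count must be positive")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p <= 0 || p >= 1) {
    return(structure(1, chisq = 0, monomorphic = TRUE))
  }
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  o <- c(n_AA, n_Aa, n_aa)
  chisq <- sum((o - e)^2 / e)
  structure(stats::pchisq(chisq, df = 1, lower.tail = FALSE),
            chisq = chisq, monomorphic = FALSE)
}

# Vectorized HWE p-values from dosages; fractional dosages are hard-called
# to the nearest integer genotype for the test only.
hwe_pvalues <- function(geno) {
  hard <- round(geno$dosages)
  nAA <- colSums(hard == 2, na.rm = TRUE)
  nAa <- colSums(hard == 1, na.rm = TRUE)
  naa <- colSums(hard == 0, na.rm = TRUE)
  n <- nAA + nAa + naa
  p <- (2 * nAA + nAa) / (2 * pmax(n, 1))
  mono <- p <= 0 | p >= 1 | n == 0
  pq <- p * (1 - p)
  eAA <- n * p^2; eAa <- n * 2 * pq; eaa <- n * (1 - p)^2
  chisq <- ifelse(mono, 0,
                  (nAA - eAA)^2 / pmax(eAA, .Machine$double.xmin) +
                  (nAa - eAa)^2 / pmax(eAa, .Machine$double.xmin) +
                  (naa - eaa)^2 / pmax(eaa, .Machine$double.xmin))
  pv <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  pv[mono] <- 1
  stats::setNames(pv, geno$marker_meta$marker_id)
}

#' Marker quality-control filter
#'
#' Retains markers with MAF >= `maf_min`, Hardy-Weinberg chi-square
#' p >= `hwe_p_min` and call rate >= `callrate_min`, preserving marker
#' order. The defaults are the filters applied to imputed sequence data in
#' routine cattle evaluations (MAF > 0.01, HWE p > 0.001).
#'
#' @param geno a `genotype_matrix`
#' @param maf_min minimum minor allele frequency in `[0, 1]`.
#' @param hwe_p_min minimum HWE p-value in `[0, 1]`.
#' @param callrate_min minimum per-marker call rate in `[0, 1]`.
#' @return a filtered `genotype_matrix`; errors if no marker survives.
#' @export
filter_markers <- function(geno, maf_min = 0.01, hwe_p_min = 0.001,
                           callrate_min = 0.95) {
  stopifnot(inherits(geno, "genotype_matrix"),
            maf_min >= 0, maf_min <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1,
            callrate_min >= 0, callrate_min <= 1)
  keep <- maf(geno) >= maf_min &
    hwe_pvalues(geno) >= hwe_p_min &
    call_rate(geno) >= callrate_min
  if (!any(keep)) stop("no markers survive QC filtering")
  subset_genotypes(geno, markers = which(keep))
}
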