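#' Centered or standardized design matrix
#'
#' Builds the design matrix used by all models. In `centered` mode column j
#' is `dosage - 2*f_j` (VanRaden's first coding: effect sizes independent of
#' allele frequency). In `standardized` mode columns are further divided by
#' `sqrt(2*f_j*(1 - f_j))` (Yang et al. coding: all markers contribute
#' equally to the genetic variance, so rare alleles carry larger effects).
#' Allele frequencies are always estimated from the full supplied matrix,
#' once, before any reference/target split.
#'
#' @param geno a `genotype_matrix` (no monomorphic markers).
#' @param mode `"centered"` or `"standardized"`.
#' @param freqs optional allele frequencies to reuse (e.g. training-set
#'   frequencies when building a target design matrix).
#' @return numeric matrix, individuals x markers.
#' @export
design_matrix <- function(geno, mode = c("centered", "standardized"),
                          freqs = NULL) {
  mode <- match.arg(mode)
  geno <- impute_mean(geno)
  f <- freqs %||% allele_freq(geno)
  mono <- f <= 0 | f >= 1
  if (any(mono)) {
    stop("monomorphic marker(s): ",
         paste(utils::head(geno$marker_meta$marker_id[mono], 5), collapse = ", "))
  }
  z <- sweep(geno$dosages, 2, 2 * f, "-")
  if (mode == "standardized") {
    z <- sweep(z, 2, sqrt(2 * f * (1 - f)), "/")
  }
  z
}

#' Genomic relationship matrix
#'
#' `centered` mode: `G = Z Z' / sum(2 f_j (1 - f_j))`; `standardized` mode:
#' `G = X X' / M` where `M` is the marker count. The normalizing constant is
#' recorded in `denom` so that per-group GRMs can be recombined exactly into
#' the all-marker GRM with weights `denom_s / sum(denom)`.
#'
#' @inheritParams design_matrix
#' @return an object of class `grm` with elements `values` (N x N), `mode`,
#'   `denom`, `n_markers`, `sample_ids`.
#' @export
compute_grm <- function(geno, mode = c("centered", "standardized"),
                        freqs = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_individuals(geno) >= 2, n_markers(geno) >= 1)
  geno <- impute_mean(geno)
  f <- freqs %||% allele_freq(geno)
  z <- design_matrix(geno, mode, freqs = f)
  denom <- if (mode == "centered") sum(2 * f * (1 - f)) else ncol(z)
  g <- tcrossprod(z) / denom
  new_grm(g, mode, denom, ncol(z), geno$sample_ids)
}

new_grm <- function(values, mode, denom, n_markers, sample_ids) {
  stopifnot(denom > 0)
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(list(values = values, mode = mode, denom = denom,
                 n_markers = n_markers, sample_ids = as.character(sample_ids)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("<grm> ", nrow(x$values), " individuals, mode = ", x$mode,
      ", markers = ", x$n_markers, ", denom = ", format(x$denom), "\n", sep = "")
  invisible(x)
}

#' Subset a GRM to a set of individuals
#' @param g a `grm`
#' @param samples sample ids (character) to keep.
#' @return a `grm`
#' @export
subset_grm <- function(g, samples) {
  ii <- match(samples, g$sample_ids)
  if (anyNA(ii)) stop("unknown sample ids in GRM subset")
  new_grm(g$values[ii, ii, drop = FALSE], g$mode, g$denom, g$n_markers,
          g$sample_ids[ii])
}

#' Validate GRM symmetry and positive semi-definiteness
#' @param g a `grm`
#' @param sym_tol symmetry tolerance.
#' @param psd_tol lower bound allowed on the smallest eigenvalue.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_grm <- function(g, sym_tol = 1e-10, psd_tol = -1e-8) {
  v <- g$values
  if (max(abs(v - t(v))) > sym_tol) stop("GRM is not symmetric to tolerance")
  ev <- min(eigen(v, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < psd_tol * max(1, max(abs(diag(v))))) {
    stop("GRM is not PSD: min eigenvalue ", format(ev))
  }
  invisible(TRUE)
}

#' Per-group GRMs for a marker partition
#'
#' One GRM per annotation group, computed with allele frequencies from the
#' full matrix so that the weighted sum of group GRMs reproduces the
#' all-marker GRM exactly (weights `denom_s / sum(denom_s)` for centered
#' GRMs, `M_s / M` for standardized ones).
#'
#' @param geno a `genotype_matrix`
#' @param anno an `annotation_map` over the same markers.
#' @param mode GRM coding mode.
#' @param min_group_size groups smaller than this are dropped with a warning.
#' @return named list of `grm` objects (one per non-empty group).
#' @export
group_grms <- function(geno, anno, mode = c("centered", "standardized"),
                       min_group_size = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(anno, "annotation_map"))
  grp <- anno$assignments$group[match(geno$marker_meta$marker_id,
                                      anno$assignments$marker_id)]
  if (anyNA(grp)) stop("annotation map does not cover all markers")
  f <- allele_freq(impute_mean(geno))
  labs <- attr(anno, "group_labels")
  out <- list()
  for (lab in labs) {
    jj <- which(grp == lab)
    if (length(jj) == 0) next
    if (length(jj) < min_group_size) {
      warning("group ", lab, " has fewer than ", min_group_size,
              " markers; dropped")
      next
    }
    sub <- subset_genotypes(geno, markers = jj)
    out[[lab]] <- compute_grm(sub, mode, freqs = f[jj])
  }
  if (!length(out)) stop("no non-empty groups")
  out
}
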