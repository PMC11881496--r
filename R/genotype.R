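#' Genotype dosage container
#'
#' Bundles an individuals-by-markers dosage matrix (values in `[0, 2]`,
#' fractional dosages allowed for imputed data) with per-marker metadata.
#' All downstream operations (QC, GRMs, LD, samplers) consume this object.
#'
#' @param dosages numeric matrix, individuals in rows, markers in columns.
#'   Missing values are allowed and are mean-imputed lazily by operations
#'   that require complete data.
#' @param marker_meta data frame with columns `marker_id`, `chrom`, `pos`
#'   (1-based bp), `ref`, `alt`; one row per column of `dosages`. Positions
#'   must be strictly increasing within a chromosome and marker ids unique.
#' @param sample_ids character vector of individual identifiers (defaults to
#'   rownames of `dosages` or `ind_1 ... ind_N`).
#'
#' @return An object of class `genotype_matrix` with elements `dosages`,
#'   `marker_meta` (tibble) and `sample_ids`.
#' @export
genotype_matrix <- function(dosages, marker_meta, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  marker_meta <- tibble::as_tibble(marker_meta)
  need <- c("marker_id", "chrom", "pos")
  if (!all(need %in% names(marker_meta))) {
    stop("marker_meta must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(c("ref", "alt") %in% names(marker_meta))) {
    marker_meta$ref <- marker_meta$ref %||% "A"
    marker_meta$alt <- marker_meta$alt %||% "B"
  }
  if (nrow(marker_meta) != ncol(dosages)) {
    stop("marker_meta rows (", nrow(marker_meta), ") != dosage columns (",
         ncol(dosages), ")")
  }
  if (anyDuplicated(marker_meta$marker_id)) {
    stop("duplicate marker ids: ",
         paste(utils::head(marker_meta$marker_id[duplicated(marker_meta$marker_id)], 3),
               collapse = ", "))
  }
  bad <- dosages < -1e-9 | dosages > 2 + 1e-9
  if (any(bad, na.rm = TRUE)) stop("dosages outside [0, 2]")
  dosages[dosages < 0] <- 0
  dosages[dosages > 2] <- 2
  by_chr <- split(marker_meta$pos, marker_meta$chrom)
  if (any(vapply(by_chr, function(p) any(diff(p) <= 0), logical(1)))) {
    stop("positions must be strictly increasing within each chromosome")
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages) %||% paste0("ind_", seq_len(nrow(dosages)))
  }
  if (length(sample_ids) != nrow(dosages)) stop("sample_ids length mismatch")
  dimnames(dosages) <- list(sample_ids, marker_meta$marker_id)
  structure(
    list(dosages = dosages, marker_meta = marker_meta,
         sample_ids = as.character(sample_ids)),
    class = "genotype_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosages), " individuals x ",
      ncol(x$dosages), " markers on ",
      length(unique(x$marker_meta$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Number of individuals / markers
#' @param geno a `genotype_matrix`
#' @return integer count
#' @export
n_markers <- function(geno) ncol(geno$dosages)

#' @rdname n_markers
#' @export
n_individuals <- function(geno) nrow(geno$dosages)

#' Subset a genotype matrix
#'
#' @param geno a `genotype_matrix`
#' @param markers marker ids (character) or column indices to keep, in the
#'   stored order; `NULL` keeps all.
#' @param samples sample ids or row indices to keep; `NULL` keeps all.
#' @return a `genotype_matrix`
#' @export
subset_genotypes <- function(geno, markers = NULL, samples = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  jj <- seq_len(n_markers(geno))
  if (!is.null(markers)) {
    jj <- if (is.character(markers)) {
      miss <- setdiff(markers, geno$marker_meta$marker_id)
      if (length(miss)) stop("unknown marker ids: ", paste(utils::head(miss, 3), collapse = ", "))
      which(geno$marker_meta$marker_id %in% markers)
    } else sort(unique(as.integer(markers)))
  }
  ii <- seq_len(n_individuals(geno))
  if (!is.null(samples)) {
    ii <- if (is.character(samples)) match(samples, geno$sample_ids) else as.integer(samples)
    if (anyNA(ii)) stop("unknown sample ids")
  }
  genotype_matrix(geno$dosages[ii, jj, drop = FALSE],
                  geno$marker_meta[jj, , drop = FALSE],
                  geno$sample_ids[ii])
}

#' Allele frequencies and minor allele frequencies
#'
#' Frequencies refer to the counted (alt) allele and are estimated from the
#' full supplied matrix after per-marker mean imputation of missing dosages.
#'
#' @param geno a `genotype_matrix`
#' @return numeric vector, one value per marker, named by marker id.
#' @export
allele_freq <- function(geno) {
  f <- colMeans(geno$dosages, na.rm = TRUE) / 2
  names(f) <- geno$marker_meta$marker_id
  f
}

#' @rdname allele_freq
#' @export
maf <- function(geno) {
  f <- allele_freq(geno)
  pmin(f, 1 - f)
}

#' Per-marker call rate
#' @param geno a `genotype_matrix`
#' @return numeric vector in `[0, 1]`, named by marker id.
#' @export
call_rate <- function(geno) {
  cr <- 1 - colMeans(is.na(geno$dosages))
  names(cr) <- geno$marker_meta$marker_id
  cr
}

# Mean-impute missing dosages per marker (imputed WGS data are complete;
# this is a robustness convention for partial inputs).
impute_mean <- function(geno) {
  d <- geno$dosages
  if (!anyNA(d)) return(geno)
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  geno$dosages <- d
  geno
}

#' Marker metadata as a tibble
#' @param geno a `genotype_matrix`
#' @return tibble with marker metadata plus `maf` and `call_rate` columns.
#' @export
marker_info <- function(geno) {
  dplyr::mutate(geno$marker_meta, maf = unname(maf(geno)),
                call_rate = unname(call_rate(geno)))
}
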