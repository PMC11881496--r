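#' Pairwise linkage disequilibrium (r-squared)
#'
#' Squared Pearson correlation between two markers' dosage vectors,
#' clipped to `[0, 1]`.
#'
#' @param geno a `genotype_matrix`
#' @param marker_i,marker_j marker ids or column indices.
#' @return numeric scalar in `[0, 1]`.
#' @export
ld_r2 <- function(geno, marker_i, marker_j) {
  geno <- impute_mean(geno)
  ix <- if (is.character(marker_i)) match(marker_i, geno$marker_meta$marker_id) else marker_i
  jx <- if (is.character(marker_j)) match(marker_j, geno$marker_meta$marker_id) else marker_j
  if (anyNA(c(ix, jx))) stop("unknown marker id")
  x <- geno$dosages[, ix]; y <- geno$dosages[, jx]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance dosage column in LD computation")
  }
  min(max(stats::cor(x, y)^2, 0), 1)
}

# Column-standardized dosages divided by sqrt(n) so crossprod gives
# correlations directly; zero-variance columns map to all-zero columns.
.ld_scaled <- function(d) {
  n <- nrow(d)
  mu <- colMeans(d)
  sdv <- sqrt(colSums(d^2) / n - mu^2)
  s <- sweep(d, 2, mu, "-")
  sdv[sdv == 0] <- Inf
  sweep(s, 2, sdv * sqrt(n), "/")
}

#' Greedy LD pruning
#'
#' Scans markers in ascending position within each chromosome; a marker is
#' dropped when its r-squared with any already-retained marker closer than
#' `window_bp` exceeds `r2_threshold`. Deterministic: the earlier marker is
#' always the one kept.
#'
#' @param geno a `genotype_matrix` (position-sorted, as enforced by the
#'   constructor).
#' @param r2_threshold prune when a pair exceeds this r-squared, in `(0, 1]`.
#' @param window_bp physical window within which pairs are tested (default
#'   1 Mb).
#' @return character vector of retained marker ids, in position order.
#' @export
ld_prune <- function(geno, r2_threshold = 0.99, window_bp = 1e6) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  geno <- impute_mean(geno)
  meta <- geno$marker_meta
  s <- .ld_scaled(geno$dosages)
  keep <- logical(nrow(meta))
  for (chr in unique(meta$chrom)) {
    idx <- which(meta$chrom == chr)
    pos <- meta$pos[idx]
    retained <- integer(0)      # indices into idx
    rpos <- numeric(0)
    for (k in seq_along(idx)) {
      inw <- retained[rpos >= pos[k] - window_bp]
      ok <- TRUE
      if (length(inw)) {
        r2 <- drop(crossprod(s[, idx[inw], drop = FALSE], s[, idx[k]]))^2
        ok <- !any(r2 > r2_threshold)
      }
      if (ok) {
        retained <- c(retained, k)
        rpos <- c(rpos, pos[k])
      }
    }
    keep[idx[retained]] <- TRUE
  }
  meta$marker_id[keep]
}

#' Per-marker LD scores
#'
#' `score_j = sum_k r2(j, k)` over markers `k` within `window_bp` of marker
#' `j` on the same chromosome, including the self term (so every score is
#' at least 1). This is the quantity used to build LD-score quartile bins
#' for LD/MAF-stratified (LDMS) models.
#'
#' @inheritParams ld_prune
#' @return tibble with columns `marker_id`, `chrom`, `pos`, `ld_score`.
#' @export
ld_scores <- function(geno, window_bp = 1e6) {
  geno <- impute_mean(geno)
  meta <- geno$marker_meta
  s <- .ld_scaled(geno$dosages)
  score <- numeric(nrow(meta))
  for (chr in unique(meta$chrom)) {
    idx <- which(meta$chrom == chr)
    pos <- meta$pos[idx]
    lo <- findInterval(pos - window_bp, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + window_bp, pos)
    for (k in seq_along(idx)) {
      nb <- idx[lo[k]:hi[k]]
      r <- drop(crossprod(s[, nb, drop = FALSE], s[, idx[k]]))
      score[idx[k]] <- sum(pmin(r^2, 1))
    }
  }
  tibble::tibble(marker_id = meta$marker_id, chrom = meta$chrom,
                 pos = meta$pos, ld_score = score)
}
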