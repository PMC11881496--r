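# Small fixtures shared across test files. Everything is generated in code.

# A toy genotype matrix from an explicit dosage matrix (markers in columns).
toy_geno <- function(dos, chrom = "1", pos = NULL) {
  dos <- as.matrix(dos)
  M <- ncol(dos)
  pos <- pos %||% (seq_len(M) * 1000L)
  gsannot::genotype_matrix(
    dos,
    tibble::tibble(marker_id = paste0("m", seq_len(M)),
                   chrom = rep(chrom, M), pos = pos,
                   ref = "A", alt = "B"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Unlinked HWE genotypes: n individuals x M markers, frequencies uniform.
hwe_geno <- function(n, M, fmin = 0.05, fmax = 0.5, seed = 1) {
  set.seed(seed)
  f <- runif(M, fmin, fmax)
  dos <- vapply(f, function(p) rbinom(n, 2, p), numeric(n))
  toy_geno(dos)
}

# Phenotype tibble from a named vector.
pheno_tbl <- function(y, ids = names(y)) {
  tibble::tibble(sample_id = ids, value = as.numeric(y))
}

# A small simulated cohort reused by several files.
small_sim <- function(n = 300, M = 1000, h2 = 0.5, seed = 42, ...) {
  gsannot::simulate_dataset(gsannot::sim_config(
    n_individuals = n, n_markers = M, h2 = h2, seed = seed, ...))
}

# Brute-force quadratic-time LD pruner (independent oracle for ld_prune).
brute_prune <- function(geno, r2, window_bp) {
  meta <- geno$marker_meta
  keep <- character(0)
  for (chr in unique(meta$chrom)) {
    idx <- which(meta$chrom == chr)
    kept <- integer(0)
    for (k in idx) {
      ok <- TRUE
      for (j in kept) {
        if (abs(meta$pos[j] - meta$pos[k]) <= window_bp &&
            gsannot::ld_r2(geno, j, k) > r2) { ok <- FALSE; break }
      }
      if (ok) kept <- c(kept, k)
    }
    keep <- c(keep, meta$marker_id[kept])
  }
  keep
}

# Wrap an explicit relationship matrix for REML edge-case tests.
new_grm_for_test <- function(values, ids) {
  gsannot:::new_grm(values, "centered", 1, ncol(values), ids)
}
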