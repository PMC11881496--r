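#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults emulate the
#' statistical structure the analysis assumes for imputed sequence data in
#' a beef-cattle cohort: a rare-skewed MAF spectrum floored at 0.01,
#' block-wise LD from a founder-haplotype pool, eight functional annotation
#' categories with genome-wide proportions of roughly 0.37 / 0.28 / 7.58 /
#' 3.83 / 2.96 / 6.49 / 26.54 / 51.94 percent (coding, eQTL, ATAC-only,
#' epigenetic-only, both, exon-associated, intronic, intergenic),
#' group-specific effect sizes with strong enrichment of coding and eQTL
#' variants and depletion of intergenic ones, spike-plus-mixture effects
#' (relative component variances 1e-4 / 1e-3 / 1e-2), and a birth-date
#' range/cutoff that sends about 18.4% of individuals to the target set.
#'
#' @param n_individuals,n_markers,n_chromosomes cohort dimensions.
#' @param spacing_bp distance between adjacent markers.
#' @param maf_beta shape parameters of the Beta draw for block allele
#'   frequencies, rescaled to `[maf_floor, 0.5]`.
#' @param maf_floor minimum realized MAF (enforced by rejection).
#' @param ld_block_len haplotype-block length in bp.
#' @param copy_rate per-marker probability that a haplotype keeps copying
#'   the same founder allele within a block (controls within-block r2).
#' @param pool_size founder haplotypes per block.
#' @param group_props named FAN1 category proportions (must sum to 1 after
#'   normalization).
#' @param group_enrichments named per-group relative effect sizes; the
#'   implied genetic-variance shares `prop * enrichment` are normalized to
#'   sum to 1. A single raw share above 1 is infeasible and errors.
#' @param mixture a [mixture_spec()].
#' @param mixture_props probabilities of (null, small, medium, large)
#'   effect components for causal-architecture draws.
#' @param h2 per-trait heritability (recycled over traits).
#' @param n_traits number of linear score traits (4 adds the weighted
#'   overall score).
#' @param shared_causal_frac fraction of causal markers shared between
#'   traits.
#' @param muscle_eqtl_frac,muscle_reg_frac fractions of eQTL / epigenetic
#'   regulatory entries flagged as detected in muscle.
#' @param mmd_frac,array_frac fractions of markers placed on the
#'   medium-density and commercial arrays (MAF-weighted sampling).
#' @param birth_date_range,split_cutoff uniform birth-date range and the
#'   reference/target cutoff date.
#' @param architecture `"centered"` (effect sizes independent of
#'   frequency; common variants carry most variance) or `"standardized"`
#'   (rare variants carry larger effects).
#' @param seed base RNG seed; the genotype, track and phenotype stages use
#'   `seed`, `seed + 1`, `seed + 2`.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 1000, n_markers = 5000,
                       n_chromosomes = 5, spacing_bp = 1000,
                       maf_beta = c(0.5, 1.0), maf_floor = 0.01,
                       ld_block_len = 25000, copy_rate = 0.95,
                       pool_size = 30,
                       group_props = c(coding = 0.37, eqtl = 0.28,
                                       reg_atac = 7.58, reg_epigenetic = 3.83,
                                       reg_both = 2.96, exon_assoc = 6.49,
                                       intronic = 26.54, intergenic = 51.94) / 100,
                       group_enrichments = c(coding = 16, eqtl = 20,
                                             reg_atac = 1.7,
                                             reg_epigenetic = 3.1,
                                             reg_both = 3.9, exon_assoc = 1,
                                             intronic = 1, intergenic = 0.43),
                       mixture = mixture_spec(),
                       mixture_props = c(0.994, 0.0045, 0.001, 0.0005),
                       h2 = 0.4, n_traits = 4, shared_causal_frac = 0.7,
                       muscle_eqtl_frac = 4889 / 22817,
                       muscle_reg_frac = 0.05,
                       mmd_frac = 0.01, array_frac = 0.077,
                       birth_date_range = c("2010-03-01", "2020-12-31"),
                       split_cutoff = "2019-01-01",
                       architecture = c("centered", "standardized"),
                       seed = 1) {
  architecture <- match.arg(architecture)
  stopifnot(all(h2 >= 0 & h2 < 1), abs(sum(mixture_props) - 1) < 1e-8,
            copy_rate >= 0, copy_rate <= 1)
  group_props <- group_props / sum(group_props)
  stopifnot(identical(sort(names(group_props)), sort(names(group_enrichments))))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate genotype dosages
#'
#' Block-haplotype-pool model: each LD block holds a pool of founder
#' haplotypes generated by a Markov copying process (stationary allele
#' frequency per block, copy rate `copy_rate` between adjacent markers);
#' every individual draws two founder haplotypes per block independently
#' across blocks, which creates strong within-block LD and negligible
#' cross-block LD. Markers whose realized MAF falls below the floor are
#' redrawn.
#'
#' @param cfg a [sim_config()].
#' @return a `genotype_matrix`.
#' @export
simulate_genotypes <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  M <- cfg$n_markers
  per_chr <- diff(round(seq(0, M, length.out = cfg$n_chromosomes + 1)))
  markers_per_block <- max(1, round(cfg$ld_block_len / cfg$spacing_bp))
  K <- cfg$pool_size
  draw_f <- function(k) {
    cfg$maf_floor + (0.5 - cfg$maf_floor) *
      stats::rbeta(k, cfg$maf_beta[1], cfg$maf_beta[2])
  }
  dos <- matrix(0, n, M)
  meta <- vector("list", cfg$n_chromosomes)
  col0 <- 0
  for (chr in seq_len(cfg$n_chromosomes)) {
    m_chr <- per_chr[chr]
    if (m_chr == 0) next
    pos <- seq_len(m_chr) * cfg$spacing_bp
    block_of <- (seq_len(m_chr) - 1) %/% markers_per_block
    for (b in unique(block_of)) {
      jj <- which(block_of == b)
      f_b <- draw_f(1)
      pool <- matrix(0L, K, length(jj))
      pool[, 1] <- stats::rbinom(K, 1, f_b)
      if (length(jj) > 1) {
        for (m in 2:length(jj)) {
          keep <- stats::runif(K) < cfg$copy_rate
          pool[, m] <- ifelse(keep, pool[, m - 1], stats::rbinom(K, 1, f_b))
        }
      }
      i1 <- sample.int(K, n, replace = TRUE)
      i2 <- sample.int(K, n, replace = TRUE)
      dos[, col0 + jj] <- pool[i1, , drop = FALSE] + pool[i2, , drop = FALSE]
      # enforce the MAF floor marker by marker
      for (m in seq_along(jj)) {
        for (try in 1:20) {
          fm <- mean(dos[, col0 + jj[m]]) / 2
          if (min(fm, 1 - fm) >= cfg$maf_floor) break
          f_new <- if (try < 20) draw_f(1) else 0.3
          colp <- stats::rbinom(K, 1, f_new)
          dos[, col0 + jj[m]] <- colp[i1] + colp[i2]
        }
      }
    }
    meta[[chr]] <- tibble::tibble(
      marker_id = sprintf("snp_%d_%d", chr, seq_len(m_chr)),
      chrom = as.character(chr), pos = pos, ref = "A", alt = "B")
    col0 <- col0 + m_chr
  }
  genotype_matrix(dos, dplyr::bind_rows(meta),
                  sample_ids = sprintf("ind_%04d", seq_len(n)))
}

#' Simulate functional annotation tracks
#'
#' Assigns markers to the eight functional categories multinomially with
#' the configured proportions and materializes consistent evidence tracks:
#' id lists for coding and eQTL variants (with muscle flags), interval
#' tracks for ATAC-seq, epigenetic, exon-associated and intronic evidence
#' (intervals centered on the tagged positions, narrow enough never to
#' cover a neighboring marker), and MAF-weighted MMD/commercial-array
#' memberships (the commercial set includes the MMD markers).
#'
#' @param cfg a [sim_config()].
#' @param geno a `genotype_matrix` from [simulate_genotypes()].
#' @return list with `tracks` (a `feature_tracks`) and `categories`
#'   (tibble `marker_id`, `category` of the generating assignment).
#' @export
simulate_tracks <- function(cfg, geno) {
  set.seed(cfg$seed + 1)
  meta <- geno$marker_meta
  M <- nrow(meta)
  cats <- names(cfg$group_props)
  assign <- sample(cats, M, replace = TRUE, prob = cfg$group_props)
  hw <- max(0L, floor(min(diff(sort(unique(meta$pos)))) / 2) - 1L)
  iv_for <- function(sel) {
    tibble::tibble(chrom = meta$chrom[sel],
                   start = pmax(1L, meta$pos[sel] - hw),
                   end = meta$pos[sel] + hw)
  }
  is_atac <- assign %in% c("reg_atac", "reg_both")
  is_epi <- assign %in% c("reg_epigenetic", "reg_both")
  epi <- iv_for(is_epi)
  epi$muscle <- stats::runif(nrow(epi)) < cfg$muscle_reg_frac
  eqtl_ids <- meta$marker_id[assign == "eqtl"]
  mafs <- maf(geno)
  pick_weighted <- function(k) {
    sample(meta$marker_id, min(k, M), prob = mafs)
  }
  mmd <- pick_weighted(round(cfg$mmd_frac * M))
  arr <- union(mmd, pick_weighted(round(cfg$array_frac * M)))
  tracks <- feature_tracks(
    coding_ids = meta$marker_id[assign == "coding"],
    eqtl = tibble::tibble(marker_id = eqtl_ids,
                          muscle = stats::runif(length(eqtl_ids)) <
                            cfg$muscle_eqtl_frac),
    atac = iv_for(is_atac),
    epigenetic = epi,
    exon_assoc = iv_for(assign == "exon_assoc"),
    intron = iv_for(assign == "intronic"),
    mmd_ids = mmd, array_ids = arr)
  list(tracks = tracks,
       categories = tibble::tibble(marker_id = meta$marker_id,
                                   category = assign))
}

#' Simulate marker effects and phenotypes
#'
#' Per annotation group, marker effects follow a spike at zero plus the
#' configured Gaussian mixture; per-group effects are rescaled so the
#' realized genetic-variance shares match `prop * enrichment` (normalized
#' to 1). Genetic values are `Z beta` under the centered architecture or
#' `X beta` under the standardized one; Gaussian noise is scaled
#' empirically against the realized genetic variance so the target
#' heritability is met in-sample. Traits share `shared_causal_frac` of
#' their causal markers; with four traits the weighted overall score is
#' appended. Birth dates are drawn uniformly over the configured range.
#'
#' @param cfg a [sim_config()].
#' @param geno a `genotype_matrix`.
#' @param tracks a `feature_tracks` (only the assignment-relevant parts
#'   are used, via [assign_fan1()]).
#' @return list with `truth` (per-trait tibbles of `true_effects`,
#'   `true_bv`, `true_group_shares`, `true_h2_realized`) and `pheno`
#'   (tibble `sample_id`, `birth_date`, one column per trait).
#' @export
simulate_effects_and_phenotypes <- function(cfg, geno, tracks) {
  set.seed(cfg$seed + 2)
  anno <- assign_fan1(geno, tracks)
  grp <- anno$assignments$group
  M <- n_markers(geno)
  n <- n_individuals(geno)
  W <- design_matrix(geno, cfg$architecture)
  props <- table(factor(grp, levels = names(cfg$group_props))) / M
  raw_share <- as.numeric(props) * cfg$group_enrichments[names(cfg$group_props)]
  names(raw_share) <- names(cfg$group_props)
  if (any(raw_share > 1)) {
    stop("infeasible enrichment target: group share above 1 for ",
         paste(names(raw_share)[raw_share > 1], collapse = ", "))
  }
  share <- raw_share / sum(raw_share)
  share[as.numeric(props) == 0] <- 0
  share <- share / sum(share)
  h2 <- rep(cfg$h2, length.out = cfg$n_traits)
  relv <- cfg$mixture$rel_variances
  # base architecture: per-marker component (0 = null)
  draw_components <- function() {
    comp <- sample(0:length(relv), M, replace = TRUE, prob = cfg$mixture_props)
    for (g in names(share)) {
      jj <- which(grp == g)
      if (length(jj) && share[g] > 0 && all(comp[jj] == 0)) {
        comp[jj[sample.int(length(jj), 1)]] <- 2L  # guarantee a causal marker
      }
    }
    comp
  }
  base_comp <- draw_components()
  causal_base <- which(base_comp > 0)
  shared <- causal_base[stats::runif(length(causal_base)) < cfg$shared_causal_frac]
  trait_names <- if (cfg$n_traits == 4) {
    c("shoulder", "top", "buttock_side", "buttock_rear")
  } else paste0("trait_", seq_len(cfg$n_traits))
  bd <- as.Date(cfg$birth_date_range)
  birth <- bd[1] + floor(stats::runif(n) * (as.numeric(bd[2] - bd[1]) + 1))
  pheno <- tibble::tibble(sample_id = geno$sample_ids, birth_date = birth)
  truth <- list()
  for (t in seq_len(cfg$n_traits)) {
    comp <- integer(M)
    comp[shared] <- base_comp[shared]
    respec <- setdiff(causal_base, shared)
    for (j in respec) {   # trait-specific causal markers: same group/component
      cand <- which(grp == grp[j] & comp == 0)
      if (length(cand)) comp[cand[sample.int(length(cand), 1)]] <- base_comp[j]
    }
    beta <- numeric(M)
    nz <- comp > 0
    beta[nz] <- stats::rnorm(sum(nz), 0, sqrt(relv[comp[nz]]))
    u <- numeric(n)
    gshare <- stats::setNames(numeric(length(share)), names(share))
    for (g in names(share)) {
      jj <- which(grp == g & nz)
      if (!length(jj) || share[g] == 0) next
      ug <- drop(W[, jj, drop = FALSE] %*% beta[jj])
      v <- stats::var(ug)
      if (v > 0) {
        sc <- sqrt(share[g] / v)
        beta[jj] <- beta[jj] * sc
        u <- u + ug * sc
      }
    }
    vu <- stats::var(u)
    for (g in names(share)) {
      jj <- which(grp == g & nz)
      if (length(jj)) {
        gshare[g] <- stats::var(drop(W[, jj, drop = FALSE] %*% beta[jj])) / vu
      }
    }
    e0 <- stats::rnorm(n)
    if (h2[t] == 0) {        # degenerate: no genetic signal at all
      beta[] <- 0
      u[] <- 0
      vu <- 0
      gshare[] <- 0
      yph <- e0
    } else {
      e <- e0 / stats::sd(e0) * sqrt(vu * (1 - h2[t]) / h2[t])
      yph <- u + e
    }
    pheno[[trait_names[t]]] <- yph
    truth[[trait_names[t]]] <- list(
      true_effects = stats::setNames(beta, geno$marker_meta$marker_id),
      true_bv = stats::setNames(u, geno$sample_ids),
      true_group_shares = gshare,
      true_h2_realized = vu / stats::var(yph))
  }
  if (cfg$n_traits == 4) {
    pheno$overall <- combine_overall_score(pheno$shoulder, pheno$top,
                                           pheno$buttock_side,
                                           pheno$buttock_rear)
  }
  list(truth = truth, pheno = pheno, target_shares = share,
       annotation = anno)
}

#' Simulate a full cohort
#'
#' Convenience wrapper running genotype, track and phenotype simulation.
#'
#' @param cfg a [sim_config()].
#' @return list with `geno`, `tracks`, `categories`, `truth`, `pheno`,
#'   `annotation`, `target_shares` and the `cfg` used.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  geno <- simulate_genotypes(cfg)
  tr <- simulate_tracks(cfg, geno)
  ep <- simulate_effects_and_phenotypes(cfg, geno, tr$tracks)
  list(geno = geno, tracks = tr$tracks, categories = tr$categories,
       truth = ep$truth, pheno = ep$pheno, annotation = ep$annotation,
       target_shares = ep$target_shares, cfg = cfg)
}
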