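test_that("genotype simulation is deterministic and respects the MAF floor", {
  cfg <- sim_config(n_individuals = 200, n_markers = 800, seed = 71)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosages, g2$dosages)
  expect_true(all(maf(g1) >= cfg$maf_floor))
  expect_true(all(g1$dosages %in% 0:2))
  # different seeds differ
  g3 <- simulate_genotypes(sim_config(n_individuals = 200, n_markers = 800,
                                      seed = 72))
  expect_false(identical(g1$dosages, g3$dosages))
})

test_that("block LD structure matches the copying-rate dial", {
  # near-perfect copying: adjacent markers tightly linked
  tight <- simulate_genotypes(sim_config(n_individuals = 400, n_markers = 400,
                                         n_chromosomes = 1, copy_rate = 0.999,
                                         seed = 73))
  meta <- tight$marker_meta
  blocks <- (seq_len(400) - 1) %/% 25
  adj <- which(diff(blocks) == 0)  # adjacent pairs inside a block
  r2_adj <- vapply(adj[seq(1, length(adj), by = 4)], function(j) {
    ld_r2(tight, j, j + 1)
  }, numeric(1))
  expect_gt(mean(r2_adj), 0.8)

  # independent blocks: negligible cross-block LD
  far <- replicate(60, {
    j <- sample.int(375, 1)
    ld_r2(tight, j, j + 25)  # one full block away
  })
  expect_lt(mean(far), 0.05)
})

test_that("annotation category draws match the configured proportions", {
  cfg <- sim_config(n_individuals = 30, n_markers = 20000, seed = 75)
  g <- simulate_genotypes(cfg)
  tr <- simulate_tracks(cfg, g)
  tab <- table(factor(tr$categories$category, levels = names(cfg$group_props)))
  # chi-square goodness of fit against the configured proportions
  gof <- suppressWarnings(
    chisq.test(as.integer(tab), p = as.numeric(cfg$group_props)))
  expect_gt(gof$p.value, 0.001)
  # intergenic fraction close to its genome-wide share
  expect_lt(abs(tab[["intergenic"]] / 20000 - 0.5194), 0.02)
  # the realized FAN1 assignment reproduces the generating categories
  a <- assign_fan1(g, tr$tracks)
  agree <- mean(a$assignments$group == tr$categories$category)
  expect_gt(agree, 0.999)
})

test_that("track draws with different seeds differ but keep sizes", {
  cfg1 <- sim_config(n_individuals = 30, n_markers = 3000, seed = 76)
  g <- simulate_genotypes(cfg1)
  t1 <- simulate_tracks(cfg1, g)
  cfg2 <- cfg1; cfg2$seed <- 99
  t2 <- simulate_tracks(cfg2, g)
  expect_false(identical(t1$categories$category, t2$categories$category))
  expect_equal(length(t1$tracks$mmd_ids), length(t2$tracks$mmd_ids))
})

test_that("realized heritability hits the target", {
  dat <- small_sim(n = 2000, M = 1500, h2 = 0.4, seed = 77)
  for (tr in c("shoulder", "top")) {
    expect_lt(abs(dat$truth[[tr]]$true_h2_realized - 0.4), 0.02)
  }
  # zero heritability: phenotype carries no genetic signal
  dat0 <- small_sim(n = 400, M = 300, h2 = 0, seed = 78)
  expect_equal(dat0$truth$shoulder$true_h2_realized, 0)
  expect_equal(unname(dat0$truth$shoulder$true_bv), rep(0, 400))
})

test_that("group enrichment targets shape the realized variance shares", {
  cfg <- sim_config(n_individuals = 800, n_markers = 4000, seed = 79,
                    group_enrichments = c(coding = 20, eqtl = 1,
                                          reg_atac = 1, reg_epigenetic = 1,
                                          reg_both = 1, exon_assoc = 1,
                                          intronic = 1, intergenic = 1))
  dat <- simulate_dataset(cfg)
  props <- group_sizes(dat$annotation) / 4000
  expected <- props * cfg$group_enrichments[names(props)]
  expected <- expected / sum(expected)
  got <- dat$truth$shoulder$true_group_shares
  # shares of the large groups track prop x enrichment (normalized)
  big <- names(expected)[props > 0.05]
  expect_lt(max(abs(got[big] - expected[big])), 0.12)
  expect_equal(sum(got), 1, tolerance = 0.2)  # cross-group covariance slack

  # infeasible target: a single group asked to exceed the whole variance
  cfg_bad <- sim_config(n_individuals = 50, n_markers = 500, seed = 80,
                        group_enrichments = c(coding = 5000, eqtl = 1,
                                              reg_atac = 1,
                                              reg_epigenetic = 1,
                                              reg_both = 1, exon_assoc = 1,
                                              intronic = 1, intergenic = 1))
  g <- simulate_genotypes(cfg_bad)
  trk <- simulate_tracks(cfg_bad, g)
  expect_error(simulate_effects_and_phenotypes(cfg_bad, g, trk$tracks),
               "infeasible")
})

test_that("overall score column is the weighted score combination", {
  dat <- small_sim(n = 100, M = 200, seed = 81)
  expect_equal(dat$pheno$overall,
               combine_overall_score(dat$pheno$shoulder, dat$pheno$top,
                                     dat$pheno$buttock_side,
                                     dat$pheno$buttock_rear))
})
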