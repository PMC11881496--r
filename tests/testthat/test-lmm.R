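# Independent oracle: Henderson's mixed-model equations over ref + target
# individuals, records mapped by an incidence matrix.
mme_oracle <- function(y, G, ref_idx, sg, se) {
  n_all <- nrow(G)
  Z <- matrix(0, length(ref_idx), n_all)
  Z[cbind(seq_along(ref_idx), ref_idx)] <- 1
  X <- matrix(1, length(ref_idx), 1)
  lambda <- se / sg
  lhs <- rbind(cbind(crossprod(X), crossprod(X, Z)),
               cbind(crossprod(Z, X), crossprod(Z) + solve(G) * lambda))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- solve(lhs, rhs)
  list(mu = sol[1], g = sol[-1])
}

test_that("BLUP equals an independent mixed-model-equation solve", {
  set.seed(101)
  g <- hwe_geno(6, 12, seed = 101)
  G <- compute_grm(g, "centered")
  G$values <- G$values + diag(1e-6, 6)  # keep the oracle's G invertible
  y <- rnorm(4)
  ref <- g$sample_ids[1:4]
  tgt <- g$sample_ids[5:6]
  vc <- list(sigma2_groups = c(all = 0.7), sigma2_e = 0.3)
  pred <- blup_predict(pheno_tbl(y, ref), list(all = G), vc, tgt)
  oracle <- mme_oracle(y, G$values, 1:4, 0.7, 0.3)
  expect_equal(pred$gebv, unname(oracle$g[5:6]), tolerance = 1e-8)
})

test_that("GRM-based BLUP equals the ridge (SNP-effect) formulation", {
  set.seed(7)
  g <- hwe_geno(30, 60, seed = 7)
  Z <- design_matrix(g, "centered")
  G <- compute_grm(g, "centered")
  ref <- 1:22; tgt <- 23:30
  sg <- 0.6; se <- 0.4
  y <- rnorm(22)
  vc <- list(sigma2_groups = c(all = sg), sigma2_e = se)
  pred <- blup_predict(pheno_tbl(y, g$sample_ids[ref]), list(all = G), vc,
                       g$sample_ids[tgt])
  # ridge on the design matrix: beta = Z_r'(sg/c Z_r Z_r' + se I)^-1 (y - mu)
  c0 <- G$denom
  Vr <- (sg / c0) * tcrossprod(Z[ref, ]) + diag(se, length(ref))
  Vi <- solve(Vr)
  mu <- sum(Vi %*% y) / sum(Vi)
  beta <- (sg / c0) * crossprod(Z[ref, ], Vi %*% (y - mu))
  expect_equal(pred$gebv, unname(drop(Z[tgt, ] %*% beta)), tolerance = 1e-8)
})

test_that("single-group MGFBLUP is identical to GBLUP", {
  dat <- small_sim(n = 200, M = 500, seed = 12)
  G <- compute_grm(dat$geno, "centered")
  y <- rnorm(150)
  ref <- dat$geno$sample_ids[1:150]
  tgt <- dat$geno$sample_ids[151:200]
  Gr <- subset_grm(G, ref)
  f1 <- reml_fit(pheno_tbl(y, ref), Gr)                 # GBLUP path
  f2 <- reml_fit(pheno_tbl(y, ref), list(only = Gr))    # list-of-1 (MGF path)
  expect_equal(unname(f1$sigma2_groups), unname(f2$sigma2_groups),
               tolerance = 1e-10)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  p1 <- blup_predict(pheno_tbl(y, ref), G, f1, tgt)
  p2 <- blup_predict(pheno_tbl(y, ref), list(only = G), f2, tgt)
  expect_equal(p1$gebv, p2$gebv, tolerance = 1e-10)
})

test_that("predictions vanish as the genetic variance goes to zero", {
  g <- hwe_geno(20, 30, seed = 3)
  G <- compute_grm(g, "centered")
  vc <- list(sigma2_groups = c(all = 0), sigma2_e = 1)
  pred <- blup_predict(pheno_tbl(rnorm(15), g$sample_ids[1:15]), G, vc,
                       g$sample_ids[16:20])
  expect_equal(pred$gebv, rep(0, 5))
})

test_that("REML estimates scale as the square of the phenotype scale", {
  dat <- small_sim(n = 300, M = 800, seed = 14)
  G <- compute_grm(dat$geno, "centered")
  y <- dat$pheno$shoulder
  f1 <- reml_fit(pheno_tbl(y, dat$geno$sample_ids), G)
  f2 <- reml_fit(pheno_tbl(3 * y, dat$geno$sample_ids), G)
  expect_equal(9 * unname(f1$sigma2_groups), unname(f2$sigma2_groups),
               tolerance = 1e-3)
  expect_equal(9 * f1$sigma2_e, f2$sigma2_e, tolerance = 1e-3)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-5)
})

test_that("an identity GRM raises the flat-likelihood flag", {
  n <- 50
  G <- new_grm_for_test(diag(n), paste0("i", 1:n))
  f <- reml_fit(pheno_tbl(rnorm(n), paste0("i", 1:n)), G)
  expect_false(f$converged)
  expect_true("flat_likelihood" %in% f$flags)
})

test_that("REML recovers h2 on a quick single-GRM simulation", {
  dat <- small_sim(n = 500, M = 1500, h2 = 0.5, seed = 15)
  G <- compute_grm(dat$geno, "centered")
  f <- reml_fit(pheno_tbl(dat$pheno$shoulder, dat$geno$sample_ids), G)
  expect_true(f$converged)
  expect_lt(abs(f$h2 - dat$truth$shoulder$true_h2_realized), 0.15)
})

test_that("more than eight GRMs is rejected", {
  g <- hwe_geno(10, 5, seed = 1)
  G <- compute_grm(g, "centered")
  expect_error(reml_fit(pheno_tbl(rnorm(10), g$sample_ids),
                        rep(list(G), 9)), "at most 8")
})

test_that("heritability partition and enrichment follow their formulas", {
  p <- partition_h2(c(a = 0.25, b = 0.75), c(a = 100, b = 100))
  expect_equal(p$pct_h2, c(25, 75))
  expect_equal(p$enrichment, c(0.5, 1.5))
  expect_equal(sum(p$pct_h2), 100)
  expect_equal(sum(p$group_prop * p$enrichment), 1)
  expect_error(partition_h2(c(a = 0, b = 0), c(a = 1, b = 1)), "zero")

  # tidy/glance round out the fitted-object interface
  dat <- small_sim(n = 120, M = 300, seed = 16)
  G <- compute_grm(dat$geno, "centered")
  f <- reml_fit(pheno_tbl(dat$pheno$shoulder, dat$geno$sample_ids), G)
  td <- tidy(f)
  expect_equal(td$component, c("g1", "residual"))
  expect_s3_class(glance(f), "tbl_df")
})
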