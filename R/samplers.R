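#' MCMC configuration
#'
#' Defaults follow common practice for these samplers on livestock data:
#' 5000 Gibbs iterations with a 2000-iteration burn-in, thinning 1, and
#' standardized genotype coding (the grouped mixture model is defined on
#' centered-and-scaled genotypes; centered coding is available as an
#' option).
#'
#' @param n_iter total iterations.
#' @param burn_in discarded iterations (must be `< n_iter`).
#' @param thin keep every `thin`-th post-burn-in sample.
#' @param seed RNG seed applied via `set.seed()` before the chain starts.
#' @param coding `"standardized"` or `"centered"` genotype coding.
#' @return a list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 5000, burn_in = 2000, thin = 1, seed = 1,
                        coding = c("standardized", "centered")) {
  coding <- match.arg(coding)
  stopifnot(burn_in < n_iter, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 coding = coding),
            class = "mcmc_config")
}

#' Effect-size mixture specification
#'
#' Non-null mixture components with variances expressed relative to the
#' group (or total) genetic variance; defaults `1e-4`, `1e-3`, `1e-2`
#' (small, medium, large effects).
#'
#' @param rel_variances strictly increasing positive reals.
#' @param prior_pi Dirichlet concentration for the mixture proportions
#'   (spike included), recycled to length `length(rel_variances) + 1`.
#' @return a list of class `mixture_spec`.
#' @export
mixture_spec <- function(rel_variances = c(1e-4, 1e-3, 1e-2), prior_pi = 1) {
  stopifnot(all(rel_variances > 0), !is.unsorted(rel_variances, strictly = TRUE))
  structure(list(rel_variances = rel_variances,
                 prior_pi = rep(prior_pi, length(rel_variances) + 1)),
            class = "mixture_spec")
}

.sampler_design <- function(pheno, geno, cfg, trait) {
  y <- .align_pheno(pheno, trait, geno$sample_ids)
  f <- allele_freq(impute_mean(geno))
  X <- design_matrix(geno, cfg$coding, freqs = f)
  list(y = y, X = X, freqs = f)
}

.new_posterior <- function(model, geno, cfg, beta_mean, pip, traces,
                           pi_est = NULL, sigma2_groups = NULL,
                           group = NULL, group_labels = NULL,
                           freqs = NULL, mu = NULL, extra = list()) {
  ids <- geno$marker_meta$marker_id
  structure(c(list(model = model,
                   beta_mean = stats::setNames(as.numeric(beta_mean), ids),
                   pip = stats::setNames(pmin(pmax(as.numeric(pip), 0), 1), ids),
                   pi_est = pi_est,
                   sigma2_groups = sigma2_groups,
                   sigma2_e = mean(traces$sigma2_e),
                   h2 = mean(traces$h2),
                   traces = traces,
                   marker_ids = ids,
                   marker_meta = geno$marker_meta,
                   group = group, group_labels = group_labels,
                   coding = cfg$coding, freqs = freqs, mu = mu,
                   config = cfg),
              extra),
            class = "gsannot_posterior")
}

#' @export
print.gsannot_posterior <- function(x, ...) {
  cat("<gsannot_posterior> model =", x$model, "|", length(x$beta_mean),
      "markers |", nrow(x$traces), "kept samples\n")
  cat("  posterior mean h2 =", round(x$h2, 4),
      "| sigma2_e =", round(x$sigma2_e, 4), "\n")
  invisible(x)
}

#' BayesCpi spike-and-slab regression
#'
#' `y = 1*mu + X beta + e` where each marker effect is null with
#' probability `pi` and `N(0, sigma2_beta)` otherwise; `pi` (uniform prior
#' via beta conjugacy), the slab variance and the residual variance are
#' estimated unless fixed. Weak scaled-inverse-chi-square priors (nu = 4)
#' are centered so that the prior genetic and residual variances split
#' `var(y)` in half.
#'
#' @param pheno data frame (`sample_id`, trait) or named numeric vector.
#' @param geno a `genotype_matrix` row-aligned with `pheno`.
#' @param cfg an [mcmc_config()].
#' @param trait trait column name.
#' @param pi_fixed,sigma2_beta,sigma2_e optionally fix a parameter instead
#'   of sampling it (mainly for closed-form validation).
#' @param sample_mu set `FALSE` to pin the intercept at 0.
#' @return a `gsannot_posterior`.
#' @export
run_bayes_cpi <- function(pheno, geno, cfg = mcmc_config(), trait = "value",
                          pi_fixed = NULL, sigma2_beta = NULL,
                          sigma2_e = NULL, sample_mu = TRUE) {
  dd <- .sampler_design(pheno, geno, cfg, trait)
  vy <- max(stats::var(dd$y), 1e-8)
  M <- ncol(dd$X)
  s0_beta <- sigma2_beta %||% (vy / (2 * max(1, 0.01 * M)))
  set.seed(cfg$seed)
  res <- cpp_bayescpi(dd$y, dd$X, cfg$n_iter, cfg$burn_in, cfg$thin,
                      4, s0_beta, vy / 2,
                      pi_fixed %||% -1, sigma2_beta %||% -1,
                      sigma2_e %||% -1, sample_mu)
  traces <- tibble::tibble(iter = seq_along(res$trace_h2),
                           mu = res$trace_mu, pi = res$trace_pi,
                           sigma2_beta = res$trace_sigma2_beta,
                           sigma2_e = res$trace_sigma2_e,
                           h2 = res$trace_h2,
                           n_included = res$trace_n_included)
  .new_posterior("bayescpi", geno, cfg, res$beta_mean, res$pip, traces,
                 pi_est = mean(res$trace_pi), freqs = dd$freqs,
                 mu = mean(res$trace_mu))
}

#' Grouped Bayesian mixture regression (BayesRR-RC) and BayesR
#'
#' `run_bayes_rr_rc` fits the grouped mixture model: within annotation
#' group s, marker effects follow a spike at zero plus Gaussian components
#' with variances `rel_variances * sigma2_s`, where `sigma2_s` (the
#' variance explained by the group) and the per-group mixture proportions
#' (Dirichlet(1) prior) are estimated. `run_bayes_r` is the same model
#' with a single group covering all markers, i.e. component variances are
#' fixed fractions (`1e-4`, `1e-3`, `1e-2`) of the genetic variance.
#'
#' @inheritParams run_bayes_cpi
#' @param anno an `annotation_map` partitioning the markers (at most 96
#'   groups). Empty groups are dropped with a warning; groups with fewer
#'   than 10 markers trigger an instability warning.
#' @param mix a [mixture_spec()].
#' @return a `gsannot_posterior`; `sigma2_groups` holds the posterior mean
#'   variance explained by each group (variance of the group's genetic
#'   values), `pi_est` the per-group mixture proportions, and the traces
#'   include per-iteration counts of medium and large effect markers.
#' @export
run_bayes_rr_rc <- function(pheno, geno, anno, mix = mixture_spec(),
                            cfg = mcmc_config(), trait = "value") {
  stopifnot(inherits(anno, "annotation_map"))
  grp <- anno$assignments$group[match(geno$marker_meta$marker_id,
                                      anno$assignments$marker_id)]
  if (anyNA(grp)) stop("annotation map does not cover all markers")
  labs_all <- attr(anno, "group_labels")
  if (length(labs_all) > 96) stop("at most 96 groups are supported")
  labs <- labs_all[labs_all %in% unique(grp)]
  if (length(labs) < length(labs_all)) {
    warning(length(labs_all) - length(labs), " empty group(s) dropped")
  }
  sizes <- table(factor(grp, levels = labs))
  if (any(sizes < 10)) {
    warning("group(s) with fewer than 10 markers: ",
            paste(names(sizes)[sizes < 10], collapse = ", "),
            " (hyperparameters may be unstable)")
  }
  gidx <- as.integer(factor(grp, levels = labs)) - 1L
  dd <- .sampler_design(pheno, geno, cfg, trait)
  vy <- max(stats::var(dd$y), 1e-8)
  S <- length(labs)
  set.seed(cfg$seed)
  res <- cpp_bayesrrrc(dd$y, dd$X, gidx, S, mix$rel_variances,
                       cfg$n_iter, cfg$burn_in, cfg$thin,
                       4, rep(vy / (2 * S), S), vy / 2)
  traces <- tibble::tibble(iter = seq_along(res$trace_h2),
                           mu = res$trace_mu,
                           sigma2_e = res$trace_sigma2_e,
                           h2 = res$trace_h2,
                           n_medium = res$trace_n_medium,
                           n_large = res$trace_n_large)
  pi_est <- res$pi_est
  dimnames(pi_est) <- list(labs, c("null", paste0("comp", seq_along(mix$rel_variances))))
  .new_posterior(if (S == 1) "bayesr" else "bayesrrrc", geno, cfg,
                 res$beta_mean, res$pip, traces,
                 pi_est = pi_est,
                 sigma2_groups = stats::setNames(as.numeric(res$var_explained), labs),
                 group = grp, group_labels = labs, freqs = dd$freqs,
                 mu = mean(res$trace_mu),
                 extra = list(sigma2_s_hyper = stats::setNames(as.numeric(res$sigma2_s), labs),
                              mixture = mix))
}

#' @rdname run_bayes_rr_rc
#' @export
run_bayes_r <- function(pheno, geno, mix = mixture_spec(),
                        cfg = mcmc_config(), trait = "value") {
  anno <- annotation_map(
    tibble::tibble(marker_id = geno$marker_meta$marker_id, group = "all"),
    "ALL", "all")
  run_bayes_rr_rc(pheno, geno, anno, mix = mix, cfg = cfg, trait = trait)
}

#' Bayesian sparse linear mixed model (BSLMM)
#'
#' All markers contribute through a polygenic term `u ~ N(0, G sigma2_poly)`
#' (the GRM of the training markers) and a sparse subset carries additional
#' effects, null with probability `1 - pi`. The chain works in the GRM
#' eigenbasis so the polygenic conditionals are independent. Variances use
#' conjugate updates; `pi` uses a random-walk Metropolis step on `log(pi)`
#' with a log-uniform prior on `[1/M, 1]`.
#'
#' @inheritParams run_bayes_cpi
#' @param grm a `grm` built from the same markers (computed from `geno`
#'   with the configured coding when `NULL`).
#' @param sparse set `FALSE` to disable the additional-effect component,
#'   which reduces the model to GBLUP.
#' @param rw_sd random-walk standard deviation for `log(pi)`.
#' @return a `gsannot_posterior`; per-marker `pip` is the posterior
#'   probability of carrying an additional effect and the traces include
#'   the per-iteration count of additional-effect markers.
#' @export
run_bslmm <- function(pheno, geno, grm = NULL, cfg = mcmc_config(),
                      trait = "value", sparse = TRUE, rw_sd = 0.3) {
  dd <- .sampler_design(pheno, geno, cfg, trait)
  grm <- grm %||% compute_grm(geno, mode = cfg$coding)
  if (!identical(grm$sample_ids, geno$sample_ids)) {
    stop("GRM individuals do not match the genotype matrix")
  }
  ed <- eigen(grm$values, symmetric = TRUE)
  d <- pmax(ed$values, 0)
  U <- ed$vectors
  yt <- drop(crossprod(U, dd$y))
  Xt <- crossprod(U, dd$X)
  onest <- drop(crossprod(U, rep(1, length(dd$y))))
  vy <- max(stats::var(dd$y), 1e-8)
  M <- ncol(dd$X)
  set.seed(cfg$seed)
  res <- cpp_bslmm(yt, Xt, d, onest, cfg$n_iter, cfg$burn_in, cfg$thin,
                   4, vy / (2 * max(1, 0.01 * M)), vy / 2, vy / 2,
                   max(10 / M, 1 / M), 1 / M, rw_sd, sparse)
  traces <- tibble::tibble(iter = seq_along(res$trace_h2),
                           pi = res$trace_pi,
                           sigma2_a = res$trace_sigma2_a,
                           sigma2_poly = res$trace_sigma2_poly,
                           sigma2_e = res$trace_sigma2_e,
                           h2 = res$trace_h2,
                           n_additional = res$trace_n_additional)
  u_mean <- drop(U %*% res$u_mean_rot)
  post <- .new_posterior("bslmm", geno, cfg, res$beta_mean, res$pip, traces,
                         pi_est = mean(res$trace_pi), freqs = dd$freqs,
                         mu = res$mu_mean,
                         extra = list(
                           sigma2_poly = mean(res$trace_sigma2_poly),
                           sigma2_a = mean(res$trace_sigma2_a),
                           u_mean = stats::setNames(u_mean, geno$sample_ids),
                           train_ids = geno$sample_ids,
                           y_adj = stats::setNames(
                             dd$y - res$mu_mean -
                               drop(dd$X %*% res$beta_mean),
                             geno$sample_ids)))
  post
}

#' Genomic values from a posterior summary
#'
#' `GEBV = Z beta_mean` (or `X beta_mean` under standardized coding), with
#' the training-set allele frequencies reused to build the target design
#' matrix. For BSLMM the conditional mean of the polygenic term is added,
#' which requires a GRM covering training plus target individuals.
#'
#' @param object a `gsannot_posterior`.
#' @param geno_target a `genotype_matrix` with exactly the training
#'   markers (same ids, same order).
#' @param grm for BSLMM: a `grm` over training + target individuals built
#'   from the training markers.
#' @return tibble `sample_id`, `gebv`.
#' @export
predict_from_posterior <- function(object, geno_target, grm = NULL) {
  stopifnot(inherits(object, "gsannot_posterior"))
  tids <- geno_target$marker_meta$marker_id
  if (!identical(tids, object$marker_ids)) {
    off <- c(setdiff(object$marker_ids, tids), setdiff(tids, object$marker_ids))
    stop("target markers do not match training markers; offenders: ",
         paste(utils::head(off, 5), collapse = ", "),
         if (length(off) > 5) paste0(" (+", length(off) - 5, " more)") else "")
  }
  X <- design_matrix(geno_target, object$coding, freqs = object$freqs)
  gebv <- unname(drop(X %*% object$beta_mean))
  if (object$model == "bslmm") {
    if (is.null(grm)) stop("BSLMM prediction requires a GRM over training + target individuals")
    ref <- object$train_ids
    tg <- geno_target$sample_ids
    ri <- match(ref, grm$sample_ids)
    ti <- match(tg, grm$sample_ids)
    if (anyNA(ri) || anyNA(ti)) stop("GRM does not cover all individuals")
    sp2 <- object$sigma2_poly
    se2 <- object$sigma2_e
    V <- sp2 * grm$values[ri, ri, drop = FALSE] + diag(se2, length(ri))
    alpha <- solve(V, object$y_adj[ref])
    gebv <- gebv + sp2 * drop(grm$values[ti, ri, drop = FALSE] %*% alpha)
  }
  tibble::tibble(sample_id = geno_target$sample_ids, gebv = gebv)
}
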