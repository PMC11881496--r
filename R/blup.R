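#' GBLUP / MGFBLUP prediction of genomic values
#'
#' Conditional mean of the target individuals' genetic values given the
#' reference phenotypes under the fitted Gaussian model: with
#' `V = sum_s sigma2_s G_s[ref, ref] + sigma2_e I` and GLS intercept
#' `mu`, the prediction is
#' `g_hat[target] = sum_s sigma2_s G_s[target, ref] V^{-1} (y - mu)`.
#' For a single GRM this is GBLUP; for several it is the sum of per-group
#' conditional means (MGFBLUP).
#'
#' @param pheno_ref data frame (`sample_id`, trait) or named numeric vector
#'   of reference phenotypes.
#' @param grms_full a `grm` or list of `grm`s over reference plus target
#'   individuals, the same GRMs used in [reml_fit()].
#' @param vc a `gsannot_reml` fit (or a list with `sigma2_groups` and
#'   `sigma2_e`).
#' @param target_ids sample ids to predict (must be disjoint from the
#'   reference ids).
#' @param trait trait column name when `pheno_ref` is a data frame.
#' @return tibble with `sample_id`, `gebv`, and one `gebv_<group>` column
#'   per GRM when more than one GRM is fitted.
#' @export
blup_predict <- function(pheno_ref, grms_full, vc, target_ids,
                         trait = "value") {
  grms_full <- .as_grm_list(grms_full)
  ids_all <- grms_full[[1]]$sample_ids
  stopifnot(all(target_ids %in% ids_all))
  ref_ids <- if (is.numeric(pheno_ref)) {
    intersect(ids_all, names(pheno_ref) %||% setdiff(ids_all, target_ids))
  } else intersect(ids_all, as.data.frame(pheno_ref)$sample_id)
  ref_ids <- setdiff(ref_ids, target_ids)
  if (!length(ref_ids)) stop("no reference individuals")
  y <- .align_pheno(pheno_ref, trait, ref_ids)
  sg <- vc$sigma2_groups
  se <- vc$sigma2_e
  if (length(sg) != length(grms_full)) {
    stop("variance components do not match the number of GRMs")
  }
  ri <- match(ref_ids, ids_all)
  ti <- match(target_ids, ids_all)
  n <- length(ri)
  V <- diag(se, n)
  for (s in seq_along(grms_full)) {
    V <- V + sg[s] * grms_full[[s]]$values[ri, ri, drop = FALSE]
  }
  ch <- tryCatch(chol(V), error = function(e) NULL)
  rc <- if (is.null(ch)) 0 else 1 / kappa(V, exact = FALSE)
  if (is.null(ch) || rc < 1e-14) {
    stop("singular coefficient matrix in BLUP solve; reciprocal condition ",
         format(rc, digits = 3))
  }
  vi1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  viy <- backsolve(ch, forwardsolve(t(ch), y))
  mu <- sum(vi1 * y) / sum(vi1)
  alpha <- viy - vi1 * mu
  out <- tibble::tibble(sample_id = target_ids, gebv = 0)
  parts <- matrix(0, length(ti), length(grms_full))
  for (s in seq_along(grms_full)) {
    parts[, s] <- sg[s] *
      drop(grms_full[[s]]$values[ti, ri, drop = FALSE] %*% alpha)
  }
  out$gebv <- rowSums(parts)
  if (length(grms_full) > 1) {
    pg <- tibble::as_tibble(as.data.frame(parts))
    names(pg) <- paste0("gebv_", names(grms_full))
    out <- dplyr::bind_cols(out, pg)
  }
  attr(out, "mu") <- mu
  out
}
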