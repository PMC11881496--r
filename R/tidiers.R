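#' Tidy REML variance components
#'
#' @param x a `gsannot_reml` fit.
#' @param ... unused.
#' @return tibble with one row per variance component (`residual` last):
#'   `component`, `sigma2`, `pct_h2` (share of the genetic variance, `NA`
#'   for the residual).
#' @method tidy gsannot_reml
#' @export
tidy.gsannot_reml <- function(x, ...) {
  sg <- x$sigma2_groups
  tibble::tibble(
    component = c(names(sg), "residual"),
    sigma2 = c(unname(sg), x$sigma2_e),
    pct_h2 = c(if (sum(sg) > 0) 100 * unname(sg) / sum(sg)
               else rep(NA_real_, length(sg)), NA_real_))
}

#' @rdname tidy.gsannot_reml
#' @method glance gsannot_reml
#' @export
glance.gsannot_reml <- function(x, ...) {
  tibble::tibble(h2 = x$h2, sigma2_e = x$sigma2_e, loglik = x$loglik,
                 converged = x$converged, n_iter = x$n_iter, n = x$n,
                 flags = paste(x$flags, collapse = ";"))
}

#' Tidy a posterior summary
#'
#' @param x a `gsannot_posterior`.
#' @param ... unused.
#' @return tibble with per-marker `marker_id`, `chrom`, `pos`,
#'   `beta_mean`, `pip` and, when the model is grouped, `group`.
#' @method tidy gsannot_posterior
#' @export
tidy.gsannot_posterior <- function(x, ...) {
  out <- dplyr::mutate(x$marker_meta[, c("marker_id", "chrom", "pos")],
                       beta_mean = unname(x$beta_mean),
                       pip = unname(x$pip))
  if (!is.null(x$group)) out$group <- x$group
  out
}

#' @rdname tidy.gsannot_posterior
#' @method glance gsannot_posterior
#' @export
glance.gsannot_posterior <- function(x, ...) {
  tibble::tibble(model = x$model, h2 = x$h2, sigma2_e = x$sigma2_e,
                 n_markers = length(x$beta_mean),
                 n_kept = nrow(x$traces),
                 mean_n_nonnull = if ("n_included" %in% names(x$traces))
                   mean(x$traces$n_included)
                 else if ("n_additional" %in% names(x$traces))
                   mean(x$traces$n_additional)
                 else mean(x$pip) * length(x$pip))
}

#' Tidy bootstrap comparison results
#'
#' @param x a `gsannot_boot`.
#' @param ... unused.
#' @return the per-method reliability CI tibble.
#' @method tidy gsannot_boot
#' @export
tidy.gsannot_boot <- function(x, ...) x$reliability

#' @rdname tidy.gsannot_boot
#' @method glance gsannot_boot
#' @export
glance.gsannot_boot <- function(x, ...) {
  tibble::tibble(n_target = x$n_target, n_boot = x$n_boot, h2 = x$h2,
                 n_methods = nrow(x$reliability),
                 n_significant_pairs = sum(x$differences$significant))
}
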