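#' Heritability partition and enrichment per annotation group
#'
#' The share of genetic variance attributed to group s (percentage of SNP
#' heritability) is `100 * sigma2_s / sum(sigma2)`, and the enrichment of a
#' group is its heritability share divided by its share of the variants:
#' `enrichment_s = (pct_h2_s / 100) / (M_s / M)`. Enrichment above 1 means
#' that variants in the group carry larger-than-average effects.
#'
#' @param vc group variances: a `gsannot_reml` fit, a `gsannot_posterior`
#'   summary, or a named numeric vector of per-group variances (any common
#'   positive scale -- e.g. already-normalized heritability percentages).
#' @param group_sizes named numeric vector of variant counts per group,
#'   aligned with the variance names (order is matched by name when both
#'   are named).
#' @return tibble with `group`, `sigma2`, `pct_h2`, `group_prop`,
#'   `enrichment`. `pct_h2` sums to 100 and
#'   `sum(group_prop * enrichment) = 1`.
#' @export
partition_h2 <- function(vc, group_sizes) {
  sigma2 <- if (inherits(vc, "gsannot_reml")) vc$sigma2_groups
            else if (inherits(vc, "gsannot_posterior")) vc$sigma2_groups
            else vc
  stopifnot(is.numeric(sigma2), length(sigma2) >= 1, all(sigma2 >= 0))
  if (sum(sigma2) <= 0) stop("all group variances are zero")
  if (!is.null(names(sigma2)) && !is.null(names(group_sizes)) &&
      all(names(sigma2) %in% names(group_sizes))) {
    group_sizes <- group_sizes[names(sigma2)]
  }
  stopifnot(length(group_sizes) == length(sigma2), all(group_sizes > 0))
  pct <- 100 * sigma2 / sum(sigma2)
  prop <- group_sizes / sum(group_sizes)
  tibble::tibble(group = names(sigma2) %||% paste0("g", seq_along(sigma2)),
                 sigma2 = unname(sigma2),
                 pct_h2 = unname(pct),
                 group_prop = unname(prop),
                 enrichment = unname((pct / 100) / prop))
}
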