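#' Reference/target split by birth date
#'
#' Forward-validation design: individuals born strictly before the cutoff
#' form the reference (training) set, those born on or after the cutoff
#' form the target (validation) set.
#'
#' @param samples data frame with `sample_id` and `birth_date` (Date or
#'   ISO string).
#' @param cutoff cutoff date.
#' @return list with `reference` and `target` character vectors of ids;
#'   errors when either side is empty.
#' @export
split_by_date <- function(samples, cutoff) {
  samples <- as.data.frame(samples)
  stopifnot(all(c("sample_id", "birth_date") %in% names(samples)))
  bd <- as.Date(samples$birth_date)
  cutoff <- as.Date(cutoff)
  ref <- samples$sample_id[bd < cutoff]
  tgt <- samples$sample_id[bd >= cutoff]
  if (!length(ref)) stop("empty reference set: all individuals born on/after cutoff")
  if (!length(tgt)) stop("empty target set: all individuals born before cutoff")
  list(reference = as.character(ref), target = as.character(tgt))
}

#' Prediction reliability
#'
#' Squared correlation between genomic estimated breeding values and
#' (pre-corrected) trait deviations, divided by the trait heritability.
#'
#' @param gebv,trait_dev aligned numeric vectors (n >= 3).
#' @param h2 trait heritability in `(0, 1]`.
#' @return numeric scalar.
#' @export
reliability <- function(gebv, trait_dev, h2) {
  stopifnot(length(gebv) == length(trait_dev), length(gebv) >= 3,
            h2 > 0, h2 <= 1)
  if (stats::sd(gebv) == 0) stop("zero-variance GEBV: reliability undefined")
  stats::cor(gebv, trait_dev)^2 / h2
}

#' Dispersion bias of genomic predictions
#'
#' Ordinary least-squares slope of trait deviations on predictions; 1
#' indicates correctly scaled (neither inflated nor deflated) predictions,
#' below 1 over-dispersed predictions.
#'
#' @param gebv,trait_dev aligned numeric vectors.
#' @return numeric scalar (the regression coefficient).
#' @export
dispersion_bias <- function(gebv, trait_dev) {
  stopifnot(length(gebv) == length(trait_dev))
  v <- stats::var(gebv)
  if (v == 0) stop("zero-variance GEBV: slope undefined")
  stats::cov(gebv, trait_dev) / v
}

#' Bootstrap comparison of prediction methods
#'
#' Resamples the target individuals with replacement; each replicate uses
#' one shared index vector across all method columns (paired design, as
#' implied by building a single individuals-by-methods GEBV table).
#' Per-method reliability confidence intervals use the 2.5th/97.5th
#' percentiles; a pairwise difference is declared significant when one
#' method is higher in at least 97.5% of the resamples.
#'
#' @param gebv_table data frame with `sample_id` and one numeric column per
#'   method (no missing cells).
#' @param trait_dev named numeric vector, or data frame with `sample_id`
#'   and `value`, of trait deviations for the same individuals.
#' @param h2 trait heritability used in the reliability denominator.
#' @param n_boot number of bootstrap resamples (>= 1000).
#' @param seed RNG seed.
#' @return object of class `gsannot_boot`: tibbles `reliability` (method,
#'   point, lower, upper) and `differences` (method_a, method_b, diff,
#'   lower, upper, prop_a_higher, significant), plus `n_target`, `n_boot`.
#' @export
bootstrap_compare <- function(gebv_table, trait_dev, h2, n_boot = 10000,
                              seed = 1) {
  stopifnot(n_boot >= 1000)
  gebv_table <- as.data.frame(gebv_table)
  stopifnot("sample_id" %in% names(gebv_table))
  methods <- setdiff(names(gebv_table), "sample_id")
  G <- as.matrix(gebv_table[, methods, drop = FALSE])
  if (anyNA(G)) stop("GEBV table contains missing cells")
  y <- if (is.data.frame(trait_dev)) {
    stats::setNames(trait_dev$value, trait_dev$sample_id)[gebv_table$sample_id]
  } else if (!is.null(names(trait_dev))) {
    trait_dev[gebv_table$sample_id]
  } else trait_dev
  if (anyNA(y)) stop("trait deviations missing for some target individuals")
  n <- nrow(G)
  point <- apply(G, 2, reliability, trait_dev = y, h2 = h2)
  set.seed(seed)
  R <- matrix(NA_real_, n_boot, length(methods),
              dimnames = list(NULL, methods))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- y[idx]
    R[b, ] <- suppressWarnings(stats::cor(G[idx, , drop = FALSE], yb))^2 / h2
  }
  rel <- tibble::tibble(method = methods,
                        point = unname(point),
                        lower = apply(R, 2, stats::quantile, 0.025, na.rm = TRUE),
                        upper = apply(R, 2, stats::quantile, 0.975, na.rm = TRUE))
  pairs <- if (length(methods) >= 2) {
    utils::combn(methods, 2, simplify = FALSE)
  } else list()
  diffs <- purrr::map_dfr(pairs, function(p) {
    dd <- R[, p[1]] - R[, p[2]]
    pa <- mean(dd > 0)
    pb <- mean(dd < 0)
    tibble::tibble(method_a = p[1], method_b = p[2],
                   diff = unname(point[p[1]] - point[p[2]]),
                   lower = stats::quantile(dd, 0.025, names = FALSE),
                   upper = stats::quantile(dd, 0.975, names = FALSE),
                   prop_a_higher = pa,
                   significant = pa >= 0.975 || pb >= 0.975)
  })
  if (!length(pairs)) {
    diffs <- tibble::tibble(method_a = character(), method_b = character(),
                            diff = numeric(), lower = numeric(),
                            upper = numeric(), prop_a_higher = numeric(),
                            significant = logical())
  }
  structure(list(reliability = rel, differences = diffs,
                 n_target = n, n_boot = n_boot, h2 = h2),
            class = "gsannot_boot")
}

#' @export
print.gsannot_boot <- function(x, ...) {
  cat("<gsannot_boot>", x$n_target, "target individuals,", x$n_boot,
      "resamples, h2 =", x$h2, "\n")
  print(x$reliability)
  invisible(x)
}

#' Cumulative-PIP regions
#'
#' Sums posterior inclusion probabilities over a fixed, non-overlapping
#' 1 Mb grid per chromosome (window k covers positions
#' `((k-1)*window, k*window]`) and reports windows whose cumulative PIP
#' exceeds the threshold -- regions carrying an (additional) effect in more
#' than half of the iterations at the default threshold of 0.5.
#'
#' @param pip_table data frame with `chrom`, `pos`, `pip` (e.g. from
#'   [tidy.gsannot_posterior()]).
#' @param window_bp grid size in bp.
#' @param threshold report windows with cumulative PIP strictly above this.
#' @return tibble `chrom`, `window_start`, `window_end`, `cumulative_pip`,
#'   `n_markers`, sorted by chromosome and window.
#' @export
pip_regions <- function(pip_table, window_bp = 1e6, threshold = 0.5) {
  d <- tibble::as_tibble(pip_table)
  stopifnot(all(c("chrom", "pos", "pip") %in% names(d)))
  d |>
    dplyr::mutate(win = floor((.data$pos - 1) / window_bp)) |>
    dplyr::group_by(.data$chrom, .data$win) |>
    dplyr::summarise(cumulative_pip = sum(.data$pip),
                     n_markers = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$cumulative_pip > threshold) |>
    dplyr::mutate(window_start = .data$win * window_bp + 1,
                  window_end = (.data$win + 1) * window_bp) |>
    dplyr::select("chrom", "window_start", "window_end",
                  "cumulative_pip", "n_markers") |>
    dplyr::arrange(.data$chrom, .data$window_start)
}

#' Overall muscular-development score
#'
#' Combines the four linear classification scores with weights 1 for
#' shoulder and top muscling and 2 for the two buttock views, normalized
#' by the weight sum so the result stays on the 0-50 score scale.
#'
#' @param shoulder,top,buttock_side,buttock_rear numeric vectors.
#' @param weights weights for the four scores.
#' @return numeric vector.
#' @export
combine_overall_score <- function(shoulder, top, buttock_side, buttock_rear,
                                  weights = c(1, 1, 2, 2)) {
  stopifnot(length(weights) == 4, sum(weights) > 0)
  (weights[1] * shoulder + weights[2] * top +
     weights[3] * buttock_side + weights[4] * buttock_rear) / sum(weights)
}
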