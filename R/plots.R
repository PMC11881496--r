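#' Plot an evaluation report
#'
#' Dot plot of reliability per trait, faceted by panel and colored by
#' model.
#'
#' @param object a `gsannot_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot gsannot_report
#' @export
autoplot.gsannot_report <- function(object, ...) {
  ggplot2::ggplot(object$reliability,
                  ggplot2::aes(x = .data$trait, y = .data$reliability,
                               colour = .data$model)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5),
                        size = 2) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = NULL, y = "Reliability") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot bootstrap reliability intervals
#'
#' Point estimates with 95% percentile intervals per method.
#'
#' @param object a `gsannot_boot`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot gsannot_boot
#' @export
autoplot.gsannot_boot <- function(object, ...) {
  ggplot2::ggplot(object$reliability,
                  ggplot2::aes(x = stats::reorder(.data$method, .data$point),
                               y = .data$point)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Reliability (95% bootstrap CI)") +
    ggplot2::theme_bw()
}

#' Plot per-marker posterior inclusion probabilities
#'
#' PIP along the genome with 1 Mb cumulative-PIP regions highlighted.
#'
#' @param object a `gsannot_posterior`.
#' @param window_bp,threshold passed to [pip_regions()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot gsannot_posterior
#' @export
autoplot.gsannot_posterior <- function(object, window_bp = 1e6,
                                       threshold = 0.5, ...) {
  d <- tidy(object)
  regions <- pip_regions(d, window_bp = window_bp, threshold = threshold)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos / 1e6, y = .data$pip)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "Posterior inclusion probability") +
    ggplot2::theme_bw()
  if (nrow(regions)) {
    p <- p + ggplot2::geom_rect(
      data = regions, inherit.aes = FALSE, alpha = 0.2, fill = "red",
      ggplot2::aes(xmin = .data$window_start / 1e6,
                   xmax = .data$window_end / 1e6, ymin = 0, ymax = 1))
  }
  p
}
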