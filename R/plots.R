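#' Plot a coverage profile
#'
#' Line plot of an [metagene_profile()] or [anchor_profile()] result
#' (RPM per bin).
#'
#' @param object an `hmc_profile`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.hmc_profile <- function(object, ...) {
  xlab <- if (attr(object, "kind") == "metagene") "bin (TSS → TTS)"
  else "distance from anchor (bp)"
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$bin_center, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = sprintf("coverage (%s)", attr(object, "units")),
                  subtitle = sprintf("%d anchors", attr(object, "n_anchors"))) +
    ggplot2::theme_minimal()
}

#' Plot per-quartile gene-body 5-hmC medians
#'
#' @param object an `hmc_quartiles` result of [quartile_trend()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.hmc_quartiles <- function(object, ...) {
  ggplot2::ggplot(object$quartiles,
                  ggplot2::aes(x = factor(.data$quartile),
                               y = .data$median_coverage)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "expression quartile (Q1 low → Q4 high)",
                  y = "median gene-body 5-hmC",
                  subtitle = sprintf("trend p = %.3g", object$trend_p)) +
    ggplot2::theme_minimal()
}

#' Bar plot of a peak annotation distribution
#'
#' @param dist output of [peak_annotation_distribution()].
#' @return A ggplot object.
#' @export
plot_annotation_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$category, y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of peaks") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
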