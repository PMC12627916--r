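# ggplot2 views of the main result types.

#' Panel evaluation plots
#'
#' Four-panel summary of a marker panel: call-frequency distribution,
#' heterozygous-proportion distribution, per-locus discriminative power and
#' allele counts per marker.
#'
#' @param summary Output of [summarize_markers()].
#' @return A ggplot object (facetted).
#' @export
plot_marker_summary <- function(summary) {
  long <- summary |>
    dplyr::select("locus_id", "call_frequency", "het_proportion",
                  "dp_locus", "n_alleles") |>
    tidyr::pivot_longer(-"locus_id", names_to = "statistic") |>
    dplyr::mutate(statistic = factor(
      .data$statistic,
      levels = c("call_frequency", "het_proportion", "dp_locus", "n_alleles"),
      labels = c("Call frequency", "Heterozygous proportion",
                 "Discriminative power", "Alleles per marker")
    ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(x = NULL, y = "Markers") +
    ggplot2::theme_minimal()
}

#' Differentiation-rate heatmap
#' @param d An `mnp_dist` from [pairwise_differentiation()].
#' @param ... Unused.
#' @return A ggplot heatmap of pairwise differentiation rates.
#' @export
autoplot.mnp_dist <- function(d, ...) {
  samples <- attr(d, "samples")
  df <- tidy(d) |>
    dplyr::mutate(sample1 = factor(.data$sample1, levels = samples),
                  sample2 = factor(.data$sample2, levels = samples))
  ggplot2::ggplot(df, ggplot2::aes(.data$sample1, .data$sample2,
                                   fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "Differentiation") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' Calibration-curve plot
#'
#' Known vs estimated copies on log10 axes with the fitted regression line
#' and the identity (slope 1) reference.
#'
#' @param object An `mnp_calibration` from [fit_calibration()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mnp_calibration <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data$known, .data$estimated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept, colour = "firebrick") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Known copies / reaction", y = "Estimated copies / reaction",
      subtitle = sprintf("slope %.3f, r² %.4f",
                         object$slope, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Detection-probability curve
#'
#' Probability of detecting at least `k_min` markers as a function of the
#' per-marker detection probability, for one or more panel sizes.
#'
#' @param k_min Minimum markers detected (default 1).
#' @param panel_sizes Panel sizes to draw (default `c(20, 50, 115)`).
#' @return A ggplot object.
#' @export
plot_detection_power <- function(k_min = 1, panel_sizes = c(20, 50, 115)) {
  grid <- tidyr::expand_grid(p = seq(0.01, 0.99, by = 0.01),
                             panel_size = panel_sizes)
  grid$prob <- detection_probability(grid$p, grid$panel_size, k_min)
  ggplot2::ggplot(grid, ggplot2::aes(.data$p, .data$prob,
                                     colour = factor(.data$panel_size))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Per-marker detection probability",
                  y = sprintf("P(detect ≥ %d markers)", k_min),
                  colour = "Panel size") +
    ggplot2::theme_minimal()
}
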