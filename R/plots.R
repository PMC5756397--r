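#' Plot an allele frequency spectrum
#'
#' @param object An [afs()] spectrum.
#' @param ... Unused.
#' @return A ggplot bar chart of bin proportions.
#' @method autoplot af_spectrum
#' @export
autoplot.af_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_lo + 0.0125,
                                       y = .data$proportion)) +
    ggplot2::geom_col(width = 0.023, fill = "steelblue") +
    ggplot2::labs(x = "alternative-allele frequency", y = "proportion of SNPs") +
    ggplot2::theme_minimal()
}

#' Expected-heterozygosity comparison plot
#'
#' Array versus reference per-population He for each filtered version, with
#' the identity line.
#'
#' @param report A `comparison_report`.
#' @return A ggplot facetted by version.
#' @export
plot_he_comparison <- function(report) {
  tab <- purrr::imap_dfr(report$versions, function(v, vname) {
    dplyr::mutate(v$he$table, version = vname)
  })
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$he_reference,
                                    y = .data$he_array)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.4) +
    ggplot2::facet_wrap(~version) +
    ggplot2::labs(x = "reference He", y = "array He") +
    ggplot2::theme_minimal()
}

#' Pairwise F_ST regression plot
#'
#' @param report A `comparison_report`.
#' @return A ggplot of array versus reference pairwise F_ST, facetted by
#'   version, with the identity line.
#' @export
plot_fst_regression <- function(report) {
  tab <- purrr::imap_dfr(report$versions, function(v, vname) {
    dplyr::mutate(v$fst$table, version = vname)
  })
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$fst_reference,
                                    y = .data$fst_array)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.5, colour = "steelblue") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.4) +
    ggplot2::facet_wrap(~version) +
    ggplot2::labs(x = "reference F_ST", y = "array F_ST") +
    ggplot2::theme_minimal()
}

#' Tree-distance baseline plot
#'
#' Replicate-versus-replicate distance distributions (boxplots) with the
#' array-versus-replicate mean overlaid, per version.
#'
#' @param report A `comparison_report`.
#' @param which One of "partition", "branch_score", "frobenius".
#' @return A ggplot.
#' @export
plot_distance_baseline <- function(report,
                                   which = c("partition", "branch_score",
                                             "frobenius")) {
  which <- match.arg(which)
  pull_block <- function(v) {
    if (which == "frobenius") v$frobenius else v$tree[[which]]
  }
  base <- purrr::imap_dfr(report$versions, function(v, vname) {
    tibble(version = vname, value = pull_block(v)$baseline_values)
  })
  means <- purrr::imap_dfr(report$versions, function(v, vname) {
    tibble(version = vname, value = pull_block(v)$mean)
  })
  ggplot2::ggplot(base, ggplot2::aes(x = .data$version, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::geom_point(data = means, colour = "blue", size = 2) +
    ggplot2::labs(x = NULL, y = which) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Comparison report overview plot
#'
#' @param object A `comparison_report`.
#' @param ... Unused.
#' @return The He comparison plot (see [plot_he_comparison()]).
#' @method autoplot comparison_report
#' @export
autoplot.comparison_report <- function(object, ...) {
  plot_he_comparison(object)
}
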