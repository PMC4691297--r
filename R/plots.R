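#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot SSR density by motif length
#'
#' Bar chart of counts per Mbp by motif length, faceted by SSR class.
#'
#' @param object An `ssr_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssr_summary <- function(object, ...) {
  ggplot2::ggplot(object$by_period,
                  ggplot2::aes(x = factor(.data$period),
                               y = .data$density_per_mbp)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~ssr_class, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "motif length (bp)", y = "SSR counts per Mbp",
                  title = object$dataset_name) +
    ggplot2::theme_minimal()
}

#' Plot the encoded amino-acid profile of SSR loci
#'
#' @param object An `ssr_aa_profile` from [amino_acid_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssr_aa_profile <- function(object, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), !.data$is_stop)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$residue, -.data$count), y = .data$count)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::facet_wrap(~ssr_class, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "amino acid", y = "occurrences in SSR loci") +
    ggplot2::theme_minimal()
}

#' Plot a comparison report
#'
#' Chi-square statistics of the comparison battery, coloured by
#' significance at the 0.01 level.
#'
#' @param object An `ssr_comparison` from [compare_datasets()].
#' @param alpha Significance threshold for colouring.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssr_comparison <- function(object, alpha = 0.01, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object),
                       .data$test == "chi_square", !is.na(.data$statistic))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$comparison, y = .data$statistic,
    fill = .data$p_value < alpha)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~ssr_class, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "heterogeneity chi-square",
                  fill = paste0("p < ", alpha)) +
    ggplot2::theme_minimal()
}
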