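#' Equal-expectation chi-square heterogeneity test
#'
#' Goodness-of-fit test for heterogeneity among k non-negative density
#' values (counts per Mbp): under the null all k cells share the common
#' expectation `e = mean(values)`, the statistic is
#' `sum((v - e)^2 / e)` with `k - 1` degrees of freedom, and the p-value is
#' the upper tail of the chi-square distribution. No continuity correction
#' is applied. Note the statistic scales linearly with the input scale
#' (`c * values` gives `c *` the statistic), as is usual when the test is
#' run directly on per-Mbp densities.
#'
#' @param values Numeric vector of k >= 2 non-negative values, not all zero.
#' @return An object of class `ssr_chisq` with elements `statistic`, `df`,
#'   `p_value` and `expected`; supports [generics::tidy()] and
#'   [generics::glance()].
#' @examples
#' chi_square_heterogeneity(c(1768.2, 1541.9))
#' @export
chi_square_heterogeneity <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least two values", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("values must be finite and non-negative", call. = FALSE)
  }
  if (all(values == 0)) stop("all values are zero", call. = FALSE)
  e <- mean(values)
  statistic <- sum((values - e)^2 / e)
  df <- length(values) - 1L
  structure(list(
    statistic = statistic,
    df = df,
    p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
    expected = e
  ), class = "ssr_chisq")
}

#' @export
print.ssr_chisq <- function(x, ...) {
  cat(sprintf("Heterogeneity chi-square: statistic = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @rdname chi_square_heterogeneity
#' @param x An `ssr_chisq` object.
#' @param ... Unused.
#' @export
tidy.ssr_chisq <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' @rdname chi_square_heterogeneity
#' @export
glance.ssr_chisq <- function(x, ...) tidy(x)

#' Welch two-sample t-test on tract lengths
#'
#' Two-sided unequal-variance (Welch) t-test comparing mean per-locus tract
#' lengths between two groups, e.g. class I SSR lengths of two species.
#'
#' @param lengths_a,lengths_b Numeric vectors (bp), each with at least two
#'   values and positive variance overall.
#' @return An object of class `ssr_ttest` with `statistic`, `df`, `p_value`,
#'   `mean_a`, `mean_b`; supports [generics::tidy()].
#' @examples
#' welch_t_test(c(21, 24, 27, 21), c(12, 14, 12, 16))
#' @export
welch_t_test <- function(lengths_a, lengths_b) {
  if (length(lengths_a) < 2L || length(lengths_b) < 2L) {
    stop("each group needs at least two values", call. = FALSE)
  }
  if (stats::var(lengths_a) + stats::var(lengths_b) == 0) {
    stop("zero variance in both groups", call. = FALSE)
  }
  tt <- stats::t.test(lengths_a, lengths_b, var.equal = FALSE)
  structure(list(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_a = mean(lengths_a),
    mean_b = mean(lengths_b)
  ), class = "ssr_ttest")
}

#' @export
print.ssr_ttest <- function(x, ...) {
  cat(sprintf(
    "Welch t-test: t = %.4g, df = %.2f, p = %.4g (means %.2f vs %.2f)\n",
    x$statistic, x$df, x$p_value, x$mean_a, x$mean_b))
  invisible(x)
}

#' @rdname welch_t_test
#' @param x An `ssr_ttest` object.
#' @param ... Unused.
#' @export
tidy.ssr_ttest <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 mean_a = x$mean_a, mean_b = x$mean_b)
}

density_of <- function(summary, ssr_class) {
  d <- summary$headline$density_per_mbp[summary$headline$ssr_class == ssr_class]
  if (length(d) == 0L) 0 else d
}

period_density_of <- function(summary, ssr_class, period) {
  tab <- summary$by_period
  d <- tab$density_per_mbp[tab$ssr_class == ssr_class & tab$period == period]
  if (length(d) == 0L) 0 else d
}

richness_density_of <- function(summary, ssr_class, kind) {
  tab <- summary$richness
  d <- tab$density_per_mbp[tab$ssr_class == ssr_class & tab$richness == kind]
  if (length(d) == 0L) 0 else d
}

nt_density_of <- function(summary, ssr_class, bases) {
  tab <- summary$nt_differential
  sum(tab$density_per_mbp[tab$ssr_class == ssr_class &
                            tab$nucleotide %in% bases])
}

chisq_row <- function(comparison, ssr_class, a, b) {
  res <- tryCatch(chi_square_heterogeneity(c(a, b)), error = function(e) NULL)
  tibble::tibble(
    comparison = comparison, ssr_class = ssr_class, test = "chi_square",
    value_a = a, value_b = b,
    statistic = if (is.null(res)) NA_real_ else res$statistic,
    df = if (is.null(res)) NA_real_ else as.numeric(res$df),
    p_value = if (is.null(res)) NA_real_ else res$p_value
  )
}

#' Compare the SSR content of two datasets
#'
#' Runs the standard battery of comparisons between two summarised datasets,
#' per SSR class: between-dataset density heterogeneity, within-dataset
#' trimer-vs-hexamer heterogeneity, AT-rich vs GC-rich heterogeneity,
#' (A+T) vs (G+C) differential nucleotide heterogeneity, and the Welch
#' t-test on per-locus tract lengths. Chi-square rows on degenerate inputs
#' (both values zero) carry `NA` statistics.
#'
#' @param summary_a,summary_b `ssr_summary` objects computed with the same
#'   thresholds and monomer flag.
#' @return A tibble (class `ssr_comparison`) with columns `comparison`,
#'   `ssr_class`, `test`, `value_a`, `value_b`, `statistic`, `df`,
#'   `p_value`.
#' @export
compare_datasets <- function(summary_a, summary_b) {
  stopifnot(inherits(summary_a, "ssr_summary"),
            inherits(summary_b, "ssr_summary"))
  if (summary_a$include_monomers != summary_b$include_monomers) {
    stop("summaries computed with different monomer flags", call. = FALSE)
  }
  rows <- list()
  for (cls in c("I", "II")) {
    rows <- c(rows, list(
      chisq_row("between_dataset_density", cls,
                density_of(summary_a, cls), density_of(summary_b, cls)),
      chisq_row(paste0("trimer_vs_hexamer_", summary_a$dataset_name), cls,
                period_density_of(summary_a, cls, 3L),
                period_density_of(summary_a, cls, 6L)),
      chisq_row(paste0("trimer_vs_hexamer_", summary_b$dataset_name), cls,
                period_density_of(summary_b, cls, 3L),
                period_density_of(summary_b, cls, 6L)),
      chisq_row(paste0("at_rich_vs_gc_rich_", summary_a$dataset_name), cls,
                richness_density_of(summary_a, cls, "AT_RICH"),
                richness_density_of(summary_a, cls, "GC_RICH")),
      chisq_row(paste0("at_rich_vs_gc_rich_", summary_b$dataset_name), cls,
                richness_density_of(summary_b, cls, "AT_RICH"),
                richness_density_of(summary_b, cls, "GC_RICH")),
      chisq_row(paste0("at_vs_gc_nucleotides_", summary_a$dataset_name), cls,
                nt_density_of(summary_a, cls, c("A", "T")),
                nt_density_of(summary_a, cls, c("G", "C"))),
      chisq_row(paste0("at_vs_gc_nucleotides_", summary_b$dataset_name), cls,
                nt_density_of(summary_b, cls, c("A", "T")),
                nt_density_of(summary_b, cls, c("G", "C")))
    ))
    la <- summary_a$tract_lengths[[cls]]
    lb <- summary_b$tract_lengths[[cls]]
    tt <- if (!is.null(la) && !is.null(lb) && length(la) >= 2L &&
              length(lb) >= 2L && stats::var(la) + stats::var(lb) > 0) {
      welch_t_test(la, lb)
    } else NULL
    rows <- c(rows, list(tibble::tibble(
      comparison = "tract_length_between_dataset", ssr_class = cls,
      test = "welch_t",
      value_a = if (length(la)) mean(la) else NA_real_,
      value_b = if (length(lb)) mean(lb) else NA_real_,
      statistic = if (is.null(tt)) NA_real_ else tt$statistic,
      df = if (is.null(tt)) NA_real_ else tt$df,
      p_value = if (is.null(tt)) NA_real_ else tt$p_value
    )))
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("ssr_comparison", class(out)))
}
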