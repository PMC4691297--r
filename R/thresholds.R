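#' Minimum repeat-count thresholds for an SSR class
#'
#' Returns the per-motif-length minimum number of whole repeat units a
#' perfect tandem repeat must reach to qualify for an SSR class. The defaults
#' are the standard settings for genic SSR surveys: class I (long,
#' marker-grade repeats, nominally >= 20 bp of tract) uses
#' monomer 20, dimer 10, trimer 7, tetramer 5, pentamer 4, hexamer 4,
#' heptamer 3, octamer 3, nonamer 3, decamer 2; class II (short repeats,
#' nominally 12-19 bp) uses monomer 12, dimer 6, trimer 4, tetramer 3,
#' pentamer 3, hexamer 2, heptamer 2, octamer 2, nonamer 2, and does not
#' search decamers at all. A motif length absent from a class's table is not
#' searched for that class. The repeat-count tables, not the nominal bp
#' ranges, are authoritative: e.g. two octamer units (16 bp) are class II
#' while three (24 bp) are class I, so no octamer tract can sit at 20 bp.
#'
#' @param ssr_class `"I"` or `"II"`.
#' @param min_repeats Optional named replacement: an integer vector whose
#'   names are motif lengths (`"1"` to `"10"`), e.g. `c("2" = 8, "3" = 5)`.
#'   All values must be >= 2.
#' @return A tibble with columns `ssr_class`, `period` and `min_repeats`.
#' @examples
#' ssr_thresholds("I")
#' ssr_thresholds("II")
#' @export
ssr_thresholds <- function(ssr_class = c("I", "II"), min_repeats = NULL) {
  ssr_class <- match.arg(ssr_class)
  if (is.null(min_repeats)) {
    min_repeats <- switch(ssr_class,
      I  = c(`1` = 20L, `2` = 10L, `3` = 7L, `4` = 5L, `5` = 4L,
             `6` = 4L, `7` = 3L, `8` = 3L, `9` = 3L, `10` = 2L),
      II = c(`1` = 12L, `2` = 6L, `3` = 4L, `4` = 3L, `5` = 3L,
             `6` = 2L, `7` = 2L, `8` = 2L, `9` = 2L)
    )
  }
  if (is.null(names(min_repeats)) || any(!nzchar(names(min_repeats)))) {
    stop("min_repeats must be named by motif length", call. = FALSE)
  }
  period <- as.integer(names(min_repeats))
  if (any(is.na(period)) || any(period < 1L) || any(period > 10L)) {
    stop("motif lengths must be integers in 1..10", call. = FALSE)
  }
  if (any(min_repeats < 2L)) {
    stop("all minimum repeat counts must be >= 2", call. = FALSE)
  }
  tibble::tibble(
    ssr_class = ssr_class,
    period = period,
    min_repeats = as.integer(min_repeats)
  ) |> dplyr::arrange(.data$period)
}
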