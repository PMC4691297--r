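#' Smallest period of a string
#'
#' The smallest `p` such that `s` is a whole-number repetition of its first
#' `p` characters; `p` always divides `nchar(s)`. A motif is *primitive* when
#' its smallest period equals its length.
#'
#' @param s Non-empty character string(s) over `{A,C,G,T}` (vectorised).
#' @return Integer vector of smallest periods.
#' @examples
#' smallest_period("ATAT") # 2
#' smallest_period("ATC")  # 3
#' @export
smallest_period <- function(s) {
  vapply(s, function(x) {
    n <- nchar(x)
    if (n == 0L) stop("empty string has no period", call. = FALSE)
    if (grepl("[^ACGT]", x)) {
      stop("non-ACGT character in ", x, call. = FALSE)
    }
    for (p in seq_len(n - 1L)) {
      if (n %% p == 0L &&
          x == strrep(substr(x, 1L, p), n %/% p)) {
        return(p)
      }
    }
    n
  }, integer(1), USE.NAMES = FALSE)
}

#' Find maximal perfect tandem-repeat runs in one sequence
#'
#' Scans an uppercase nucleotide string for every maximal perfect repeat run
#' with primitive motif length (period) in `k_range` and at least two whole
#' repeat units. A run of period `k` is anchored at the leftmost position of
#' a maximal stretch where each base equals the base `k` positions ahead;
#' the reported extent keeps whole units only (a trailing partial unit
#' neither counts toward `repeats` nor extends the tract). Any non-ACGT
#' character (assembly `N`s, IUPAC codes) breaks the run: no motif containing
#' one is ever reported. Each physical tract appears once, at its smallest
#' period.
#'
#' @param sequence Uppercase nucleotide string.
#' @param k_range Integer vector of motif lengths to search, within 1..10.
#' @return Tibble with columns `start` (0-based), `end` (0-based half-open),
#'   `motif` (first repeat unit as it appears), `period`, `repeats`,
#'   `length_bp`, ordered by ascending `start` then `period`.
#' @examples
#' find_maximal_runs(paste0("CGT", strrep("AT", 20), "CGT"), 1:10)
#' @export
find_maximal_runs <- function(sequence, k_range = 1:10) {
  stopifnot(length(sequence) == 1L)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1L) || any(k_range > 10L)) {
    stop("k_range must lie within 1..10", call. = FALSE)
  }
  runs <- scan_runs_cpp(sequence, k_range)
  runs_to_tibble(runs, sequence)
}

runs_to_tibble <- function(runs, sequences) {
  if (length(runs$start) == 0L) {
    return(tibble::tibble(
      seq_index = integer(), start = integer(), end = integer(),
      motif = character(), period = integer(), repeats = integer(),
      length_bp = integer()
    ))
  }
  out <- tibble::tibble(
    seq_index = runs$seq_index,
    start = runs$start,
    end = runs$start + runs$period * runs$repeats,
    motif = substr(sequences[runs$seq_index], runs$start + 1L,
                   runs$start + runs$period),
    period = runs$period,
    repeats = runs$repeats,
    length_bp = runs$period * runs$repeats
  )
  dplyr::arrange(out, .data$seq_index, .data$start, .data$period)
}

classify_repeats <- function(period, repeats, class1, class2) {
  min1 <- class1$min_repeats[match(period, class1$period)]
  min2 <- class2$min_repeats[match(period, class2$period)]
  out <- rep(NA_character_, length(period))
  out[!is.na(min2) & repeats >= min2] <- "II"
  out[!is.na(min1) & repeats >= min1] <- "I"   # class I takes precedence
  out
}

#' Detect classified SSR loci in CDS records
#'
#' Runs the maximal-run scanner over every record and classifies each run:
#' class I if its whole-unit repeat count meets the class I minimum for its
#' motif length, otherwise class II if it meets the class II minimum,
#' otherwise dropped. Class I takes precedence, so the two class locus sets
#' are disjoint and each physical tract appears at most once. Canonical
#' motifs (rotation + reverse-complement equivalence) and AT/GC richness are
#' filled in for every locus.
#'
#' @param records Tibble of CDS records from [read_cds_fasta()] (columns
#'   `seq_id`, `sequence`), or a single tibble row.
#' @param class1,class2 Threshold tibbles from [ssr_thresholds()].
#' @return Tibble of loci with columns `seq_id`, `start` (0-based), `end`
#'   (half-open), `motif`, `period`, `repeats`, `length_bp`, `ssr_class`,
#'   `canonical_motif`, `richness`.
#' @examples
#' rec <- tibble::tibble(seq_id = "g1",
#'                       sequence = paste0("CTT", strrep("AGC", 6), "TTC"))
#' detect_ssrs(rec)
#' @export
detect_ssrs <- function(records,
                        class1 = ssr_thresholds("I"),
                        class2 = ssr_thresholds("II")) {
  stopifnot(is.data.frame(records))
  k_range <- sort(unique(c(class1$period, class2$period)))
  if (nrow(records) == 0L) return(empty_loci())
  runs <- scan_runs_cpp(records$sequence, as.integer(k_range))
  runs <- runs_to_tibble(runs, records$sequence)
  if (nrow(runs) == 0L) return(empty_loci())
  loci <- runs |>
    dplyr::mutate(
      seq_id = records$seq_id[.data$seq_index],
      ssr_class = classify_repeats(.data$period, .data$repeats,
                                   class1, class2)
    ) |>
    dplyr::filter(!is.na(.data$ssr_class))
  if (nrow(loci) == 0L) return(empty_loci())
  motifs <- unique(loci$motif)
  canon <- canonical_motif(motifs)
  rich <- richness(canon)
  idx <- match(loci$motif, motifs)
  loci |>
    dplyr::mutate(
      canonical_motif = canon[idx],
      richness = rich[idx]
    ) |>
    dplyr::select("seq_id", "start", "end", "motif", "period", "repeats",
                  "length_bp", "ssr_class", "canonical_motif", "richness")
}

empty_loci <- function() {
  tibble::tibble(
    seq_id = character(), start = integer(), end = integer(),
    motif = character(), period = integer(), repeats = integer(),
    length_bp = integer(), ssr_class = character(),
    canonical_motif = character(), richness = character()
  )
}
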