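#' Canonical representative of a motif class
#'
#' Motifs that are circular permutations (rotations) of one another, or of
#' each other's reverse complements, describe the same repeat and are
#' clustered into one canonical class (e.g. AC = GT = CA = TG). The
#' representative is the lexicographically smallest member under the base
#' order A < C < G < T, so e.g. every member of the AC class maps to "AC" and
#' every member of the AAC class (AAC, ACA, CAA, TTG, TGT, GTT) to "AAC".
#' The map is idempotent and constant on each class.
#'
#' @param motif Character vector of motifs over `{A,C,G,T}`.
#' @return Character vector of canonical motifs, same length as `motif`.
#' @examples
#' canonical_motif(c("TG", "GTT", "A"))
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    if (!nzchar(m)) stop("empty motif", call. = FALSE)
    if (grepl("[^ACGT]", m)) {
      stop("non-ACGT character in motif ", m, call. = FALSE)
    }
    min(c(rotations(m), rotations(revcomp(m))))
  }, character(1), USE.NAMES = FALSE)
}

rotations <- function(m) {
  k <- nchar(m)
  if (k == 1L) return(m)
  d <- strrep(m, 2L)
  substring(d, seq_len(k), seq_len(k) + k - 1L)
}

revcomp <- function(m) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(m, NULL), function(x) paste(rev(x), collapse = ""),
                character(1)))
}

#' AT/GC richness of a motif
#'
#' Classifies one motif copy by base composition: `AT_RICH` when A+T bases
#' outnumber G+C, `GC_RICH` for the reverse, `BALANCED` on ties (e.g. ACGT).
#' Balanced motifs form a genuine third category and belong to neither the
#' AT-rich nor the GC-rich tally. Richness is invariant under rotation and
#' reverse complement, so it is a property of the canonical class.
#'
#' @param motif Character vector of motifs over `{A,C,G,T}`.
#' @return Character vector with values `"AT_RICH"`, `"GC_RICH"`,
#'   `"BALANCED"`.
#' @examples
#' richness(c("AAT", "ACG", "ACGT"))
#' @export
richness <- function(motif) {
  at <- nchar(gsub("[^AT]", "", motif))
  gc <- nchar(gsub("[^GC]", "", motif))
  if (any(at + gc != nchar(motif))) {
    stop("non-ACGT character in motif", call. = FALSE)
  }
  dplyr::case_when(at > gc ~ "AT_RICH", gc > at ~ "GC_RICH",
                   .default = "BALANCED")
}

#' Nucleotide counts of one motif copy
#'
#' Letter counts of a single copy of each motif; rows sum to the motif
#' length. Aggregated over loci (one copy per locus) these give the
#' differential nucleotide counts used in composition tables.
#'
#' @param motif Character vector of motifs over `{A,C,G,T}`.
#' @return Tibble with columns `motif`, `A`, `C`, `G`, `T`.
#' @examples
#' motif_nucleotide_counts(c("AAG", "ACGT"))
#' @export
motif_nucleotide_counts <- function(motif) {
  if (any(grepl("[^ACGT]", motif))) {
    stop("non-ACGT character in motif", call. = FALSE)
  }
  cnt <- function(b) nchar(motif) - nchar(gsub(b, "", motif, fixed = TRUE))
  tibble::tibble(motif = motif, A = cnt("A"), C = cnt("C"),
                 G = cnt("G"), T = cnt("T"))
}

#' Enumerate canonical classes of primitive motifs
#'
#' All canonical classes of primitive motifs of length `k` (useful for
#' exhaustive checks: there are 2 for k = 1, 4 for k = 2, 10 for k = 3).
#'
#' @param k Motif length (1..6 is practical).
#' @return Character vector of canonical motifs, sorted.
#' @export
canonical_classes <- function(k) {
  stopifnot(k >= 1, k <= 8)
  all_motifs <- do.call(
    paste0,
    expand.grid(rep(list(c("A", "C", "G", "T")), k),
                stringsAsFactors = FALSE)
  )
  primitive <- all_motifs[smallest_period(all_motifs) == k]
  sort(unique(canonical_motif(primitive)))
}
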