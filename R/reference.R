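#' Reference genic SSR densities for two conifer gene catalogs
#'
#' Per-Mbp SSR densities reported by a published comparative survey of
#' perfect SSRs in the high-confidence full-length CDS catalogs of Norway
#' spruce (*Picea abies*, 26,437 gene models) and loblolly pine
#' (*Pinus taeda*, 34,059 gene models), by SSR class and motif length
#' (monomer = 1 ... decamer = 10; class II decamers were not searched).
#' These values serve as realistic inputs for the comparison battery and as
#' targets for consistency checks; the underlying gene catalogs themselves
#' are not redistributed here.
#'
#' @return A tibble with columns `species`, `ssr_class`, `period`,
#'   `density_per_mbp`.
#' @seealso [ssr_reference_headline()], [ssr_reference_nucleotides()]
#' @export
ssr_reference_densities <- function() {
  tibble::tibble(
    species = rep(c("Picea_abies", "Pinus_taeda"), each = 20L),
    ssr_class = rep(rep(c("I", "II"), each = 10L), 2L),
    period = rep(1:10, 4L),
    density_per_mbp = c(
      # Picea abies class I, monomer..decamer
      0.0, 0.0, 36.4, 0.0, 0.7, 11.5, 0.5, 0.0, 1.1, 4.5,
      # Picea abies class II
      8.6, 11.9, 409.6, 43.5, 6.4, 1088.0, 120.0, 39.5, 49.2, 0.0,
      # Pinus taeda class I
      6.2, 7.9, 11.4, 0.9, 2.1, 11.1, 0.8, 0.4, 0.4, 7.7,
      # Pinus taeda class II
      39.7, 29.0, 231.3, 70.0, 13.6, 959.8, 143.9, 48.2, 46.1, 0.0
    )
  )
}

#' Reference headline SSR figures for the two conifer gene catalogs
#'
#' Headline per-class figures from the same published survey as
#' [ssr_reference_densities()]: number of gene models analysed, genes
#' carrying SSRs, mean (population SD) tract length in bp, and the headline
#' SSR density per Mbp. Headline densities exclude mononucleotide runs.
#'
#' @return A tibble with columns `species`, `n_genes`, `ssr_class`,
#'   `n_genes_with_ssr`, `mean_length_bp`, `sd_length_bp`,
#'   `density_per_mbp`.
#' @export
ssr_reference_headline <- function() {
  tibble::tibble(
    species = rep(c("Picea_abies", "Pinus_taeda"), each = 2L),
    n_genes = rep(c(26437L, 34059L), each = 2L),
    ssr_class = rep(c("I", "II"), 2L),
    n_genes_with_ssr = c(240L, 11380L, 337L, 14967L),
    mean_length_bp = c(23.7, 12.7, 22.7, 12.7),
    sd_length_bp = c(4.6, 1.6, 4.1, 1.6),
    density_per_mbp = c(54.7, 1768.2, 42.7, 1541.9)
  )
}

#' Reference nucleotide and richness densities for the conifer catalogs
#'
#' Differential per-Mbp counts of nucleotides in repeat motifs (one motif
#' copy per locus) and the AT-rich / GC-rich motif densities, from the same
#' published survey as [ssr_reference_densities()].
#'
#' @return A tibble with columns `species`, `ssr_class`, `measure` (one of
#'   `AT_RICH`, `GC_RICH`, `A`, `T`, `G`, `C`) and `density_per_mbp`.
#' @export
ssr_reference_nucleotides <- function() {
  tibble::tibble(
    species = rep(c("Picea_abies", "Pinus_taeda"), each = 12L),
    ssr_class = rep(rep(c("I", "II"), 12L)),
    measure = rep(rep(c("AT_RICH", "GC_RICH", "A", "T", "G", "C"), each = 2L), 2L),
    density_per_mbp = c(
      # Picea abies: class I / class II pairs
      12.8, 791.2,   37.5, 542.6,
      75.3, 3002.1,  28.7, 2158.9,
      79.2, 2581.9,  57.0, 1842.6,
      # Pinus taeda
      20.8, 818.6,   14.3, 366.0,
      72.2, 2717.0,  51.9, 2354.1,
      52.4, 2134.0,  44.6, 1493.8
    )
  )
}
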