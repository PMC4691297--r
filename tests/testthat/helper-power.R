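# Two synthetic 1-Mbp CDS catalogs with planted class II loci at the
# published 1768:1542 per-Mbp density contrast (roughly 70% hexamer, 30%
# trimer, mirroring the dominant class II motif lengths); returns the two
# detected non-monomer class II densities.
two_catalog_class2_densities <- function(seed, n_a = 1768L, n_b = 1542L) {
  one <- function(n_loci, sd) {
    n_hex <- round(0.7 * n_loci)
    plants <- tibble::tibble(
      motif = c("AACGGT", "AGC"),
      repeats = c(2L, 4L),
      n = c(n_hex, n_loci - n_hex)
    )
    ds <- generate_dataset(n_genes = 1000L, gene_length = 1000L, gc = 0.45,
                           plants = plants, seed = sd)
    loci <- detect_ssrs(ds$records)
    mbp <- total_length_bp(ds$records) / 1e6
    sum(loci$ssr_class == "II" & loci$period > 1) / mbp
  }
  c(one(n_a, 2L * seed), one(n_b, 2L * seed + 1L))
}
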