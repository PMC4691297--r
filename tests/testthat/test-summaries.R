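test_that("counts_per_mbp normalises by dataset length", {
  expect_equal(counts_per_mbp(0, 1e6), 0)
  expect_equal(counts_per_mbp(55, 1e6), 55)
  expect_equal(counts_per_mbp(240, 4.39e6), 240 / 4.39, tolerance = 1e-12)
  expect_error(counts_per_mbp(1, 0), "positive")
})

test_that("gene-level tallies distinguish genes from loci", {
  # one gene with one class I and one class II locus, one with two class II
  g1 <- paste0("CTT", strrep("AGC", 7), "TTCGA", strrep("AACGGT", 2), "TCT")
  g2 <- paste0("CTT", strrep("AGT", 4), "TTCGA", strrep("ACCTGT", 2), "TCT")
  recs <- records_of(g1 = g1, g2 = g2)
  loci <- detect_ssrs(recs)
  smry <- summarize_dataset(recs, loci, dataset_name = "toy")
  h <- smry$headline
  expect_equal(h$n_genes_with_ssr[h$ssr_class == "I"], 1L)
  expect_equal(h$n_loci[h$ssr_class == "I"], 1L)
  expect_equal(h$n_genes_with_ssr[h$ssr_class == "II"], 2L)
  expect_equal(h$n_loci[h$ssr_class == "II"], 3L)
  expect_equal(smry$n_genes_with_both_classes, 1L)
  expect_error(summarize_dataset(recs[1, ], loci), "unknown seq_id")
})

test_that("summary densities equal planted counts over planted Mbp", {
  plants <- tibble::tibble(
    motif = c("AT", "AGC", "AACGGT", "C"),
    repeats = c(10L, 6L, 4L, 14L),
    n = c(12L, 20L, 8L, 5L)
  )
  ds <- generate_dataset(n_genes = 125, gene_length = 800, gc = 0.45,
                         plants = plants, seed = 31)
  expect_equal(total_length_bp(ds$records), 1e5)
  loci <- detect_ssrs(ds$records)
  smry <- summarize_dataset(ds$records, loci, dataset_name = "sim")
  mbp <- 0.1
  bp <- smry$by_period
  expect_equal(bp$n[bp$ssr_class == "I" & bp$period == 2], 12L)   # (AT)10
  expect_equal(bp$density_per_mbp[bp$ssr_class == "I" & bp$period == 2],
               12 / mbp)
  expect_equal(bp$n[bp$ssr_class == "II" & bp$period == 3], 20L)  # (AGC)6
  expect_equal(bp$n[bp$ssr_class == "I" & bp$period == 6], 8L)    # (AACGGT)4
  expect_equal(bp$n[bp$ssr_class == "II" & bp$period == 1], 5L)   # (C)14

  # headline excludes the monomer row unless the flag is set
  h <- smry$headline
  expect_equal(h$n_loci[h$ssr_class == "II"], 20L)
  sum_by_period <- sum(bp$density_per_mbp[bp$ssr_class == "II" & bp$period > 1])
  expect_equal(h$density_per_mbp[h$ssr_class == "II"], sum_by_period)
  smry_m <- summarize_dataset(ds$records, loci, include_monomers = TRUE)
  hm <- smry_m$headline
  expect_equal(hm$n_loci[hm$ssr_class == "II"], 25L)
  expect_equal(hm$density_per_mbp[hm$ssr_class == "II"],
               sum(bp$density_per_mbp[bp$ssr_class == "II"]))

  # richness partition sums to the class total
  rich <- smry$richness
  for (cls in c("I", "II")) {
    expect_equal(sum(rich$density_per_mbp[rich$ssr_class == cls]),
                 h$density_per_mbp[h$ssr_class == cls])
  }

  # nucleotide differential conservation: counts sum to the summed periods
  core <- loci[loci$period > 1, ]
  for (cls in c("I", "II")) {
    nt <- smry$nt_differential
    expect_equal(sum(nt$count[nt$ssr_class == cls]),
                 sum(core$period[core$ssr_class == cls]))
  }

  # population SD of tract lengths
  len2 <- core$length_bp[core$ssr_class == "II"]
  expect_equal(h$sd_length_bp[h$ssr_class == "II"],
               sqrt(mean((len2 - mean(len2))^2)))
})

test_that("canonical density tables aggregate rotations and order by density", {
  # plant mixed members of the AGG class plus a distinct ACG-class motif
  plants <- tibble::tibble(motif = c("AGG", "GGA", "CCT", "ACG"),
                           repeats = 5L, n = c(4L, 3L, 3L, 5L))
  ds <- generate_dataset(n_genes = 40, gene_length = 500, plants = plants,
                         seed = 9)
  loci <- detect_ssrs(ds$records)
  tab <- canonical_density_table(loci, total_length_bp(ds$records), 3)
  expect_equal(tab$canonical_motif, c("AGG", "ACG"))
  expect_equal(tab$n, c(10L, 5L))
  expect_equal(tab$density_per_mbp, c(10, 5) / (2e4 / 1e6))
  expect_equal(nrow(canonical_density_table(loci, 1e6, 4)), 0L)
})

test_that("amino-acid profiles translate in-frame codons inside tracts", {
  # (GAA)7 at a codon boundary: Glu x 7
  rec <- records_of(g1 = paste0(strrep("GAA", 7), "TGGCCTACT"))
  prof <- amino_acid_profile(rec, detect_ssrs(rec))
  expect_equal(prof$residue, "E")
  expect_equal(prof$count, 7L)

  # same tract shifted off-frame: only the 6 fully contained codons count
  rec <- records_of(g1 = paste0("CT", strrep("GAA", 7), "TGGCCTA"))
  loci <- detect_ssrs(rec)
  expect_equal(loci$start, 2L)
  prof <- amino_acid_profile(rec, loci)
  expect_equal(prof$residue, "K")   # AAG in frame 0 from position 3
  expect_equal(prof$count, 6L)

  # (AACGGT)4 in frame: Asn and Gly x 4 each
  rec <- records_of(g1 = paste0(strrep("AACGGT", 4), "TCATCG"))
  prof <- amino_acid_profile(rec, detect_ssrs(rec))
  expect_equal(sort(prof$residue), c("G", "N"))
  expect_equal(prof$count, c(4L, 4L))

  # stop codons are tallied separately from amino acids
  rec <- records_of(g1 = paste0(strrep("TAA", 7), "GGCCTG"))
  prof <- amino_acid_profile(rec, detect_ssrs(rec))
  expect_equal(prof$residue, "*")
  expect_true(all(prof$is_stop))

  # a locus containing no full in-frame codon contributes nothing
  rec <- records_of(g1 = paste0("C", strrep("TG", 2), "AACCTAG"))
  loci <- detect_ssrs(rec, class2 = ssr_thresholds("II", c(`2` = 2L)))
  expect_equal(loci$start, 1L)   # tract spans 1..5: no codon fits inside
  prof <- amino_acid_profile(rec, loci)
  expect_equal(nrow(prof), 0L)

  # total codons never exceed floor(tract_length / 3) summed over loci
  ds <- generate_dataset(n_genes = 30, gene_length = 400, seed = 12,
                         plants = tibble::tibble(motif = c("AT", "AGCT"),
                                                 repeats = c(10L, 5L),
                                                 n = c(10L, 10L)))
  loci <- detect_ssrs(ds$records)
  prof <- amino_acid_profile(ds$records, loci)
  expect_lte(sum(prof$count), sum(loci$length_bp %/% 3))
})

test_that("tidy and glance return the headline in tabular form", {
  ds <- generate_dataset(n_genes = 10, gene_length = 300, seed = 4,
                         plants = tibble::tibble(motif = "AG", repeats = 10L,
                                                 n = 3L))
  smry <- summarize_dataset(ds$records, detect_ssrs(ds$records),
                            dataset_name = "ds")
  td <- tidy(smry)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$dataset_name[1], "ds")
  gl <- glance(smry)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$total_bp, 3000)
})
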