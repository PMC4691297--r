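test_that("heterogeneity chi-square follows the equal-expectation formula", {
  res <- chi_square_heterogeneity(c(7, 7))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 1L)

  # hand-computed: e = 15, (5^2 + 0 + 5^2)/15
  res <- chi_square_heterogeneity(c(10, 15, 20))
  expect_equal(res$statistic, 50 / 15)
  expect_equal(res$df, 2L)
  expect_equal(res$p_value, stats::pchisq(50 / 15, 2, lower.tail = FALSE))

  expect_error(chi_square_heterogeneity(c(0, 0)), "zero")
  expect_error(chi_square_heterogeneity(5), "two values")
  expect_error(chi_square_heterogeneity(c(-1, 2)), "non-negative")
})

test_that("chi-square statistic matches stats::chisq.test and scales linearly", {
  set.seed(8)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    v <- stats::runif(k, 1, 500)
    ours <- chi_square_heterogeneity(v)
    ref <- suppressWarnings(stats::chisq.test(v))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    # scaling identity: statistic is linear in the measurement scale
    c0 <- stats::runif(1, 0.1, 10)
    expect_equal(chi_square_heterogeneity(c0 * v)$statistic,
                 c0 * ours$statistic, tolerance = 1e-9)
  }
})

test_that("p-values decrease monotonically in the statistic at fixed df", {
  stats_seq <- vapply(seq(0.5, 30, by = 0.5), function(s) {
    stats::pchisq(s, 1, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(diff(stats_seq) < 0))
  p <- vapply(list(c(100, 110), c(100, 130), c(100, 180)), function(v) {
    chi_square_heterogeneity(v)$p_value
  }, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("Welch t-test matches the closed-form computation", {
  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  a <- c(21, 24, 27, 30)
  b <- c(12, 14, 16)
  res <- welch_t_test(a, b)
  se <- sqrt(stats::var(a) / 4 + stats::var(b) / 3)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((stats::var(a) / 4)^2 / 3 + (stats::var(b) / 3)^2 / 2)
  expect_equal(res$statistic, t_hand)
  expect_equal(res$df, df_hand)
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_hand), df_hand))
  expect_equal(res$mean_a, mean(a))
  expect_error(welch_t_test(1, c(1, 2)), "at least two")
  expect_error(welch_t_test(c(2, 2), c(2, 2)), "zero variance")
})

test_that("the t-test detects the documented tract-length contrast in most replicates", {
  # groups drawn at the reference class I means/SDs and sample sizes
  set.seed(19)
  rejections <- vapply(1:50, function(i) {
    a <- stats::rnorm(240, 23.7, 4.6)
    b <- stats::rnorm(337, 22.7, 4.1)
    welch_t_test(a, b)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.5)
})

test_that("compare_datasets runs the full battery and matches direct calls", {
  plants_a <- tibble::tibble(motif = c("AGC", "AACGGT", "AT"),
                             repeats = c(6L, 2L, 10L), n = c(30L, 50L, 6L))
  plants_b <- tibble::tibble(motif = c("AGC", "AACGGT", "AT"),
                             repeats = c(6L, 2L, 10L), n = c(15L, 40L, 6L))
  da <- generate_dataset(n_genes = 120, gene_length = 900, plants = plants_a,
                         seed = 21)
  db <- generate_dataset(n_genes = 120, gene_length = 900, plants = plants_b,
                         seed = 22)
  sa <- summarize_dataset(da$records, detect_ssrs(da$records), dataset_name = "A")
  sb <- summarize_dataset(db$records, detect_ssrs(db$records), dataset_name = "B")
  cmp <- compare_datasets(sa, sb)

  dens_row <- cmp[cmp$comparison == "between_dataset_density" &
                    cmp$ssr_class == "II", ]
  direct <- chi_square_heterogeneity(c(
    sa$headline$density_per_mbp[sa$headline$ssr_class == "II"],
    sb$headline$density_per_mbp[sb$headline$ssr_class == "II"]))
  expect_equal(dens_row$statistic, direct$statistic)
  expect_equal(dens_row$p_value, direct$p_value)

  th_row <- cmp[cmp$comparison == "trimer_vs_hexamer_A" &
                  cmp$ssr_class == "II", ]
  bpA <- sa$by_period
  direct <- chi_square_heterogeneity(c(
    bpA$density_per_mbp[bpA$ssr_class == "II" & bpA$period == 3],
    bpA$density_per_mbp[bpA$ssr_class == "II" & bpA$period == 6]))
  expect_equal(th_row$statistic, direct$statistic)

  tt_row <- cmp[cmp$comparison == "tract_length_between_dataset" &
                  cmp$ssr_class == "II", ]
  direct <- welch_t_test(sa$tract_lengths[["II"]], sb$tract_lengths[["II"]])
  expect_equal(tt_row$statistic, direct$statistic)

  # a dataset built so every compared pair is equal (trimer = hexamer
  # density, AT-rich = GC-rich, A+T = G+C) yields all-zero statistics
  plants_eq <- tibble::tibble(motif = c("ACT", "ACG", "AACGGT"),
                              repeats = c(6L, 6L, 2L), n = c(20L, 20L, 40L))
  de <- generate_dataset(n_genes = 120, gene_length = 900, plants = plants_eq,
                         seed = 23)
  se <- summarize_dataset(de$records, detect_ssrs(de$records),
                          dataset_name = "E")
  cmp0 <- compare_datasets(se, se)
  chis <- cmp0$statistic[cmp0$test == "chi_square"]
  expect_true(all(is.na(chis) | abs(chis) < 1e-9))
  t0 <- cmp0[cmp0$test == "welch_t" & cmp0$ssr_class == "II", ]
  expect_equal(t0$statistic, 0)

  expect_error(
    compare_datasets(sa, summarize_dataset(db$records,
                                           detect_ssrs(db$records),
                                           include_monomers = TRUE)),
    "monomer")
})

test_that("published class II nucleotide totals reproduce the reported heterogeneity", {
  nt <- ssr_reference_nucleotides()
  pick <- function(sp, cls, m) {
    nt$density_per_mbp[nt$species == sp & nt$ssr_class == cls &
                         nt$measure %in% m]
  }
  at <- sum(pick("Picea_abies", "II", c("A", "T")))
  gc <- sum(pick("Picea_abies", "II", c("G", "C")))
  res <- chi_square_heterogeneity(c(at, gc))
  expect_equal(res$statistic, 56.5, tolerance = 0.01)
})
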