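#' Write loci to TSV
#'
#' Tab-separated locus table with 0-based half-open coordinates (columns
#' `seq_id`, `start0`, `end0`, `motif`, `period`, `repeats`, `length_bp`,
#' `ssr_class`, `canonical_motif`, `richness`).
#'
#' @param loci Loci tibble from [detect_ssrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci_tsv <- function(loci, path) {
  out <- dplyr::rename(loci, start0 = "start", end0 = "end")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write loci to GFF3
#'
#' One `microsatellite` feature per locus with 1-based inclusive
#' coordinates and `motif`, `repeats`, `ssr_class`, `canonical_motif`
#' attributes. Requires the `rtracklayer` package.
#'
#' @inheritParams write_loci_tsv
#' @return `path`, invisibly.
#' @export
write_loci_gff3 <- function(loci, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("GFF3 output requires the rtracklayer package", call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = loci$seq_id,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    type = "microsatellite",
    motif = loci$motif,
    repeats = loci$repeats,
    ssr_class = loci$ssr_class,
    canonical_motif = loci$canonical_motif
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

summary_as_list <- function(x) {
  list(
    dataset_name = x$dataset_name,
    n_genes = x$n_genes,
    total_bp = x$total_bp,
    include_monomers = x$include_monomers,
    n_genes_with_both_classes = x$n_genes_with_both_classes,
    headline = x$headline,
    counts_per_mbp_by_period = x$by_period,
    counts_per_mbp_by_canonical = x$by_canonical,
    richness_density = x$richness,
    nt_differential_density = x$nt_differential,
    aa_tally = as.data.frame(x$aa_profile)
  )
}

#' Write an `ssr_summary` as a single JSON document
#'
#' Full precision; table fields serialise as arrays of row objects.
#'
#' @param summary An `ssr_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(summary_as_list(summary), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

# densities printed at one decimal in TSV reports; counts stay integer
fmt_density <- function(x) sprintf("%.1f", x)

write_report_tsv <- function(tab, path) {
  tab <- dplyr::mutate(tab, dplyr::across(
    dplyr::any_of(c("density_per_mbp", "value_a", "value_b")), fmt_density))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the per-dataset report tables as TSV files
#'
#' Emits `headline.tsv`, `by_period.tsv`, `by_canonical.tsv`,
#' `richness.tsv`, `nt_differential.tsv` and `aa_profile.tsv` into a
#' directory, densities formatted at one decimal.
#'
#' @param summary An `ssr_summary`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_summary_tables <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_report_tsv(summary$headline, file.path(dir, "headline.tsv"))
  write_report_tsv(summary$by_period, file.path(dir, "by_period.tsv"))
  write_report_tsv(summary$by_canonical, file.path(dir, "by_canonical.tsv"))
  write_report_tsv(summary$richness, file.path(dir, "richness.tsv"))
  write_report_tsv(summary$nt_differential,
                   file.path(dir, "nt_differential.tsv"))
  utils::write.table(summary$aa_profile, file.path(dir, "aa_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

echo_config <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(out_dir, "run_config.yaml"))
}

thresholds_to_named <- function(tab) {
  stats::setNames(as.list(tab$min_repeats), as.character(tab$period))
}

#' Detect SSRs in a FASTA file and write locus reports
#'
#' Pipeline entry point wrapping [read_cds_fasta()] and [detect_ssrs()]:
#' writes `loci.tsv` (and optionally `loci.gff3`) plus an echo of the
#' resolved configuration (`run_config.yaml`) into `out_dir`. Output is
#' deterministic: re-running overwrites identically.
#'
#' @param input Path to a CDS FASTA file.
#' @param out_dir Output directory.
#' @param class1,class2 Threshold tibbles from [ssr_thresholds()].
#' @param classes Which SSR classes to keep (default both).
#' @param formats Output formats, subset of `c("tsv", "gff3")`.
#' @return The loci tibble, invisibly.
#' @export
run_detect <- function(input, out_dir,
                       class1 = ssr_thresholds("I"),
                       class2 = ssr_thresholds("II"),
                       classes = c("I", "II"),
                       formats = "tsv") {
  classes <- match.arg(classes, c("I", "II"), several.ok = TRUE)
  formats <- match.arg(formats, c("tsv", "gff3"), several.ok = TRUE)
  records <- read_cds_fasta(input)
  loci <- detect_ssrs(records, class1, class2)
  loci <- dplyr::filter(loci, .data$ssr_class %in% classes)
  echo_config(list(
    command = "detect", input = normalizePath(input),
    class1_thresholds = thresholds_to_named(class1),
    class2_thresholds = thresholds_to_named(class2),
    classes = classes, formats = formats
  ), out_dir)
  if ("tsv" %in% formats) write_loci_tsv(loci, file.path(out_dir, "loci.tsv"))
  if ("gff3" %in% formats) {
    write_loci_gff3(loci, file.path(out_dir, "loci.gff3"))
  }
  invisible(loci)
}

#' Summarise a FASTA file's SSR content and write report tables
#'
#' Wraps [detect_ssrs()] and [summarize_dataset()]; writes `summary.json`,
#' the per-dataset TSV tables and a configuration echo into `out_dir`.
#'
#' @inheritParams run_detect
#' @param include_monomers Include mononucleotide loci in headline tallies.
#' @param dataset_name Label for the dataset (defaults to the file name).
#' @return The `ssr_summary`, invisibly.
#' @export
run_summarize <- function(input, out_dir,
                          class1 = ssr_thresholds("I"),
                          class2 = ssr_thresholds("II"),
                          include_monomers = FALSE,
                          dataset_name = NULL) {
  records <- read_cds_fasta(input)
  loci <- detect_ssrs(records, class1, class2)
  smry <- summarize_dataset(
    records, loci, include_monomers = include_monomers,
    dataset_name = dataset_name %||% basename(input))
  echo_config(list(
    command = "summarize", input = normalizePath(input),
    class1_thresholds = thresholds_to_named(class1),
    class2_thresholds = thresholds_to_named(class2),
    include_monomers = include_monomers, dataset_name = smry$dataset_name
  ), out_dir)
  write_summary_json(smry, file.path(out_dir, "summary.json"))
  write_summary_tables(smry, file.path(out_dir, "tables"))
  invisible(smry)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Compare two FASTA datasets (or raw density values) and write a report
#'
#' In file mode, summarises both inputs and runs the full
#' [compare_datasets()] battery. In values mode (`values` given, no FASTA
#' needed), runs a single equal-expectation heterogeneity chi-square on the
#' supplied densities — convenient for feeding published per-Mbp tables
#' directly. Writes `comparison.tsv` and a configuration echo.
#'
#' @param input_a,input_b Paths to two CDS FASTA files (file mode).
#' @param values Numeric vector of densities (values mode).
#' @param out_dir Output directory.
#' @param include_monomers Passed to [summarize_dataset()] in file mode.
#' @param class1,class2 Threshold tibbles.
#' @return The comparison tibble, invisibly.
#' @export
run_compare <- function(input_a = NULL, input_b = NULL, values = NULL,
                        out_dir,
                        include_monomers = FALSE,
                        class1 = ssr_thresholds("I"),
                        class2 = ssr_thresholds("II")) {
  if (!is.null(values)) {
    res <- chi_square_heterogeneity(values)
    out <- tibble::tibble(
      comparison = "values_heterogeneity", ssr_class = NA_character_,
      test = "chi_square", value_a = values[1],
      value_b = if (length(values) == 2L) values[2] else NA_real_,
      statistic = res$statistic, df = as.numeric(res$df),
      p_value = res$p_value
    )
    echo_config(list(command = "compare", values = as.numeric(values)),
                out_dir)
  } else {
    if (is.null(input_a) || is.null(input_b)) {
      stop("need input_a and input_b, or values", call. = FALSE)
    }
    sa <- run_summarize(input_a, file.path(out_dir, "a"),
                        class1 = class1, class2 = class2,
                        include_monomers = include_monomers)
    sb <- run_summarize(input_b, file.path(out_dir, "b"),
                        class1 = class1, class2 = class2,
                        include_monomers = include_monomers)
    out <- compare_datasets(sa, sb)
    echo_config(list(
      command = "compare", input_a = normalizePath(input_a),
      input_b = normalizePath(input_b),
      include_monomers = include_monomers
    ), out_dir)
  }
  write_report_tsv(out, file.path(out_dir, "comparison.tsv"))
  invisible(out)
}

#' Simulate a CDS dataset and write FASTA plus truth TSV
#'
#' Wraps [generate_dataset()]; writes `simulated.fasta`, `truth.tsv` and a
#' configuration echo into `out_dir`. Identical configuration and seed give
#' byte-identical outputs.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed (required).
#' @inheritParams generate_dataset
#' @return The `list(records, truth)` from [generate_dataset()], invisibly.
#' @export
run_simulate <- function(out_dir, seed, n_genes = 100L,
                         gene_length = c(600L, 1500L), gc = 0.5,
                         plants = NULL, codon_aligned = FALSE) {
  ds <- generate_dataset(n_genes = n_genes, gene_length = gene_length,
                         gc = gc, plants = plants,
                         codon_aligned = codon_aligned, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cds_fasta(ds$records, file.path(out_dir, "simulated.fasta"))
  utils::write.table(ds$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  echo_config(list(
    command = "simulate", seed = as.integer(seed),
    n_genes = as.integer(n_genes), gene_length = as.integer(gene_length),
    gc = gc, codon_aligned = codon_aligned,
    plants = if (is.null(plants)) list() else as.data.frame(plants)
  ), out_dir)
  invisible(ds)
}
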