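#' Counts per megabase pair
#'
#' SSR density: a count divided by the total analysed sequence length in
#' Mbp. The denominator is the whole dataset length, not only
#' SSR-containing genes.
#'
#' @param n Count (vectorised).
#' @param total_bp Total sequence length in bp; must be > 0.
#' @return Numeric density per Mbp.
#' @examples
#' counts_per_mbp(55, 1e6)
#' @export
counts_per_mbp <- function(n, total_bp) {
  if (length(total_bp) != 1L || !is.finite(total_bp) || total_bp <= 0) {
    stop("total_bp must be a single positive number", call. = FALSE)
  }
  n / (total_bp / 1e6)
}

#' Summarise a CDS dataset's SSR content
#'
#' Aggregates detected loci into the standard per-dataset report: gene-level
#' tallies, per-Mbp densities by motif length and canonical class, AT/GC
#' richness partition, differential nucleotide counts (one motif copy per
#' locus) and the encoded amino-acid profile. A gene is counted once per
#' class no matter how many loci it carries; `n_genes_with_both_classes`
#' counts genes carrying at least one locus of each class.
#'
#' Mononucleotide runs are always present in the by-period density table,
#' but are excluded from every other tally (headline totals, gene counts,
#' canonical/richness/nucleotide/amino-acid tables) unless
#' `include_monomers = TRUE`. Short mononucleotide tracts are hard to assay
#' and inflated by sequencing error, so comparative surveys conventionally
#' report them only as a density row.
#'
#' @param records Tibble of CDS records.
#' @param loci Tibble of loci from [detect_ssrs()] run on `records`.
#' @param include_monomers Logical; include mononucleotide loci in headline
#'   and composition tallies (default `FALSE`).
#' @param dataset_name Label carried into reports.
#' @return An object of class `ssr_summary`: a list with elements
#'   `dataset_name`, `n_genes`, `total_bp`, `include_monomers`, `headline`
#'   (per-class tibble: `n_genes_with_ssr`, `n_loci`, `mean_length_bp`,
#'   `sd_length_bp`, `density_per_mbp`), `by_period`, `by_canonical`,
#'   `richness`, `nt_differential`, `aa_profile`,
#'   `n_genes_with_both_classes` and `tract_lengths` (per-class list of
#'   per-locus bp lengths, for length comparisons).
#' @export
summarize_dataset <- function(records, loci, include_monomers = FALSE,
                              dataset_name = "dataset") {
  unknown <- setdiff(loci$seq_id, records$seq_id)
  if (length(unknown) > 0L) {
    stop("loci reference unknown seq_id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  total_bp <- total_length_bp(records)
  by_period <- loci |>
    dplyr::count(.data$ssr_class, .data$period, name = "n") |>
    dplyr::mutate(density_per_mbp = counts_per_mbp(.data$n, total_bp)) |>
    dplyr::arrange(.data$ssr_class, .data$period)

  core <- if (include_monomers) loci else
    dplyr::filter(loci, .data$period > 1L)

  headline <- core |>
    dplyr::group_by(.data$ssr_class) |>
    dplyr::summarise(
      n_genes_with_ssr = dplyr::n_distinct(.data$seq_id),
      n_loci = dplyr::n(),
      mean_length_bp = mean(.data$length_bp),
      sd_length_bp = sd_pop(.data$length_bp),
      density_per_mbp = counts_per_mbp(dplyr::n(), total_bp),
      .groups = "drop"
    )

  by_canonical <- core |>
    dplyr::count(.data$ssr_class, .data$period, .data$canonical_motif,
                 name = "n") |>
    dplyr::mutate(density_per_mbp = counts_per_mbp(.data$n, total_bp)) |>
    dplyr::arrange(.data$ssr_class, .data$period,
                   dplyr::desc(.data$density_per_mbp))

  richness_tab <- core |>
    dplyr::count(.data$ssr_class, .data$richness, name = "n") |>
    dplyr::mutate(density_per_mbp = counts_per_mbp(.data$n, total_bp))

  nt_differential <- nt_differential_table(core, total_bp)

  genes_by_class <- split(core$seq_id, core$ssr_class)
  both <- length(intersect(genes_by_class[["I"]], genes_by_class[["II"]]))

  structure(list(
    dataset_name = dataset_name,
    n_genes = nrow(records),
    total_bp = total_bp,
    include_monomers = include_monomers,
    headline = headline,
    by_period = by_period,
    by_canonical = by_canonical,
    richness = richness_tab,
    nt_differential = nt_differential,
    aa_profile = amino_acid_profile(records, core),
    n_genes_with_both_classes = both,
    tract_lengths = lapply(split(core$length_bp, core$ssr_class), as.numeric)
  ), class = "ssr_summary")
}

# population standard deviation (denominator n)
sd_pop <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

nt_differential_table <- function(loci, total_bp) {
  if (nrow(loci) == 0L) {
    return(tibble::tibble(ssr_class = character(), nucleotide = character(),
                          count = integer(), density_per_mbp = numeric()))
  }
  loci |>
    dplyr::mutate(motif_nucleotide_counts(.data$motif)[, c("A", "C", "G", "T")]) |>
    dplyr::group_by(.data$ssr_class) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(c("A", "C", "G", "T")), sum),
                     .groups = "drop") |>
    tidyr::pivot_longer(dplyr::all_of(c("A", "C", "G", "T")),
                        names_to = "nucleotide", values_to = "count") |>
    dplyr::mutate(density_per_mbp = counts_per_mbp(.data$count, total_bp))
}

#' Per-Mbp densities of canonical motif classes at one motif length
#'
#' @param loci Tibble of loci.
#' @param total_bp Total dataset length in bp.
#' @param period Motif length to tabulate (1..10).
#' @param descending Sort by decreasing density (default) or by motif.
#' @return Tibble `canonical_motif`, `n`, `density_per_mbp`; canonical
#'   classes with no loci are omitted.
#' @export
canonical_density_table <- function(loci, total_bp, period,
                                    descending = TRUE) {
  stopifnot(period %in% 1:10)
  out <- loci |>
    dplyr::filter(.data$period == !!period) |>
    dplyr::count(.data$canonical_motif, name = "n") |>
    dplyr::mutate(density_per_mbp = counts_per_mbp(.data$n, total_bp))
  if (descending) {
    dplyr::arrange(out, dplyr::desc(.data$density_per_mbp),
                   .data$canonical_motif)
  } else {
    dplyr::arrange(out, .data$canonical_motif)
  }
}

#' Amino acids encoded by SSR tracts
#'
#' Translates, for each locus, the codons that lie entirely inside the
#' repeat tract, in the gene's reading frame (CDS are assumed to begin in
#' frame 0 at position 0), and tallies residue occurrences per SSR class.
#' Stop codons are tallied under residue `"*"` with `is_stop = TRUE`, kept
#' separate from the amino-acid tally. Loci spanning less than one in-frame
#' codon contribute nothing.
#'
#' @param records Tibble of CDS records.
#' @param loci Tibble of loci belonging to `records`.
#' @return A tibble (class `ssr_aa_profile`) with columns `ssr_class`,
#'   `residue` (single-letter code), `is_stop`, `count`.
#' @examples
#' rec <- tibble::tibble(seq_id = "g1",
#'                       sequence = paste0(strrep("GAA", 7), "TGGTAA"))
#' amino_acid_profile(rec, detect_ssrs(rec))
#' @export
amino_acid_profile <- function(records, loci) {
  empty <- tibble::tibble(ssr_class = character(), residue = character(),
                          is_stop = logical(), count = integer())
  if (nrow(loci) == 0L) {
    return(structure(empty, class = c("ssr_aa_profile", class(empty))))
  }
  seqs <- records$sequence[match(loci$seq_id, records$seq_id)]
  code <- Biostrings::GENETIC_CODE
  res <- purrr::pmap(
    list(seqs, loci$start, loci$end, loci$ssr_class),
    function(seq, start, end, cls) {
      q0 <- start + (3L - start %% 3L) %% 3L      # first in-frame codon start
      qmax <- (end %/% 3L) * 3L - 3L              # last in-frame codon start
      if (qmax < q0) return(NULL)
      codons <- substring(seq, seq(q0 + 1L, qmax + 1L, by = 3L),
                          seq(q0 + 3L, qmax + 3L, by = 3L))
      tibble::tibble(ssr_class = cls, residue = unname(code[codons]))
    }
  )
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    return(structure(empty, class = c("ssr_aa_profile", class(empty))))
  }
  out <- out |>
    dplyr::filter(!is.na(.data$residue)) |>
    dplyr::count(.data$ssr_class, .data$residue, name = "count") |>
    dplyr::mutate(is_stop = .data$residue == "*") |>
    dplyr::select("ssr_class", "residue", "is_stop", "count") |>
    dplyr::arrange(.data$ssr_class, dplyr::desc(.data$count))
  structure(out, class = c("ssr_aa_profile", class(out)))
}

#' @export
print.ssr_summary <- function(x, ...) {
  cat("SSR summary:", x$dataset_name, "\n")
  cat(sprintf("  %d genes, %s bp total (%.3f Mbp)\n", x$n_genes,
              format(x$total_bp, big.mark = ","), x$total_bp / 1e6))
  cat(sprintf("  monomers %s in headline tallies\n",
              if (x$include_monomers) "included" else "excluded"))
  print(x$headline)
  cat(sprintf("  genes with both classes: %d\n", x$n_genes_with_both_classes))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname summarize_dataset
#' @param x An `ssr_summary` object.
#' @param ... Unused.
#' @export
tidy.ssr_summary <- function(x, ...) {
  dplyr::mutate(x$headline, dataset_name = x$dataset_name, .before = 1L)
}

#' @rdname summarize_dataset
#' @export
glance.ssr_summary <- function(x, ...) {
  wide <- x$headline |>
    dplyr::select("ssr_class", "n_loci", "density_per_mbp") |>
    tidyr::pivot_wider(names_from = "ssr_class",
                       values_from = c("n_loci", "density_per_mbp"))
  dplyr::bind_cols(
    tibble::tibble(dataset_name = x$dataset_name, n_genes = x$n_genes,
                   total_bp = x$total_bp),
    wide
  )
}
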