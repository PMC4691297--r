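BASES <- c("A", "C", "G", "T")

base_probs <- function(gc) {
  if (!is.numeric(gc) || gc < 0 || gc > 1) {
    stop("gc must be a fraction in [0, 1]", call. = FALSE)
  }
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

# fast classified scan of one raw string (start/end/period/repeats/class
# only, no canonicalization) — the generator rescans genes many times
scan_string <- function(s, class1, class2) {
  k_range <- sort(unique(c(class1$period, class2$period)))
  runs <- scan_runs_cpp(s, as.integer(k_range))
  cls <- classify_repeats(runs$period, runs$repeats, class1, class2)
  keep <- which(!is.na(cls))
  list(
    start = runs$start[keep],
    end = runs$start[keep] + runs$period[keep] * runs$repeats[keep],
    period = runs$period[keep],
    repeats = runs$repeats[keep],
    ssr_class = cls[keep]
  )
}

#' Generate SSR-free background sequence
#'
#' Draws an i.i.d. nucleotide string with expected GC content `gc`, then
#' locally rejection-resamples any window where the detector still finds a
#' locus under either threshold table, until the string is SSR-free. The
#' result is deterministic given the seed.
#'
#' @param length Length in bp.
#' @param gc GC fraction in `[0, 1]`; skewed compositions make SSR-free
#'   strings rare, and configurations the repair budget cannot clean raise
#'   an error after bounded retries instead of returning a repeat-bearing
#'   string.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @param class1,class2 Threshold tibbles defining what counts as a locus.
#' @param max_retries Repair iterations before giving up.
#' @return A character string of length `length`.
#' @examples
#' bg <- generate_background(200, gc = 0.5, seed = 1)
#' nrow(detect_ssrs(tibble::tibble(seq_id = "bg", sequence = bg)))
#' @export
generate_background <- function(length, gc = 0.5, seed = NULL,
                                class1 = ssr_thresholds("I"),
                                class2 = ssr_thresholds("II"),
                                max_retries = 50L) {
  if (!is.null(seed)) set.seed(seed)
  p <- base_probs(gc)
  if (length == 0L) return("")
  chars <- sample(BASES, length, replace = TRUE, prob = p)
  chars <- repair_background(chars, planted = integer(), gc = gc,
                             class1 = class1, class2 = class2,
                             max_retries = max_retries)
  paste(chars, collapse = "")
}

# Resample every locus window that is not protected (1-based positions in
# `planted`) until the detector finds nothing unexpected. Returns the char
# vector; errors when the configuration cannot be made SSR-free.
repair_background <- function(chars, planted, gc, class1, class2,
                              max_retries = 50L, truth = NULL) {
  p <- base_probs(gc)
  for (i in seq_len(max_retries)) {
    loci <- scan_string(paste(chars, collapse = ""), class1, class2)
    if (!is.null(truth) && length(loci$start) > 0L) {
      keep <- !(paste(loci$start, loci$end, loci$period) %in%
                  paste(truth$start, truth$end, truth$period))
      loci <- lapply(loci, `[`, keep)
    }
    if (length(loci$start) == 0L) return(chars)
    # widen each offending window by one period so partial extensions and
    # junction effects are resampled too
    pos <- unique(unlist(Map(function(s, e, k) {
      seq(max(1L, s + 1L - k), min(length(chars), e + k))
    }, loci$start, loci$end, loci$period)))
    pos <- setdiff(pos, planted)
    if (length(pos) == 0L) {
      stop("cannot make background SSR-free: locus inside protected region",
           call. = FALSE)
    }
    chars[pos] <- sample(BASES, length(pos), replace = TRUE, prob = p)
  }
  stop("background not SSR-free after ", max_retries,
       " repair passes (gc = ", gc, ", length = ", length(chars), ")",
       call. = FALSE)
}

#' Plant a perfect SSR tract into a sequence
#'
#' Splices `motif` repeated `repeat_count` times into `sequence` at
#' `position` (0-based), overwriting the bases there, and mutates the two
#' guard bases immediately flanking the tract when they would extend the
#' repeat period, so the planted tract is exactly the maximal run the
#' detector should report. The caller is responsible for re-checking that
#' the surrounding sequence did not acquire secondary loci
#' ([generate_dataset()] does this automatically).
#'
#' @param sequence Character string.
#' @param motif Primitive motif over `{A,C,G,T}`.
#' @param repeat_count Whole repeat units (>= 2).
#' @param position 0-based start; the tract plus one-base guards must fit
#'   inside the sequence.
#' @param class1,class2 Threshold tibbles used to record the intended class.
#' @return A list with `sequence` (modified string) and `truth` (one-row
#'   tibble: `start`, `end`, `motif`, `period`, `repeats`,
#'   `intended_class`).
#' @export
plant_ssr <- function(sequence, motif, repeat_count, position,
                      class1 = ssr_thresholds("I"),
                      class2 = ssr_thresholds("II")) {
  k <- nchar(motif)
  if (smallest_period(motif) != k) {
    stop("motif ", motif, " is not primitive", call. = FALSE)
  }
  if (repeat_count < 2L) stop("repeat_count must be >= 2", call. = FALSE)
  L <- nchar(sequence)
  tract_len <- k * repeat_count
  if (position < 1L || position + tract_len + 1L > L) {
    stop("tract plus one-base guards does not fit at position ", position,
         call. = FALSE)
  }
  chars <- strsplit(sequence, NULL)[[1]]
  res <- plant_into_chars(chars, motif, repeat_count, position)
  cls <- classify_repeats(k, repeat_count, class1, class2)
  if (is.na(cls)) {
    stop("planted repeat (", motif, ")", repeat_count,
         " reaches neither SSR class", call. = FALSE)
  }
  list(
    sequence = paste(res, collapse = ""),
    truth = tibble::tibble(
      start = as.integer(position), end = as.integer(position + tract_len),
      motif = motif, period = as.integer(k),
      repeats = as.integer(repeat_count), intended_class = cls
    )
  )
}

# position is 0-based; chars is a character vector. Guards: the base before
# the tract must differ from the last motif base (else the run anchor moves
# left) and the base after must differ from the first motif base (else a
# partial unit extends the run).
plant_into_chars <- function(chars, motif, repeat_count, position) {
  k <- nchar(motif)
  unit <- strsplit(motif, NULL)[[1]]
  tract_len <- k * repeat_count
  idx <- (position + 1L):(position + tract_len)
  chars[idx] <- rep(unit, repeat_count)
  left <- position                 # 1-based index of base before tract
  if (left >= 1L && chars[left] == unit[k]) {
    chars[left] <- sample(setdiff(BASES, unit[k]), 1L)
  }
  right <- position + tract_len + 1L
  if (right <= length(chars) && chars[right] == unit[1L]) {
    chars[right] <- sample(setdiff(BASES, unit[1L]), 1L)
  }
  chars
}

#' Generate a synthetic CDS dataset with planted, ground-truthed SSRs
#'
#' Builds `n_genes` gene-sized CDS records of i.i.d. background at the
#' requested GC content, plants the instructed perfect SSR tracts at
#' randomised non-overlapping positions with guard bases, and locally
#' resamples the background until the planted truth is exactly the set of
#' loci the detector reports — so on every generated dataset, planted truth
#' and detected loci agree with precision = recall = 1 by construction.
#'
#' @param n_genes Number of gene records.
#' @param gene_length Integer vector of length 1 (fixed) or 2 (uniform
#'   min/max) gene length in bp.
#' @param gc Background GC fraction.
#' @param plants Plant instructions: a tibble/data.frame with columns
#'   `motif`, `repeats`, `n` (how many tracts of that kind to plant), or
#'   `NULL` for an SSR-free dataset. Tracts are spread over genes uniformly.
#' @param codon_aligned Place tracts at positions divisible by 3 so frame-0
#'   translation starts at a codon boundary.
#' @param seed Integer seed; fully determines the output.
#' @param class1,class2 Threshold tibbles.
#' @param id_prefix Prefix for generated `seq_id`s.
#' @return A list with `records` (tibble: `seq_id`, `sequence`, `length`)
#'   and `truth` (tibble: `seq_id`, `start`, `end`, `motif`, `period`,
#'   `repeats`, `intended_class`).
#' @examples
#' ds <- generate_dataset(n_genes = 20, gene_length = 300, seed = 1,
#'                        plants = tibble::tibble(motif = "AGC",
#'                                                repeats = 6, n = 5))
#' nrow(ds$truth)
#' @export
generate_dataset <- function(n_genes,
                             gene_length = c(600L, 1500L),
                             gc = 0.5,
                             plants = NULL,
                             codon_aligned = FALSE,
                             seed,
                             class1 = ssr_thresholds("I"),
                             class2 = ssr_thresholds("II"),
                             id_prefix = "gene") {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  stopifnot(n_genes >= 1L)
  gene_length <- as.integer(gene_length)
  lens <- if (length(gene_length) == 1L) {
    rep(gene_length, n_genes)
  } else {
    sample(gene_length[1]:gene_length[2], n_genes, replace = TRUE)
  }
  if (codon_aligned) lens <- lens - lens %% 3L

  plant_list <- expand_plants(plants, n_genes, lens, class1, class2)

  seqs <- character(n_genes)
  truths <- vector("list", n_genes)
  ids <- sprintf("%s%04d", id_prefix, seq_len(n_genes))
  for (g in seq_len(n_genes)) {
    gene <- build_gene(lens[g], gc, plant_list[[g]], codon_aligned,
                       class1, class2)
    seqs[g] <- gene$sequence
    if (nrow(gene$truth) > 0L) {
      truths[[g]] <- cbind(seq_id = ids[g], gene$truth)
    }
  }
  truth <- dplyr::bind_rows(truths)
  if (nrow(truth) == 0L) truth <- empty_truth()
  list(
    records = tibble::tibble(seq_id = ids, sequence = seqs,
                             length = nchar(seqs)),
    truth = tibble::as_tibble(truth)
  )
}

empty_truth <- function() {
  tibble::tibble(seq_id = character(), start = integer(), end = integer(),
                 motif = character(), period = integer(),
                 repeats = integer(), intended_class = character())
}

# spread instruction rows over genes; returns per-gene tibbles (motif,
# repeats), checking feasibility against gene lengths
expand_plants <- function(plants, n_genes, lens, class1, class2) {
  out <- rep(list(tibble::tibble(motif = character(), repeats = integer())),
             n_genes)
  if (is.null(plants) || nrow(plants) == 0L) return(out)
  stopifnot(all(c("motif", "repeats", "n") %in% names(plants)))
  flat <- tibble::tibble(
    motif = rep(toupper(plants$motif), plants$n),
    repeats = rep(as.integer(plants$repeats), plants$n)
  )
  bad <- smallest_period(flat$motif) != nchar(flat$motif)
  if (any(bad)) {
    stop("non-primitive plant motif(s): ",
         paste(unique(flat$motif[bad]), collapse = ", "), call. = FALSE)
  }
  cls <- classify_repeats(nchar(flat$motif), flat$repeats, class1, class2)
  if (anyNA(cls)) {
    stop("plant instruction below every class threshold", call. = FALSE)
  }
  gene_of <- rep_len(sample.int(n_genes), nrow(flat))
  flat <- flat[sample.int(nrow(flat)), , drop = FALSE]
  groups <- split(flat, gene_of)
  for (gname in names(groups)) {
    g <- as.integer(gname)
    need <- sum(nchar(groups[[gname]]$motif) * groups[[gname]]$repeats) +
      14L * (nrow(groups[[gname]]) + 1L)
    if (need > lens[g]) {
      stop("infeasible packing: gene of ", lens[g], " bp cannot hold ",
           nrow(groups[[gname]]), " tract(s) needing ~", need, " bp",
           call. = FALSE)
    }
    out[[g]] <- groups[[gname]]
  }
  out
}

# one gene: background + plants + verification that detected == truth
build_gene <- function(len, gc, gene_plants, codon_aligned, class1, class2,
                       max_retries = 60L) {
  p <- base_probs(gc)
  chars <- sample(BASES, len, replace = TRUE, prob = p)
  np <- nrow(gene_plants)
  if (np == 0L) {
    chars <- repair_background(chars, integer(), gc, class1, class2)
    return(list(sequence = paste(chars, collapse = ""),
                truth = empty_truth()[, -1]))
  }
  tract_len <- nchar(gene_plants$motif) * gene_plants$repeats
  min_gap <- 12L
  slack <- len - sum(tract_len) - min_gap * (np + 1L)
  if (slack < 0L) stop("infeasible packing", call. = FALSE)
  extra <- as.vector(stats::rmultinom(1L, slack, rep(1, np + 1L)))
  gaps <- min_gap + extra[seq_len(np)]
  starts <- cumsum(gaps) + c(0L, cumsum(tract_len))[seq_len(np)]
  if (codon_aligned) starts <- starts - starts %% 3L
  periods <- nchar(gene_plants$motif)
  truth <- data.frame(
    start = as.integer(starts),
    end = as.integer(starts + tract_len),
    motif = gene_plants$motif,
    period = as.integer(periods),
    repeats = as.integer(gene_plants$repeats),
    intended_class = classify_repeats(periods, gene_plants$repeats,
                                      class1, class2)
  )
  for (i in seq_len(np)) {
    chars <- plant_into_chars(chars, gene_plants$motif[i],
                              gene_plants$repeats[i], starts[i])
  }
  protected <- unlist(Map(seq.int, starts + 1L, starts + tract_len),
                      use.names = FALSE)
  chars <- repair_background(chars, protected, gc, class1, class2,
                             max_retries = max_retries, truth = truth)
  # final consistency check: detector must report exactly the planted truth
  loci <- scan_string(paste(chars, collapse = ""), class1, class2)
  key_l <- paste(loci$start, loci$end, loci$period)
  key_t <- paste(truth$start, truth$end, truth$period)
  if (!setequal(key_l, key_t) || length(key_l) != length(key_t)) {
    stop("planted truth and detected loci disagree after repair",
         call. = FALSE)
  }
  list(sequence = paste(chars, collapse = ""), truth = truth)
}

#' Score detector output against planted truth
#'
#' Exact-interval matching on `(seq_id, start, end, period)`:
#' precision = matched / detected, recall = matched / truth. Also reports a
#' per-class confusion table comparing the intended class of each matched
#' truth tract with the class the detector assigned.
#'
#' @param truth Truth tibble from [generate_dataset()].
#' @param detected Loci tibble from [detect_ssrs()].
#' @return An object of class `ssr_recovery`: list with `precision`,
#'   `recall`, `n_truth`, `n_detected`, `n_matched` and `confusion` (tibble
#'   `intended_class`, `detected_class`, `n`). Precision (recall) is `NA`
#'   when there are no detected (truth) loci to score.
#' @export
recovery_report <- function(truth, detected) {
  key_t <- paste(truth$seq_id, truth$start, truth$end, truth$period)
  key_d <- paste(detected$seq_id, detected$start, detected$end,
                 detected$period)
  matched <- intersect(key_t, key_d)
  confusion <- tibble::tibble(
    intended_class = truth$intended_class[match(matched, key_t)],
    detected_class = detected$ssr_class[match(matched, key_d)]
  ) |>
    dplyr::count(.data$intended_class, .data$detected_class, name = "n")
  structure(list(
    precision = if (nrow(detected)) length(matched) / nrow(detected) else NA_real_,
    recall = if (nrow(truth)) length(matched) / nrow(truth) else NA_real_,
    n_truth = nrow(truth),
    n_detected = nrow(detected),
    n_matched = length(matched),
    confusion = confusion
  ), class = "ssr_recovery")
}

#' @export
print.ssr_recovery <- function(x, ...) {
  cat(sprintf("SSR recovery: precision = %.4f, recall = %.4f (%d truth, %d detected)\n",
              x$precision, x$recall, x$n_truth, x$n_detected))
  invisible(x)
}

#' @rdname recovery_report
#' @param x An `ssr_recovery` object.
#' @param ... Unused.
#' @export
tidy.ssr_recovery <- function(x, ...) {
  tibble::tibble(precision = x$precision, recall = x$recall,
                 n_truth = x$n_truth, n_detected = x$n_detected,
                 n_matched = x$n_matched)
}
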