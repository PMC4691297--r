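# Independent brute-force oracle for maximal perfect tandem repeats.
# Re-derives the run set from first principles: for every candidate
# (start, period), the motif must be ACGT-only and primitive (checked by the
# divisor-prefix definition), the repeat count is grown unit by unit with
# substring comparisons, the run must reach two whole units, and the base
# before the start must not continue the period (leftmost anchoring).
oracle_runs <- function(seq, k_range = 1:10) {
  chars <- strsplit(seq, NULL)[[1]]
  L <- length(chars)
  acgt <- c("A", "C", "G", "T")
  rows <- list()
  for (k in k_range) {
    if (L < 2 * k) next
    for (start in 0:(L - 2 * k)) {
      motif <- substr(seq, start + 1L, start + k)
      if (grepl("[^ACGT]", motif)) next
      primitive <- TRUE
      for (p in seq_len(k - 1L)) {
        if (k %% p == 0L &&
            motif == strrep(substr(motif, 1L, p), k %/% p)) {
          primitive <- FALSE
          break
        }
      }
      if (!primitive) next
      if (start > 0L && chars[start] %in% acgt &&
          chars[start] == chars[start + k]) {
        next  # run extends further left; not the anchor
      }
      n <- 1L
      while (start + (n + 1L) * k <= L &&
             substr(seq, start + n * k + 1L, start + (n + 1L) * k) == motif) {
        n <- n + 1L
      }
      if (n >= 2L) {
        rows[[length(rows) + 1L]] <-
          data.frame(start = start, period = k, repeats = n, motif = motif)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(), period = integer(),
                      repeats = integer(), motif = character()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$period), , drop = FALSE]
}

run_key <- function(df) {
  if (nrow(df) == 0L) return(character())
  sort(paste(df$start, df$period, df$repeats, df$motif))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# all DNA strings of length k
all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE))
}

records_of <- function(...) {
  seqs <- c(...)
  ids <- names(seqs) %||% paste0("g", seq_along(seqs))
  tibble::tibble(seq_id = ids, sequence = unname(seqs),
                 length = unname(nchar(seqs)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
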