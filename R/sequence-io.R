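#' Read coding sequences from a FASTA file
#'
#' Reads a multi-record nucleotide FASTA of coding sequences (CDS) into a
#' tibble, one row per gene. The record identifier is the first
#' whitespace-delimited token of the header; the rest of the header is
#' discarded. Sequence bodies may be wrapped at any column width and may use
#' LF or CRLF line endings; lowercase bases are mapped to uppercase. IUPAC
#' ambiguity letters (including `N`) are retained — downstream SSR detection
#' treats them as hard breaks, so no repeat tract ever spans one.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `seq_id` (character), `sequence` (character,
#'   uppercase) and `length` (integer, bp). An empty file yields a zero-row
#'   tibble with a warning.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1 some description", "ATGAAA"), fa)
#' read_cds_fasta(fa)
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) {
      stop("malformed FASTA in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0L) {
    warning("no records in FASTA file: ", path, call. = FALSE)
    return(empty_records())
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  records <- tibble::tibble(
    seq_id = ids,
    sequence = seqs,
    length = nchar(seqs)
  )
  validate_records(records, source = path)
  records
}

empty_records <- function() {
  tibble::tibble(seq_id = character(), sequence = character(),
                 length = integer())
}

#' @keywords internal
validate_records <- function(records, source = "input") {
  if (anyDuplicated(records$seq_id)) {
    dup <- unique(records$seq_id[duplicated(records$seq_id)])
    stop("duplicate record ID(s) in ", source, ": ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(records$seq_id))) {
    stop("empty record ID in ", source, call. = FALSE)
  }
  if (any(records$length == 0L)) {
    stop("empty sequence record(s) in ", source, ": ",
         paste(utils::head(records$seq_id[records$length == 0L], 5),
               collapse = ", "), call. = FALSE)
  }
  bad <- grepl("[\\s.-]", records$sequence, perl = TRUE)
  if (any(bad)) {
    stop("whitespace or gap characters in sequence(s): ",
         paste(utils::head(records$seq_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(records)
}

#' Write CDS records to a FASTA file
#'
#' Inverse of [read_cds_fasta()]: round-tripping reproduces identical
#' `(seq_id, sequence)` pairs.
#'
#' @param records Tibble with `seq_id` and `sequence` columns.
#' @param path Output path.
#' @param width Line-wrap width for sequence bodies.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(records, path, width = 70L) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$seq_id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Total dataset length in base pairs
#'
#' Sum of sequence lengths over all records (not only SSR-containing genes);
#' the denominator for counts-per-Mbp normalisation.
#'
#' @param records Tibble of CDS records.
#' @return Integer-valued total length in bp (0 for an empty dataset).
#' @export
total_length_bp <- function(records) {
  if (nrow(records) == 0L) return(0)
  sum(as.numeric(nchar(records$sequence)))
}
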