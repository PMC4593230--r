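#' Sequence record tables
#'
#' `longotu` represents a set of reads or reference sequences as a plain
#' `data.frame` (class `seq_records`) with one row per sequence:
#'
#' * `id` — unique sequence identifier,
#' * `sample_id` — sample of origin (`""` when not applicable),
#' * `technology` — one of `"short_merged"`, `"ccs"`, `"reference"`,
#'   `"amplicon"`,
#' * `seq` — IUPAC DNA string (may contain `N`),
#' * `quals` — list column of integer phred vectors (or `NULL` per row),
#' * `passes` — CCS pass count (`NA` when not applicable),
#' * `spacer_start`, `spacer_end` — 1-based interval of the `N` spacer
#'   inserted by [merge_pairs()] (`NA` when the read has no spacer).
#'
#' Keeping the container a `data.frame` means standard subsetting, joins and
#' `split()` work unchanged; every function in the package accepts and
#' returns this shape.
#'
#' @param id character vector of unique ids.
#' @param seq character vector of IUPAC DNA sequences.
#' @param sample_id character vector (recycled) of sample labels.
#' @param technology character vector (recycled); one of `short_merged`,
#'   `ccs`, `reference`, `amplicon`.
#' @param quals optional list of integer phred vectors (one per sequence,
#'   `NULL` allowed), each the same length as its sequence.
#' @param passes optional integer vector of CCS pass counts (`NA` allowed).
#' @param spacer_start,spacer_end optional integer vectors marking the `N`
#'   spacer interval within each sequence.
#'
#' @return A `data.frame` of class `seq_records`.
#' @examples
#' seq_records(id = c("r1", "r2"), seq = c("ACGT", "GGGTTT"))
#' @export
seq_records <- function(id, seq, sample_id = "", technology = "reference",
                        quals = NULL, passes = NA_integer_,
                        spacer_start = NA_integer_, spacer_end = NA_integer_) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  n <- length(id)
  if (length(seq) != n) stop("id and seq must have the same length")
  if (is.null(quals)) quals <- vector("list", n)
  if (!is.list(quals)) stop("quals must be a list of integer vectors")
  rec <- data.frame(
    id = id,
    sample_id = rep_len(as.character(sample_id), n),
    technology = rep_len(as.character(technology), n),
    seq = seq,
    passes = rep_len(as.integer(passes), n),
    spacer_start = rep_len(as.integer(spacer_start), n),
    spacer_end = rep_len(as.integer(spacer_end), n),
    stringsAsFactors = FALSE
  )
  rec$quals <- quals
  class(rec) <- c("seq_records", "data.frame")
  validate_seq_records(rec)
  rec
}

#' Validate a seq_records table
#'
#' Checks the container invariants: unique non-empty ids, non-empty sequences
#' restricted to IUPAC DNA codes, quality vectors matching sequence length,
#' pass counts at least 1, and a recognized technology tag.
#'
#' @param rec a [seq_records()] table.
#' @return `rec`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_seq_records <- function(rec) {
  if (!is.data.frame(rec)) stop("records must be a data.frame")
  need <- c("id", "sample_id", "technology", "seq", "quals", "passes")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(rec$id)) stop("sequence ids must be unique")
  if (any(!nzchar(rec$seq))) stop("sequences must be non-empty")
  bad <- grepl("[^ACGTURYSWKMBDHVN]", rec$seq)
  if (any(bad)) {
    stop("non-IUPAC characters in sequence(s): ",
         paste(head(rec$id[bad], 3L), collapse = ", "))
  }
  tech_ok <- rec$technology %in% c("short_merged", "ccs", "reference", "amplicon")
  if (any(!tech_ok)) stop("unknown technology tag: ", rec$technology[!tech_ok][1L])
  ql <- vapply(rec$quals, function(q) if (is.null(q)) -1L else length(q), 1L)
  sl <- nchar(rec$seq)
  if (any(ql >= 0L & ql != sl)) {
    stop("quality vector length differs from sequence length for: ",
         paste(head(rec$id[ql >= 0L & ql != sl], 3L), collapse = ", "))
  }
  if (any(!is.na(rec$passes) & rec$passes < 1L)) stop("passes must be >= 1")
  invisible(rec)
}

# subsetting keeps the class
#' @export
`[.seq_records` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- c("seq_records", "data.frame")
  out
}

#' @export
print.seq_records <- function(x, ...) {
  cat(sprintf("<seq_records> %d sequence(s); technologies: %s\n",
              nrow(x), paste(unique(x$technology), collapse = ", ")))
  if (nrow(x)) {
    show <- head(data.frame(id = x$id, sample = x$sample_id,
                            len = nchar(x$seq),
                            has_quals = !vapply(x$quals, is.null, TRUE)), 6L)
    print(show, row.names = FALSE)
    if (nrow(x) > 6L) cat(sprintf("... and %d more\n", nrow(x) - 6L))
  }
  invisible(x)
}

#' Bind several seq_records tables into one
#'
#' @param lst list of [seq_records()] tables (empty elements allowed).
#' @return a single [seq_records()] table.
#' @export
bind_records <- function(lst) {
  lst <- lst[vapply(lst, NROW, 1L) > 0L]
  if (!length(lst)) return(seq_records(character(0), character(0)))
  out <- do.call(rbind, lapply(lst, as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("seq_records", "data.frame")
  validate_seq_records(out)
  out
}

#' Reverse-complement a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] working on plain
#' character vectors. IUPAC degeneracy codes are complemented correctly.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("ACGTN") # "NACGT"
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
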