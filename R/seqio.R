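# FASTA/FASTQ readers and writers (Biostrings-backed) plus the metadata
# header convention used to round-trip seq_records through plain files.
#
# Header tokens after the id (all optional): sample=<s> tech=<t> passes=<n>
# spacer=<start>-<end>. Unknown tokens are ignored on read.

fmt_header <- function(rec) {
  tok <- rec$id
  add <- function(tok, cond, txt) ifelse(cond, paste(tok, txt), tok)
  tok <- add(tok, nzchar(rec$sample_id), paste0("sample=", rec$sample_id))
  tok <- add(tok, rec$technology != "reference", paste0("tech=", rec$technology))
  tok <- add(tok, !is.na(rec$passes), paste0("passes=", rec$passes))
  tok <- add(tok, !is.na(rec$spacer_start),
             paste0("spacer=", rec$spacer_start, "-", rec$spacer_end))
  tok
}

parse_headers <- function(headers) {
  parts <- strsplit(headers, "[ \t]+")
  grab <- function(p, key) {
    hit <- grep(paste0("^", key, "="), p, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1L]) else NA_character_
  }
  id <- vapply(parts, `[[`, "", 1L)
  sample_id <- vapply(parts, grab, "", key = "sample")
  tech <- vapply(parts, grab, "", key = "tech")
  passes <- suppressWarnings(as.integer(vapply(parts, grab, "", key = "passes")))
  spacer <- vapply(parts, grab, "", key = "spacer")
  sp <- regmatches(spacer, regexec("^([0-9]+)-([0-9]+)$", spacer))
  s1 <- vapply(sp, function(m) if (length(m)) as.integer(m[2L]) else NA_integer_, 1L)
  s2 <- vapply(sp, function(m) if (length(m)) as.integer(m[3L]) else NA_integer_, 1L)
  list(id = id,
       sample_id = ifelse(is.na(sample_id), "", sample_id),
       technology = ifelse(is.na(tech), "reference", tech),
       passes = passes, spacer_start = s1, spacer_end = s2)
}

#' Read and write FASTQ files
#'
#' Sanger-convention FASTQ (phred offset 33). Metadata written by
#' [write_fastq()] in the header line (sample, technology, passes, spacer
#' interval) is recovered on read, so `read_fastq(write_fastq(x))` returns
#' `x` exactly.
#'
#' @param path file path.
#' @param records a [seq_records()] table; every row must carry qualities.
#' @return `read_fastq()` returns a [seq_records()] table; `write_fastq()`
#'   returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".fastq")
#' x <- seq_records("r1", "ACGT", technology = "ccs",
#'                  quals = list(c(40L, 40L, 30L, 2L)))
#' write_fastq(x, f)
#' read_fastq(f)
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  parsed <- tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    qs <- S4Vectors::mcols(x)$qualities
    quals <- if (length(x)) {
      as.list(methods::as(Biostrings::PhredQuality(qs), "IntegerList"))
    } else list()
    if (any(unlist(lapply(quals, max), use.names = FALSE) > 93L))
      stop("quality above phred 93: not Sanger offset-33 encoding")
    list(x = x, quals = quals)
  }, error = function(e) stop("malformed FASTQ in '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  x <- parsed$x
  quals <- parsed$quals
  if (length(x) == 0L) return(seq_records(character(0), character(0)))
  h <- parse_headers(names(x))
  seq_records(id = h$id, seq = as.character(x), sample_id = h$sample_id,
              technology = h$technology, quals = unname(quals),
              passes = h$passes,
              spacer_start = h$spacer_start, spacer_end = h$spacer_end)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(records, path) {
  validate_seq_records(records)
  if (any(vapply(records$quals, is.null, TRUE)))
    stop("all records need qualities to write FASTQ")
  dss <- Biostrings::DNAStringSet(records$seq)
  names(dss) <- fmt_header(records)
  qstr <- vapply(records$quals, function(q) {
    if (any(q < 0L | q > 93L)) stop("phred values must be in 0..93")
    rawToChar(as.raw(q + 33L))
  }, "")
  Biostrings::writeXStringSet(dss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qstr))
  invisible(path)
}

#' Read and write FASTA files
#'
#' Wrapped FASTA (80 columns on write). The same metadata header convention
#' as [read_fastq()] applies; records read from plain third-party FASTA get
#' `sample_id = ""` and `technology = "reference"`.
#'
#' @param path file path.
#' @param records a [seq_records()] table.
#' @return `read_fasta()` returns a [seq_records()] table; `write_fasta()`
#'   returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(x) == 0L) return(seq_records(character(0), character(0)))
  h <- parse_headers(names(x))
  seq_records(id = h$id, seq = as.character(x), sample_id = h$sample_id,
              technology = h$technology, passes = h$passes,
              spacer_start = h$spacer_start, spacer_end = h$spacer_end)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  validate_seq_records(records)
  dss <- Biostrings::DNAStringSet(records$seq)
  names(dss) <- fmt_header(records)
  Biostrings::writeXStringSet(dss, path, format = "fasta", width = 80L)
  invisible(path)
}

#' Read an aligned FASTA into a character matrix
#'
#' Rows are sequences (rownames = ids), columns are alignment columns.
#' Gap characters `-` and `.` are both read as `-`.
#'
#' @param path aligned FASTA file; all rows must have equal length.
#' @return character matrix of single characters.
#' @export
read_msa <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty alignment: ", path)
  s <- toupper(chartr(".", "-", as.character(x)))
  if (length(unique(nchar(s))) != 1L)
    stop("alignment rows differ in length in '", path, "'")
  m <- do.call(rbind, unname(strsplit(s, "", fixed = TRUE)))
  rownames(m) <- vapply(strsplit(names(x), "[ \t]+"), `[[`, "", 1L)
  m
}

#' Read a barcode/primer table
#'
#' Tab-separated file with columns `sample_id`, `barcode` and optionally
#' `primer` (IUPAC-degenerate). Barcodes must be unique and of one common
#' length within a run.
#'
#' @param path TSV file path.
#' @return data.frame with columns `sample_id`, `barcode`, `primer`.
#' @export
read_barcode_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "barcode") %in% names(tab)))
    stop("barcode table needs columns sample_id and barcode")
  if (is.null(tab$primer)) tab$primer <- NA_character_
  tab$barcode <- toupper(tab$barcode)
  if (anyDuplicated(tab$barcode)) stop("duplicate barcodes in table")
  if (length(unique(nchar(tab$barcode))) != 1L)
    stop("barcodes must all have the same length")
  tab[, c("sample_id", "barcode", "primer")]
}
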