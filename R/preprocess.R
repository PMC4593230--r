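# Read preprocessing: pair merging, quality-fraction filtering, length
# filtering, barcode demultiplexing, seeded shuffling.

# evaluate expr under a temporary RNG state; NULL seed = use current stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# IUPAC code -> regex character class (subject N tolerated everywhere)
iupac_regex <- function(primer) {
  map <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
           R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
           B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
  chars <- strsplit(toupper(primer), "")[[1]]
  bad <- !chars %in% names(map)
  if (any(bad)) stop("invalid IUPAC code in primer: ", chars[bad][1L])
  paste0(vapply(chars, function(ch) paste0("[", map[[ch]], "N]"), ""),
         collapse = "")
}

#' Merge a read pair into one spacer-separated sequence
#'
#' The 3'-most `trim_tail` bases of the second read are discarded; the
#' remainder is reverse-complemented and appended to the first read behind a
#' run of `spacer_len` `N` bases. Spacer positions get quality 0 and the
#' spacer interval is recorded on the record so downstream per-base
#' statistics can exclude it. The MiSeq convention is
#' `trim_tail = 42, spacer_len = 42`; simulated short pairs use
#' `trim_tail = 0, spacer_len = 10`.
#'
#' @param r1,r2 single-row [seq_records()] tables (forward and reverse read).
#' @param trim_tail number of 3' bases to drop from `r2` before merging.
#' @param spacer_len length of the `N` spacer.
#' @return a one-row [seq_records()] table with technology `short_merged`.
#' @examples
#' r1 <- seq_records("p/1", "ACGT")
#' r2 <- seq_records("p/2", "AAAAAATT")
#' merge_pairs(r1, r2, trim_tail = 2, spacer_len = 3)$seq # "ACGTNNNTTTTTT"
#' @export
merge_pairs <- function(r1, r2, trim_tail = 42L, spacer_len = 42L) {
  stopifnot(nrow(r1) == 1L, nrow(r2) == 1L)
  len2 <- nchar(r2$seq)
  if (len2 <= trim_tail)
    stop("second read (", len2, " bp) not longer than trim_tail (",
         trim_tail, ")")
  kept2 <- substr(r2$seq, 1L, len2 - trim_tail)
  seq <- paste0(r1$seq, strrep("N", spacer_len), revcomp(kept2))
  q1 <- r1$quals[[1L]]; q2 <- r2$quals[[1L]]
  quals <- if (!is.null(q1) && !is.null(q2)) {
    list(c(q1, rep(0L, spacer_len), rev(q2[seq_len(len2 - trim_tail)])))
  } else {
    list(NULL)
  }
  len1 <- nchar(r1$seq)
  seq_records(id = r1$id, seq = seq, sample_id = r1$sample_id,
              technology = "short_merged", quals = quals,
              spacer_start = if (spacer_len > 0L) len1 + 1L else NA_integer_,
              spacer_end = if (spacer_len > 0L) len1 + spacer_len else NA_integer_)
}

#' Quality-fraction filter
#'
#' Keeps a read when the fraction of considered positions at sufficient
#' quality reaches `min_fraction`. With `strict = TRUE` a position counts
#' when its phred value is `> min_q` (the CCS rule, ">Q30 across 90%");
#' with `strict = FALSE` when `>= min_q` (the merged short-read rule,
#' ">=Q30 over 97% excluding the spacer").
#'
#' @param records a [seq_records()] table; all rows must carry qualities.
#' @param min_q phred threshold.
#' @param min_fraction required fraction of qualifying positions.
#' @param strict compare with `>` (TRUE) or `>=` (FALSE).
#' @param exclude_spacer drop recorded spacer positions before counting.
#' @return logical vector, one element per record.
#' @export
quality_fraction_filter <- function(records, min_q = 30L, min_fraction = 0.9,
                                    strict = TRUE, exclude_spacer = TRUE) {
  validate_seq_records(records)
  vapply(seq_len(nrow(records)), function(i) {
    q <- records$quals[[i]]
    if (is.null(q)) stop("record '", records$id[i], "' has no qualities")
    if (exclude_spacer && !is.na(records$spacer_start[i])) {
      q <- q[-(records$spacer_start[i]:records$spacer_end[i])]
    }
    ok <- if (strict) q > min_q else q >= min_q
    mean(ok) >= min_fraction
  }, TRUE)
}

#' Length filter
#'
#' Keeps sequences within `tolerance` bases of the expected amplicon size
#' (inclusive bounds), e.g. "within 100 bp of the expected amplicon size".
#'
#' @param records a [seq_records()] table.
#' @param expected_len expected amplicon length (> 0).
#' @param tolerance allowed absolute deviation in bases.
#' @return logical vector, one element per record.
#' @export
length_filter <- function(records, expected_len, tolerance = 100L) {
  if (expected_len <= 0) stop("expected_len must be positive")
  abs(nchar(records$seq) - expected_len) <= tolerance
}

#' Demultiplex reads by exact 5' barcode match
#'
#' Each read is assigned to the unique barcode matching its 5' prefix with
#' zero mismatches; the barcode (and the primer, when given and matching
#' with IUPAC degeneracy) is stripped from sequence and qualities.
#' Non-matching reads land in the `unassigned` bin.
#'
#' @param records a [seq_records()] table.
#' @param specs data.frame with columns `sample_id`, `barcode` and optional
#'   `primer` (see [read_barcode_table()]).
#' @return list with `samples` (named list of [seq_records()] per sample)
#'   and `unassigned` (a [seq_records()] table).
#' @export
demultiplex <- function(records, specs) {
  validate_seq_records(records)
  if (anyDuplicated(specs$barcode)) stop("duplicate barcodes in specs")
  if (length(unique(nchar(specs$barcode))) != 1L)
    stop("all barcodes must have the same length")
  if (is.null(specs$primer)) specs$primer <- NA_character_
  bl <- nchar(specs$barcode[1L])
  prefix <- substr(records$seq, 1L, bl)
  hit <- match(prefix, specs$barcode)

  trim_one <- function(i, strip) {
    rec <- records[i, , drop = FALSE]
    rec$seq <- substr(rec$seq, strip + 1L, nchar(rec$seq))
    q <- rec$quals[[1L]]
    if (!is.null(q)) rec$quals[[1L]] <- q[-seq_len(strip)]
    if (!is.na(rec$spacer_start)) {
      rec$spacer_start <- rec$spacer_start - strip
      rec$spacer_end <- rec$spacer_end - strip
    }
    rec
  }

  samples <- stats::setNames(vector("list", nrow(specs)), specs$sample_id)
  for (s in seq_len(nrow(specs))) {
    idx <- which(hit == s)
    rows <- lapply(idx, function(i) {
      strip <- bl
      primer <- specs$primer[s]
      if (!is.na(primer) && nzchar(primer)) {
        after <- substr(records$seq[i], bl + 1L, bl + nchar(primer))
        if (grepl(paste0("^", iupac_regex(primer)), after)) {
          strip <- bl + nchar(primer)
        }
      }
      trim_one(i, strip)
    })
    samples[[s]] <- if (length(rows)) do.call(rbind, rows) else
      seq_records(character(0), character(0))
    class(samples[[s]]) <- c("seq_records", "data.frame")
  }
  unassigned <- records[is.na(hit), , drop = FALSE]
  list(samples = samples, unassigned = unassigned)
}

#' Deterministically shuffle records
#'
#' Random permutation of the rows under a fixed seed, used to make sure
#' input order cannot influence clustering.
#'
#' @param records a [seq_records()] table.
#' @param seed integer seed.
#' @return the same records in permuted order.
#' @export
shuffle_records <- function(records, seed) {
  perm <- with_seed(seed, sample.int(nrow(records)))
  records[perm, , drop = FALSE]
}
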