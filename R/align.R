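# Needleman-Wunsch global alignment, strand orientation, and the
# CCS-oriented alignment post-processing that precedes the genetic distance.

default_scoring <- function() {
  list(match = 5, mismatch = -4, gap_open = 10, gap_extend = 0.5)
}

check_scoring <- function(scoring) {
  need <- c("match", "mismatch", "gap_open", "gap_extend")
  if (!all(need %in% names(scoring)))
    stop("scoring needs fields: ", paste(need, collapse = ", "))
  lapply(scoring[need], as.numeric)
}

new_alignment <- function(row_a, row_b, score, scoring) {
  st <- .pair_distance_c(row_a, row_b, FALSE, TRUE)
  structure(
    list(row_a = row_a, row_b = row_b, score = score,
         mismatches = as.integer(st[1L]), indel_events = as.integer(st[2L]),
         examined_columns = as.integer(st[3L]), scoring = scoring),
    class = "pairwise_alignment")
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment under affine-gap scoring (Gotoh
#' algorithm). A gap run of length L costs `gap_open + L * gap_extend`;
#' terminal gaps are penalized. Among co-optimal paths the traceback prefers
#' diagonal over gap-in-second-sequence over gap-in-first, so results are
#' identical across runs, platforms, and input orders. `N` scores 0 against
#' any base.
#'
#' Defaults follow the EMBOSS needle conventions: match +5, mismatch -4,
#' gap open 10, gap extend 0.5.
#'
#' @param a,b DNA strings (non-empty).
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @param band optional non-negative integer: restrict the alignment path to
#'   a band of this half-width around the length-difference diagonal.
#'   `NULL` (default) searches the full dynamic-programming matrix. Banding
#'   is a speed device for all-versus-all runs on reads of similar length;
#'   a too-narrow band can miss the optimum for very gappy pairs.
#' @return a `pairwise_alignment`: gapped rows `row_a`/`row_b`, `score`, and
#'   difference bookkeeping (`mismatches`, `indel_events`,
#'   `examined_columns`) computed on the raw alignment.
#' @examples
#' aln <- nw_align("GATTACA", "GATCA")
#' aln$row_a
#' @export
nw_align <- function(a, b, scoring = default_scoring(), band = NULL) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  sc <- check_scoring(scoring)
  res <- .gotoh_align_c(toupper(a), toupper(b), sc$match, sc$mismatch,
                        sc$gap_open, sc$gap_extend,
                        if (is.null(band)) -1L else as.integer(band))
  new_alignment(res$row_a, res$row_b, res$score, sc)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> score %.1f, %d columns, %d mismatches, %d indel events\n",
              x$score, nchar(x$row_a), x$mismatches, x$indel_events))
  if (nchar(x$row_a) <= 60L) cat(x$row_a, x$row_b, sep = "\n")
  invisible(x)
}

aln_chars <- function(aln) {
  list(a = strsplit(aln$row_a, "", fixed = TRUE)[[1L]],
       b = strsplit(aln$row_b, "", fixed = TRUE)[[1L]])
}

rebuild_alignment <- function(a, b, aln) {
  new_alignment(paste(a, collapse = ""), paste(b, collapse = ""),
                aln$score, aln$scoring)
}

#' Strip terminal alignment gaps
#'
#' Removes leading and trailing columns that belong to a terminal gap run in
#' either row. With amplicon reads of unequal span, terminal gaps reflect
#' missing sequence, not evolutionary events, so they are removed before
#' distance computation.
#'
#' @param aln a `pairwise_alignment` from [nw_align()].
#' @return the trimmed `pairwise_alignment`.
#' @export
strip_terminal_gaps <- function(aln) {
  ch <- aln_chars(aln)
  ga <- ch$a == "-"; gb <- ch$b == "-"
  n <- length(ga)
  lead <- max(match(FALSE, ga, nomatch = n + 1L),
              match(FALSE, gb, nomatch = n + 1L)) - 1L
  tail_a <- n - max(which(!ga), 0L)
  tail_b <- n - max(which(!gb), 0L)
  trail <- max(tail_a, tail_b)
  if (lead + trail >= n)
    stop("alignment has no overlapping columns after terminal-gap removal")
  keep <- (lead + 1L):(n - trail)
  rebuild_alignment(ch$a[keep], ch$b[keep], aln)
}

# positions of gap runs of exactly length 1 in a logical gap mask
single_run_positions <- function(gaps) {
  r <- rle(gaps)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts[r$values & r$lengths == 1L]
}

#' Remove internal single-base indels
#'
#' Deletes every alignment column belonging to an internal gap run of length
#' exactly one (in either row); runs of length two or more are untouched.
#' Single-base insertions and deletions are the dominant error mode of CCS
#' reads, and counting them as differences would inflate OTU estimates.
#' Terminal gaps must already be stripped (see [strip_terminal_gaps()]).
#'
#' @param aln a `pairwise_alignment`.
#' @return the `pairwise_alignment` with single-base indel columns deleted.
#' @export
remove_single_base_indels <- function(aln) {
  ch <- aln_chars(aln)
  drop <- c(single_run_positions(ch$a == "-"),
            single_run_positions(ch$b == "-"))
  if (length(drop) == 0L) return(aln)
  rebuild_alignment(ch$a[-drop], ch$b[-drop], aln)
}

#' Post-process an alignment for distance computation
#'
#' Convenience composition of [strip_terminal_gaps()] and
#' [remove_single_base_indels()].
#'
#' @param aln a `pairwise_alignment`.
#' @return the post-processed `pairwise_alignment`.
#' @export
postprocess_alignment <- function(aln) {
  remove_single_base_indels(strip_terminal_gaps(aln))
}

#' Genetic distance of a post-processed alignment
#'
#' The distance is the number of differences divided by the number of
#' examined columns. Each surviving gap run counts as one difference
#' ("each indel counted once"); with `collapse_runs = TRUE` (default) its
#' columns also collapse to a single column in the denominator, so a k-base
#' indel weighs exactly like one substitution. With `collapse_runs = FALSE`
#' the full run length enters the denominator. Columns where either row has
#' `N` are excluded from both counts.
#'
#' @param aln a post-processed `pairwise_alignment`.
#' @param collapse_runs collapse each gap run to one denominator column.
#' @return numeric distance in `[0, 1]`.
#' @examples
#' aln <- postprocess_alignment(nw_align("ACGTTACGT", "ACGTACGT"))
#' genetic_distance(aln) # 0: the single-base indel is removed
#' @export
genetic_distance <- function(aln, collapse_runs = TRUE) {
  ch <- aln_chars(aln)
  ga <- ch$a == "-"; gb <- ch$b == "-"
  if (any(ga & gb)) stop("invalid alignment: column gapped in both rows")
  base_cols <- !ga & !gb & ch$a != "N" & ch$b != "N"
  mism <- sum(ch$a[base_cols] != ch$b[base_cols])
  matched <- sum(base_cols) - mism
  ra <- rle(ga); rb <- rle(gb)
  runs <- sum(ra$values) + sum(rb$values)
  run_cols <- sum(ra$lengths[ra$values]) + sum(rb$lengths[rb$values])
  denom <- matched + mism + if (collapse_runs) runs else run_cols
  if (denom == 0L) stop("zero examined columns: distance undefined")
  (mism + runs) / denom
}

#' Orient sequences to a common strand
#'
#' Aligns each record and its reverse complement against a panel of anchor
#' sequences and keeps whichever orientation attains the higher best
#' identity (matching columns over examined columns). Ties keep the input
#' orientation. By default the anchor panel is a seeded sample of up to
#' `n_anchors` sequences from the input itself, so no external database is
#' needed.
#'
#' @param records a [seq_records()] table.
#' @param anchors optional [seq_records()] table of anchor sequences.
#' @param n_anchors panel size when sampling anchors from the input.
#' @param scoring alignment scoring, see [nw_align()].
#' @param band optional alignment band, see [nw_align()].
#' @param seed seed for the anchor sample.
#' @return the records with sequences strand-normalized (qualities of
#'   flipped reads are reversed).
#' @export
orient <- function(records, anchors = NULL, n_anchors = 10L,
                   scoring = default_scoring(), band = NULL, seed = 1L) {
  validate_seq_records(records)
  if (is.null(anchors)) {
    k <- min(n_anchors, nrow(records))
    idx <- with_seed(seed, sample.int(nrow(records), k))
    anchors <- records[idx, , drop = FALSE]
  }
  if (nrow(anchors) == 0L) stop("need at least one anchor sequence")
  sc <- check_scoring(scoring)
  bnd <- if (is.null(band)) -1L else as.integer(band)
  best_identity <- function(s) {
    max(vapply(anchors$seq, function(anc) {
      r <- .gotoh_align_c(s, anc, sc$match, sc$mismatch,
                          sc$gap_open, sc$gap_extend, bnd)
      st <- .pair_distance_c(r$row_a, r$row_b, FALSE, FALSE)
      if (is.na(st[4L])) 0 else 1 - st[4L]
    }, 1.0))
  }
  for (i in seq_len(nrow(records))) {
    fwd <- best_identity(records$seq[i])
    rcseq <- revcomp(records$seq[i])
    rev <- best_identity(rcseq)
    if (rev > fwd) {
      records$seq[i] <- rcseq
      q <- records$quals[[i]]
      if (!is.null(q)) records$quals[[i]] <- rev(q)
      if (!is.na(records$spacer_start[i])) {
        len <- nchar(rcseq)
        s <- records$spacer_start[i]; e <- records$spacer_end[i]
        records$spacer_start[i] <- len - e + 1L
        records$spacer_end[i] <- len - s + 1L
      }
    }
  }
  records
}
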