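# All-versus-all distance matrices (pairwise-alignment and MSA variants).

#' Remove the recorded N spacer from merged reads
#'
#' Merged read pairs carry an internal run of `N` with a recorded interval;
#' aligning through it would fabricate indels, so it is excised before
#' distance computation.
#'
#' @param records a [seq_records()] table.
#' @return the records with spacer bases removed and intervals cleared.
#' @export
strip_spacer <- function(records) {
  for (i in which(!is.na(records$spacer_start))) {
    s <- records$spacer_start[i]; e <- records$spacer_end[i]
    len <- nchar(records$seq[i])
    records$seq[i] <- paste0(substr(records$seq[i], 1L, s - 1L),
                             substr(records$seq[i], e + 1L, len))
    q <- records$quals[[i]]
    if (!is.null(q)) records$quals[[i]] <- q[-(s:e)]
    records$spacer_start[i] <- NA_integer_
    records$spacer_end[i] <- NA_integer_
  }
  records
}

#' All-versus-all pairwise genetic distances
#'
#' For every pair of sequences: global alignment ([nw_align()]),
#' post-processing ([postprocess_alignment()]), then the genetic distance
#' ([genetic_distance()]). Recorded merged-read spacers are excised first.
#' The result is identical for any `jobs` value and any input order (up to
#' id-keyed lookup).
#'
#' @param records a [seq_records()] table with unique ids (>= 2 rows).
#' @param scoring alignment scoring, see [nw_align()].
#' @param jobs number of worker processes for the pair loop (forked via
#'   the parallel package; 1 = serial).
#' @param band optional alignment band half-width, see [nw_align()].
#' @param collapse_runs indel denominator convention, see
#'   [genetic_distance()].
#' @return symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @examples
#' rec <- seq_records(c("a", "b"), c("ACGTACGTAC", "ACGTTCGTAC"))
#' distance_matrix(rec)
#' @export
distance_matrix <- function(records, scoring = default_scoring(), jobs = 1L,
                            band = NULL, collapse_runs = TRUE) {
  validate_seq_records(records)
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records")
  records <- strip_spacer(records)
  ids <- records$id
  # canonical id order: each pair is aligned with the lexicographically
  # smaller id first, so the matrix is identical for any input order
  ord <- order(ids)
  seqs <- toupper(records$seq)[ord]
  sids <- ids[ord]
  sc <- check_scoring(scoring)
  bnd <- if (is.null(band)) -1L else as.integer(band)

  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  run_chunk <- function(rows) {
    .dist_pairs_c(seqs, pairs[rows, 1L], pairs[rows, 2L],
                  sc$match, sc$mismatch, sc$gap_open, sc$gap_extend,
                  bnd, TRUE, collapse_runs)
  }
  vals <- if (jobs > 1L) {
    chunks <- split(seq_len(nrow(pairs)),
                    rep_len(seq_len(jobs * 4L), nrow(pairs)))
    res <- parallel::mclapply(chunks, run_chunk, mc.cores = jobs)
    out <- numeric(nrow(pairs))
    for (ch in seq_along(chunks)) out[chunks[[ch]]] <- res[[ch]]
    out
  } else {
    run_chunk(seq_len(nrow(pairs)))
  }
  if (anyNA(vals)) {
    k <- which(is.na(vals))[1L]
    stop("non-overlapping pair: ", sids[pairs[k, 1L]], " / ",
         sids[pairs[k, 2L]])
  }
  D <- matrix(0, n, n, dimnames = list(sids, sids))
  D[upper.tri(D)] <- vals
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D[ids, ids]
}

#' Genetic distances from a multiple sequence alignment
#'
#' For each pair of alignment rows the distance is the fraction of differing
#' columns among columns where both rows carry a plain base (gaps and `N`
#' excluded, frequencies renormalized). This equals the square of the
#' square-root genetic distance returned by classical MSA distance
#' functions.
#'
#' @param msa character matrix (rows = sequences, see [read_msa()]) or a
#'   [seq_records()] table of equal-length aligned sequences.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
msa_distance <- function(msa) {
  if (inherits(msa, "seq_records") || is.data.frame(msa)) {
    if (length(unique(nchar(msa$seq))) != 1L)
      stop("aligned rows must have equal length")
    m <- do.call(rbind, strsplit(toupper(msa$seq), "", fixed = TRUE))
    rownames(m) <- msa$id
    msa <- m
  }
  if (!is.matrix(msa)) stop("msa must be a character matrix or seq_records")
  n <- nrow(msa)
  ids <- rownames(msa)
  ok <- msa %in% c("A", "C", "G", "T")
  dim(ok) <- dim(msa)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- ok[i, ] & ok[j, ]
      nb <- sum(both)
      if (nb == 0L)
        stop("no mutually ungapped columns for pair: ",
             ids[i], " / ", ids[j])
      d <- sum(msa[i, both] != msa[j, both]) / nb
      D[i, j] <- d; D[j, i] <- d
    }
  }
  D
}

#' Write / read a distance matrix as lower-triangular TSV
#'
#' Columns `id_i`, `id_j`, `distance`, one row per unordered pair.
#'
#' @param D symmetric distance matrix with dimnames.
#' @param path output file.
#' @return `write_dist_tsv()` returns `path` invisibly; `read_dist_tsv()`
#'   returns the symmetric matrix.
#' @export
write_dist_tsv <- function(D, path) {
  idx <- which(upper.tri(D), arr.ind = TRUE)
  tab <- data.frame(id_i = rownames(D)[idx[, 1L]],
                    id_j = colnames(D)[idx[, 2L]],
                    distance = D[idx])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_tsv
#' @export
read_dist_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  ids <- unique(c(tab$id_i, tab$id_j))
  D <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  D[cbind(tab$id_i, tab$id_j)] <- tab$distance
  D[cbind(tab$id_j, tab$id_i)] <- tab$distance
  D
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param D symmetric distance matrix with dimnames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dist_phylip <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    writeLines(paste(c(sprintf("%-10s", rownames(D)[i]),
                       sprintf("%.6f", D[i, ])), collapse = " "), con)
  }
  invisible(path)
}
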