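# Shannon-entropy profiling of a reference-projected multiple sequence
# alignment, averaged in non-overlapping windows.

#' Project an alignment onto reference coordinates
#'
#' Drops every alignment column where the reference row carries a gap
#' (insertions in the other sequences relative to the reference), so the
#' remaining columns are indexed 1..reference_length.
#'
#' @param msa character matrix (rows = sequences; see [read_msa()]).
#' @param reference_row_id rowname of the reference sequence.
#' @return character matrix with `reference_length` columns; the reference
#'   row is retained.
#' @export
project_to_reference <- function(msa, reference_row_id) {
  if (!reference_row_id %in% rownames(msa))
    stop("reference row '", reference_row_id, "' not in alignment")
  keep <- msa[reference_row_id, ] != "-"
  msa[, keep, drop = FALSE]
}

#' Shannon entropy of one alignment column
#'
#' `H = -sum(f_a * log2(f_a))` over the plain bases `a in {A, C, G, T}`;
#' gaps and `N`/ambiguity codes are excluded and the frequencies
#' renormalized over the remaining bases (`0 * log2(0)` taken as 0). A
#' column with no plain base at all has entropy 0 and is flagged via the
#' `"low_coverage"` attribute.
#'
#' @param column character vector of symbols.
#' @return entropy in bits, in `[0, 2]`.
#' @examples
#' column_entropy(c("A", "C", "G", "T")) # 2
#' column_entropy(c("A", "A", "C", "C")) # 1
#' @export
column_entropy <- function(column) {
  counts <- tabulate(match(column, c("A", "C", "G", "T")), nbins = 4L)
  tot <- sum(counts)
  if (tot == 0L) return(structure(0, low_coverage = TRUE))
  f <- counts[counts > 0L] / tot
  0 - sum(f * log2(f)) + 0 # + 0 normalizes IEEE negative zero
}

#' Per-position entropies of an alignment
#'
#' @param msa character matrix, typically already projected with
#'   [project_to_reference()].
#' @return numeric vector of per-column entropies (bits).
#' @export
position_entropies <- function(msa) {
  apply(msa, 2L, function(col) as.numeric(column_entropy(col)))
}

#' Average entropy in non-overlapping windows
#'
#' Means of consecutive `window`-position blocks; a trailing partial window
#' is dropped so all windows average the same number of positions.
#'
#' @param H numeric vector of per-position entropies.
#' @param window window size in positions (default 10).
#' @param start coordinate of the first position (default 1).
#' @return data.frame of class `entropy_profile` with columns
#'   `window_start` (position of the first base in the window) and
#'   `mean_entropy`.
#' @export
window_entropy <- function(H, window = 10L, start = 1L) {
  if (window < 1L) stop("window must be >= 1")
  n_win <- length(H) %/% window
  if (n_win == 0L)
    return(structure(data.frame(window_start = integer(0),
                                mean_entropy = numeric(0)),
                     class = c("entropy_profile", "data.frame")))
  idx <- seq_len(n_win * window)
  m <- matrix(H[idx], nrow = window)
  structure(data.frame(window_start = start + (seq_len(n_win) - 1L) * window,
                       mean_entropy = colMeans(m)),
            class = c("entropy_profile", "data.frame"))
}

#' Windowed entropy profile of an alignment
#'
#' Convenience composition: project the alignment onto the reference,
#' compute per-position entropies, average in non-overlapping windows.
#' Peaks of the profile mark hypervariable regions.
#'
#' @param msa character matrix (see [read_msa()]).
#' @param reference_row_id rowname of the reference sequence.
#' @param window window size (default 10).
#' @return an `entropy_profile` data.frame (see [window_entropy()]).
#' @export
entropy_profile <- function(msa, reference_row_id, window = 10L) {
  proj <- project_to_reference(msa, reference_row_id)
  others <- proj[setdiff(rownames(proj), reference_row_id), , drop = FALSE]
  window_entropy(position_entropies(others), window = window)
}

#' Write an entropy profile as TSV
#'
#' Columns `window_start`, `mean_entropy`.
#'
#' @param profile an `entropy_profile` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_entropy_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
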