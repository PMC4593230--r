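# Mixed-technology OTU analysis: trim long reads to the short-read region,
# subsample short reads to the long-read depth, cluster jointly, classify
# shared OTUs, and refine them with full-length long reads.

trim_to_region <- function(records, region) {
  stopifnot(inherits(region, "amplicon_spec"))
  kept <- vector("list", nrow(records))
  dropped <- 0L
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    if (region$mode == "interval") {
      len <- nchar(rec$seq)
      if (region$start > len) { dropped <- dropped + 1L; next }
      to <- min(region$end, len)
      rec$seq <- substr(rec$seq, region$start, to)
      q <- rec$quals[[1L]]
      if (!is.null(q)) rec$quals[[1L]] <- q[region$start:to]
    } else {
      seg <- tryCatch(
        find_primer_product(rec$seq, region$forward, region$reverse, rec$id),
        error = function(e) NULL)
      if (is.null(seg)) { dropped <- dropped + 1L; next }
      rec$seq <- seg
      rec$quals[1L] <- list(NULL)
    }
    rec$spacer_start <- NA_integer_
    rec$spacer_end <- NA_integer_
    kept[[i]] <- rec
  }
  list(records = bind_records(kept[!vapply(kept, is.null, TRUE)]),
       dropped = dropped)
}

#' Mixed-technology OTU inference with sub-OTU refinement
#'
#' Long (CCS) reads are trimmed to the short-read region; short reads are
#' sub-sampled (seeded) to the trimmed CCS count; the pooled set is
#' clustered at each threshold in `h_list`. OTUs reaching `min_reads` are
#' classified as shared (at least one read from each technology) or
#' technology-specific. For the `top_n` shared OTUs with the most CCS
#' reads, the full-length CCS members are re-clustered at the same
#' threshold; the number of resulting clusters is the sub-OTU count — the
#' substructure visible only to the longer reads.
#'
#' @param ccs_records full-length CCS [seq_records()].
#' @param short_records merged short-read [seq_records()].
#' @param region an [amplicon_spec()] locating the short-read region on the
#'   CCS reads (read coordinates or primer pair); reads where the region
#'   cannot be located are dropped and counted.
#' @param h_list clustering thresholds (default 0.01-0.03).
#' @param min_reads minimum OTU size for classification (default 10).
#' @param top_n shared OTUs selected for full-length refinement.
#' @param seed seed for the short-read sub-sample.
#' @param scoring,band,jobs passed to [distance_matrix()].
#' @return list with `dropped_ccs` (count) and per-threshold entries
#'   (named `h_0.01`, ...), each holding `shared`, `ccs_only`,
#'   `short_only` (OTU member lists), `counts` (summary row) and
#'   `sub_otus` (named vector: shared OTU -> sub-OTU count).
#' @export
hybrid_analysis <- function(ccs_records, short_records, region,
                            h_list = c(0.01, 0.02, 0.03), min_reads = 10L,
                            top_n = 10L, seed = 1L,
                            scoring = default_scoring(), band = NULL,
                            jobs = 1L) {
  validate_seq_records(ccs_records)
  validate_seq_records(short_records)
  tr <- trim_to_region(ccs_records, region)
  trimmed <- tr$records
  if (nrow(trimmed) < 2L) stop("too few CCS reads carry the region")
  if (tr$dropped > 0L)
    message(tr$dropped, " CCS read(s) dropped: region not found")

  n_ccs <- nrow(trimmed)
  short_use <- if (nrow(short_records) > n_ccs) {
    idx <- with_seed(seed, sample.int(nrow(short_records), n_ccs))
    short_records[sort(idx), , drop = FALSE]
  } else short_records

  pooled <- bind_records(list(trimmed, short_use))
  D <- distance_matrix(pooled, scoring = scoring, band = band, jobs = jobs)
  dend <- linkage(D, method = "complete")
  tech <- stats::setNames(pooled$technology, pooled$id)

  out <- list(dropped_ccs = tr$dropped)
  for (h in h_list) {
    part <- cut_tree(dend, h)
    members <- split(names(part), part)
    sizes <- lengths(members)
    big <- members[sizes >= min_reads]
    has_ccs <- vapply(big, function(m) any(tech[m] == "ccs"), TRUE)
    has_short <- vapply(big, function(m) any(tech[m] == "short_merged"), TRUE)
    shared <- big[has_ccs & has_short]
    ccs_only <- big[has_ccs & !has_short]
    short_only <- big[!has_ccs & has_short]

    ccs_count <- vapply(shared, function(m) sum(tech[m] == "ccs"), 1L)
    sel <- names(sort(ccs_count, decreasing = TRUE))
    sel <- sel[seq_len(min(top_n, length(sel)))]
    sub_otus <- vapply(sel, function(lab) {
      ids <- shared[[lab]][tech[shared[[lab]]] == "ccs"]
      full <- ccs_records[match(ids, ccs_records$id), , drop = FALSE]
      if (nrow(full) < 2L) return(1L)
      Df <- distance_matrix(full, scoring = scoring, band = band,
                            jobs = jobs)
      length(unique(cut_tree(linkage(Df, "complete"), h)))
    }, 1L)

    out[[sprintf("h_%.2f", h)]] <- list(
      shared = shared, ccs_only = ccs_only, short_only = short_only,
      counts = data.frame(h = h, n_otus = length(members),
                          n_filtered = length(big),
                          n_shared = length(shared),
                          n_ccs_only = length(ccs_only),
                          n_short_only = length(short_only)),
      sub_otus = sub_otus)
  }
  out
}
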