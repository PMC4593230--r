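# Agglomerative clustering of a dissimilarity matrix, threshold cutting,
# OTU tables and per-OTU summaries.

check_dist_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (is.null(rownames(D))) stop("D needs id dimnames")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-12)))
    stop("distance matrix is not symmetric")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
  if (any(D < 0 | D > 1)) stop("distances must lie in [0, 1]")
  invisible(D)
}

#' Agglomerative clustering of a distance matrix
#'
#' Hierarchical clustering via [stats::hclust()], the same engine used for
#' OTU inference throughout the package. Complete linkage is the default:
#' it guarantees that every cluster cut at height h has diameter at most h.
#' Leaves are ordered by id before clustering, so the merge tree does not
#' depend on the input order of the sequences.
#'
#' @param D symmetric dissimilarity matrix in `[0, 1]` with id dimnames.
#' @param method `"complete"` (default), `"average"` or `"single"`.
#' @return an [stats::hclust()] tree whose `labels` are the sequence ids.
#' @export
linkage <- function(D, method = c("complete", "average", "single")) {
  method <- match.arg(method)
  check_dist_matrix(D)
  if (nrow(D) < 2L) stop("need at least 2 sequences")
  ord <- order(rownames(D))
  stats::hclust(stats::as.dist(D[ord, ord, drop = FALSE]), method = method)
}

#' Cut a dendrogram at a dissimilarity threshold
#'
#' Clusters are the connected groups remaining when merges above height `h`
#' are undone; merges at exactly `h` are kept (inclusive cut), so cutting at
#' 0.03 corresponds to OTUs at 3 % sequence dissimilarity.
#'
#' @param dend an [stats::hclust()] tree from [linkage()].
#' @param h cut height in `[0, 1]`.
#' @return named integer vector mapping sequence id to cluster, with
#'   attribute `cut_height`.
#' @export
cut_tree <- function(dend, h) {
  if (h < 0 || h > 1) stop("cut height must lie in [0, 1]")
  part <- stats::cutree(dend, h = h)
  attr(part, "cut_height") <- h
  part
}

#' Number of singleton clusters
#'
#' @param partition named vector mapping id to cluster label.
#' @return integer count of clusters of size one.
#' @export
count_singletons <- function(partition) {
  sum(table(partition) == 1L)
}

#' Build an OTU-by-sample count table
#'
#' Counts reads per OTU and sample, together with per-sample normalized
#' abundances (count / sample total) and a per-sample centered and scaled
#' variant (mean 0, SD 1 per sample; the heat-map display convention).
#' OTUs are relabeled `OTU_1, OTU_2, ...` by decreasing total size, ties
#' broken by the lexicographically smallest member id.
#'
#' @param partition named cluster vector from [cut_tree()].
#' @param records a [seq_records()] table; every clustered id must have a
#'   record with a non-empty `sample_id`.
#' @return an object of class `otu_table`: list with `counts`, `normalized`
#'   and `scaled` matrices (rows OTUs, columns samples), `totals`,
#'   `singleton` flags, and `members` (list of read ids per OTU).
#' @export
otu_table <- function(partition, records) {
  ids <- names(partition)
  hit <- match(ids, records$id)
  if (anyNA(hit)) stop("partition id without record: ", ids[is.na(hit)][1L])
  samples <- records$sample_id[hit]
  if (any(!nzchar(samples)))
    stop("record without sample_id: ", ids[!nzchar(samples)][1L])

  members <- split(ids, partition)
  sizes <- lengths(members)
  first_id <- vapply(members, function(m) min(m), "")
  ord <- order(-sizes, first_id)
  members <- members[ord]
  names(members) <- paste0("OTU_", seq_along(members))

  sample_levels <- sort(unique(samples))
  counts <- do.call(rbind, lapply(members, function(m) {
    as.integer(table(factor(samples[match(m, ids)],
                            levels = sample_levels)))
  }))
  dimnames(counts) <- list(names(members), sample_levels)

  totals <- rowSums(counts)
  csum <- colSums(counts)
  normalized <- sweep(counts, 2L, pmax(csum, 1L), "/")
  scaled <- apply(normalized, 2L, function(x) {
    s <- sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  if (is.null(dim(scaled))) scaled <- matrix(scaled, nrow = nrow(counts),
                                             dimnames = dimnames(counts))
  structure(list(counts = counts, normalized = normalized, scaled = scaled,
                 totals = totals, singleton = totals == 1L,
                 members = members),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d OTUs x %d samples; %d reads; %d singletons\n",
              nrow(x$counts), ncol(x$counts), sum(x$totals),
              sum(x$singleton)))
  invisible(x)
}

#' Drop OTUs below a minimum read support
#'
#' Removes OTUs whose total read count is below `min_reads` ("at least 10
#' or more supporting reads"); counts of the surviving OTUs are unchanged,
#' and the operation is idempotent.
#'
#' @param tab an [otu_table()].
#' @param min_reads minimum total reads per OTU (inclusive; default 10).
#' @return the filtered `otu_table`.
#' @export
filter_min_size <- function(tab, min_reads = 10L) {
  if (min_reads < 1L) stop("min_reads must be >= 1")
  keep <- tab$totals >= min_reads
  structure(list(counts = tab$counts[keep, , drop = FALSE],
                 normalized = tab$normalized[keep, , drop = FALSE],
                 scaled = tab$scaled[keep, , drop = FALSE],
                 totals = tab$totals[keep], singleton = tab$singleton[keep],
                 members = tab$members[keep]),
            class = "otu_table")
}

#' Representative sequence of an OTU
#'
#' The member with the minimum mean genetic distance to all other members;
#' a singleton represents itself; exact ties resolve to the
#' lexicographically smallest id.
#'
#' @param members character vector of member ids.
#' @param D distance matrix containing all members.
#' @return a single id.
#' @export
representative <- function(members, D) {
  if (length(members) == 0L) stop("empty OTU")
  if (length(members) == 1L) return(members)
  if (!all(members %in% rownames(D)))
    stop("missing distance entries for: ",
         paste(setdiff(members, rownames(D)), collapse = ", "))
  sub <- D[members, members, drop = FALSE]
  mean_d <- rowSums(sub) / (length(members) - 1L)
  cand <- members[mean_d == min(mean_d)]
  sort(cand)[1L]
}

#' Representatives for every OTU of a table
#'
#' @param tab an [otu_table()].
#' @param D distance matrix over all clustered reads.
#' @return named character vector, OTU label -> representative read id.
#' @export
representatives <- function(tab, D) {
  vapply(tab$members, representative, "", D = D)
}

#' OTU quality diagnostics: small versus large OTUs
#'
#' Compares the mean per-read quality score of reads in small (< cutoff
#' reads) versus large (>= cutoff) OTUs, reporting group means and standard
#' two-sample statistics (Kolmogorov-Smirnov and Welch t). Low-quality
#' reads concentrating in small OTUs indicates that sequencing error, not
#' biology, is generating them.
#'
#' @param partition named cluster vector.
#' @param records a [seq_records()] table with qualities.
#' @param size_cutoff OTU size separating small from large (default 10).
#' @return list with per-group `n_otus`, `n_reads`, `mean`, `sd`, and
#'   `ks_p` / `t_p` p-values (`NA`, with `available = FALSE`, when a group
#'   is empty).
#' @export
otu_quality_diagnostics <- function(partition, records, size_cutoff = 10L) {
  ids <- names(partition)
  hit <- match(ids, records$id)
  if (anyNA(hit)) stop("partition id without record: ", ids[is.na(hit)][1L])
  mq <- vapply(records$quals[hit], function(q) {
    if (is.null(q)) stop("records must carry qualities")
    mean(q)
  }, 1.0)
  sizes <- table(partition)
  small <- partition %in% names(sizes)[sizes < size_cutoff]
  grp <- list(small = mq[small], large = mq[!small])
  n_otus <- c(small = sum(sizes < size_cutoff),
              large = sum(sizes >= size_cutoff))
  available <- all(lengths(grp) > 0L)
  ks_p <- t_p <- NA_real_
  if (available && all(lengths(grp) > 1L)) {
    ks_p <- suppressWarnings(ks.test(grp$small, grp$large)$p.value)
    t_p <- tryCatch(t.test(grp$small, grp$large)$p.value,
                    error = function(e) NA_real_) # constant data
  }
  list(size_cutoff = size_cutoff, n_otus = n_otus,
       n_reads = lengths(grp),
       mean = vapply(grp, function(x) if (length(x)) mean(x) else NA_real_, 1.0),
       sd = vapply(grp, function(x) if (length(x) > 1L) sd(x) else NA_real_, 1.0),
       ks_p = ks_p, t_p = t_p, available = available)
}

#' Write cluster membership as TSV
#'
#' Columns `read_id`, `otu_label`, `cut_height`.
#'
#' @param partition named cluster vector from [cut_tree()].
#' @param path output file.
#' @param labels optional named vector renaming clusters.
#' @return `path`, invisibly.
#' @export
write_membership_tsv <- function(partition, path, labels = NULL) {
  lab <- as.character(partition)
  if (!is.null(labels)) lab <- labels[lab]
  h <- attr(partition, "cut_height")
  tab <- data.frame(read_id = names(partition), otu_label = lab,
                    cut_height = if (is.null(h)) NA_real_ else h)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
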