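# Clustering-quality evaluation: adjusted Rand index, precision/recall,
# threshold sweeps, and cross-replicate medians.

align_partitions <- function(p, q) {
  if (is.null(names(p)) && is.null(names(q))) {
    if (length(p) != length(q)) stop("partitions differ in length")
    return(list(p = as.vector(p), q = as.vector(q)))
  }
  if (is.null(names(p)) || is.null(names(q)) ||
      !setequal(names(p), names(q)) || length(p) != length(q))
    stop("partitions must cover the same id set")
  list(p = as.vector(p), q = as.vector(q[names(p)]))
}

#' Adjusted Rand index of two partitions
#'
#' Hubert-Arabie chance-corrected Rand index:
#' `(sum_ij C(n_ij,2) - E) / (M - E)` with
#' `E = sum_i C(a_i,2) * sum_j C(b_j,2) / C(n,2)` and
#' `M = (sum_i C(a_i,2) + sum_j C(b_j,2)) / 2`, where `n_ij` is the
#' contingency table of the two partitions. 1 means identical partitions;
#' values near 0 mean chance-level agreement. The degenerate case `M == E`
#' (e.g. both partitions all singletons) returns 0 by convention.
#'
#' @param p,q named cluster vectors over the same ids (or unnamed vectors
#'   of equal length, matched by position).
#' @return numeric ARI.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)) # -0.5
#' @export
adjusted_rand_index <- function(p, q) {
  al <- align_partitions(p, q)
  tab <- table(al$p, al$q)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  E <- a * b / choose(n, 2)
  M <- (a + b) / 2
  if (M == E) return(0)
  (sum_ij - E) / (M - E)
}

#' Precision and recall of a clustering against ground truth
#'
#' Precision is cluster purity: the size-weighted mean, over inferred
#' clusters, of the largest truth-class fraction within the cluster.
#' Recall is the size-weighted mean, over truth classes, of the largest
#' fraction of the class kept in a single cluster. Both are 1 exactly when
#' the clustering reproduces the truth.
#'
#' @param p named cluster vector (inferred).
#' @param truth named cluster vector (ground truth), same ids.
#' @return named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(p, truth) {
  al <- align_partitions(p, truth)
  tab <- table(al$p, al$q)
  n <- sum(tab)
  c(precision = sum(apply(tab, 1L, max)) / n,
    recall = sum(apply(tab, 2L, max)) / n)
}

#' Sweep clustering thresholds and evaluate against truth
#'
#' Clusters the distance matrix once ([linkage()]), cuts at each threshold,
#' and reports OTU counts, singleton counts, ARI, precision and recall per
#' threshold. The row attaining the maximum ARI (first on ties) is exposed
#' via `attr(result, "best")` — the "best identity threshold" view.
#'
#' @param D distance matrix with id dimnames.
#' @param truth named cluster vector (ids -> genome of origin).
#' @param h_list thresholds (default 0.01 to 0.06 by 0.01).
#' @param method linkage method (default complete).
#' @return data.frame with columns `h`, `n_otus`, `n_singletons`, `ari`,
#'   `precision`, `recall`.
#' @export
threshold_sweep <- function(D, truth, h_list = seq(0.01, 0.06, by = 0.01),
                            method = "complete") {
  dend <- linkage(D, method = method)
  rows <- lapply(h_list, function(h) {
    part <- cut_tree(dend, h)
    pr <- precision_recall(part, truth)
    data.frame(h = h, n_otus = length(unique(part)),
               n_singletons = count_singletons(part),
               ari = adjusted_rand_index(part, truth),
               precision = pr[["precision"]], recall = pr[["recall"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "best") <- out[which.max(out$ari), , drop = FALSE]
  out
}

#' Median OTU counts across replicates
#'
#' Medians of `value` per (technology, h) cell; an even number of
#' replicates uses the mean-of-middle-two convention of [stats::median()].
#'
#' @param tab data.frame with columns `technology`, `h`, and `value`
#'   (or a column named by `value_col`).
#' @param value_col name of the value column (default `"n_otus"`).
#' @return data.frame with columns `technology`, `h`, `median`.
#' @export
median_otus <- function(tab, value_col = "n_otus") {
  if (!value_col %in% names(tab)) stop("no column ", value_col)
  agg <- stats::aggregate(tab[[value_col]],
                          by = list(technology = tab$technology, h = tab$h),
                          FUN = median)
  names(agg)[3L] <- "median"
  agg[order(agg$technology, agg$h), , drop = FALSE]
}

#' Linear model of clustering quality against read length
#'
#' Reporting helper fitting `ari ~ read_length` by ordinary least squares
#' followed by ANOVA — the routine check that clustering quality improves
#' with longer reads.
#'
#' @param tab data.frame with numeric columns `ari` and `read_length`.
#' @return list with the `lm` fit and its `anova` table.
#' @export
ari_read_length_model <- function(tab) {
  fit <- stats::lm(ari ~ read_length, data = tab)
  list(fit = fit, anova = stats::anova(fit))
}
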