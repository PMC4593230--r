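# Independent oracles and fixture builders used across the test files.
# These re-derive expected values from first principles and never call the
# package's own hot paths.

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# --- exhaustive affine-gap global alignment score (independent DP) --------
# Full-matrix three-state recursion written directly from the gap-cost
# definition: a gap run of length L costs gap_open + L * gap_extend.
oracle_nw_score <- function(a, b, match = 5, mismatch = -4,
                            gap_open = 10, gap_extend = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e30
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(gap_open + i * gap_extend)
  for (j in seq_len(m)) Y[1, j + 1] <- -(gap_open + j * gap_extend)
  sub <- function(x, y) {
    if (x == "N" || y == "N") 0 else if (x == y) match else mismatch
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sub(av[i], bv[j])
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend,
                             Y[i, j + 1] - gap_open - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             X[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# score an alignment's two gapped rows directly from the definition
score_alignment_rows <- function(ra, rb, match = 5, mismatch = -4,
                                 gap_open = 10, gap_extend = 0.5) {
  av <- strsplit(ra, "")[[1]]
  bv <- strsplit(rb, "")[[1]]
  s <- 0
  for (run in c("a", "b")) {
    gaps <- if (run == "a") av == "-" else bv == "-"
    r <- rle(gaps)
    s <- s - sum(gap_open + r$lengths[r$values] * gap_extend)
  }
  plain <- av != "-" & bv != "-"
  xa <- av[plain]; xb <- bv[plain]
  ncol_ <- xa == "N" | xb == "N"  # N columns score 0
  s + sum(ifelse(xa[!ncol_] == xb[!ncol_], match, mismatch))
}

# --- naive O(n^3) agglomerative clustering oracle -------------------------
oracle_linkage_heights <- function(D, method) {
  upd <- switch(method, complete = max, single = min, average = mean)
  clusters <- as.list(rownames(D))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- upd(D[clusters[[i]], clusters[[j]]])
        if (d < best) { best <- d; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# cut the naive agglomeration at height h -> number of clusters
oracle_cut_count <- function(D, method, h) {
  upd <- switch(method, complete = max, single = min, average = mean)
  clusters <- as.list(rownames(D))
  repeat {
    if (length(clusters) == 1) break
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- upd(D[clusters[[i]], clusters[[j]]])
        if (d < best) { best <- d; bi <- i; bj <- j }
      }
    }
    if (best > h) break
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  length(clusters)
}

# random symmetric distance matrix with unique off-diagonal values
rand_dist_matrix <- function(n) {
  vals <- sample(seq(0.01, 0.99, length.out = n * (n - 1) / 2))
  D <- matrix(0, n, n, dimnames = list(letters[seq_len(n)],
                                       letters[seq_len(n)]))
  D[upper.tri(D)] <- vals
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}

# --- pair-counting adjusted Rand index ------------------------------------
oracle_ari <- function(p, q) {
  if (!is.null(names(p))) q <- q[names(p)]
  n <- length(p)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sp <- p[i] == p[j]; sq <- q[i] == q[j]
      if (sp && sq) a <- a + 1
      else if (sp) b <- b + 1
      else if (sq) cc <- cc + 1
      else d <- d + 1
    }
  }
  den <- (a + b) * (b + d) + (a + cc) * (cc + d)
  if (den == 0) return(0)
  2 * (a * d - b * cc) / den
}

rand_partition <- function(n, k) {
  stats::setNames(sample.int(k, n, replace = TRUE),
                  sprintf("s%02d", seq_len(n)))
}

# substitute exactly k distinct positions with a different base
substitute_chars <- function(seq, k) {
  x <- strsplit(seq, "")[[1]]
  pos <- sample(length(x), k)
  for (p in pos) {
    x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
  }
  x
}

# delete k single bases at well-separated internal positions (>= 10 apart,
# away from the ends) so each becomes an isolated single-base indel
delete_spread_bases <- function(seq, k) {
  n <- nchar(seq)
  pos <- sort(sample(seq(20, n - 20, by = 15), k))
  x <- strsplit(seq, "")[[1]]
  paste(x[-pos], collapse = "")
}

# --- fixture records ------------------------------------------------------
fixture_records <- function() {
  seq_records(
    id = c("r1", "r2", "r3"),
    seq = c("ACGTACGTAC", "TTGCAACGTT", "ACGTACGTTT"),
    sample_id = c("s1", "s1", "s2"),
    technology = "ccs",
    quals = list(rep(40L, 10), c(rep(40L, 5), rep(20L, 5)), rep(30L, 10)),
    passes = c(15L, 8L, 22L)
  )
}
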