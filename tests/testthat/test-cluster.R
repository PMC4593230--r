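test_that("linkage merge heights match the naive agglomerative oracle", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    D <- rand_dist_matrix(n)
    for (method in c("complete", "average", "single")) {
      dend <- linkage(D, method)
      expect_equal(dend$height, oracle_linkage_heights(D, method),
                   tolerance = 1e-12)
    }
  }
})

test_that("two leaves merge at their distance under every method", {
  D <- matrix(c(0, 0.04, 0.04, 0), 2, 2, dimnames = list(c("a", "b"),
                                                         c("a", "b")))
  for (method in c("complete", "average", "single")) {
    expect_equal(linkage(D, method)$height, 0.04)
  }
})

test_that("linkage validates its input matrix", {
  D <- rand_dist_matrix(4)
  bad <- D; bad[1, 2] <- bad[1, 2] + 0.1
  expect_error(linkage(bad), "symmetric")
  bad2 <- D; bad2[1, 2] <- bad2[2, 1] <- 1.5
  expect_error(linkage(bad2), "\\[0, 1\\]")
  bad3 <- D; diag(bad3)[1] <- 0.2
  expect_error(linkage(bad3), "diagonal")
})

test_that("linkage result is independent of leaf input order", {
  set.seed(22)
  D <- rand_dist_matrix(8)
  dend1 <- linkage(D, "complete")
  perm <- sample(8)
  dend2 <- linkage(D[perm, perm], "complete")
  for (h in c(0.1, 0.3, 0.6)) {
    p1 <- cut_tree(dend1, h)
    p2 <- cut_tree(dend2, h)
    expect_equal(adjusted_rand_index(p1, p2[names(p1)]), 1)
  }
})

test_that("cut_tree is inclusive at h and monotone in h", {
  set.seed(23)
  D <- rand_dist_matrix(10)
  dend <- linkage(D, "complete")
  # inclusive: cutting exactly at a merge height keeps that merge
  h1 <- dend$height[1]
  part <- cut_tree(dend, h1)
  expect_equal(length(unique(part)), 9L)
  expect_equal(length(unique(cut_tree(dend, 0))), 10L)
  expect_equal(length(unique(cut_tree(dend, max(dend$height)))), 1L)
  hs <- seq(0.01, 0.99, by = 0.07)
  counts <- vapply(hs, function(h) length(unique(cut_tree(dend, h))), 1L)
  expect_true(all(diff(counts) <= 0))
  expect_error(cut_tree(dend, 1.5), "\\[0, 1\\]")
})

test_that("cut counts match the naive oracle across 0.01..0.06", {
  set.seed(24)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    # distances concentrated in the OTU-threshold range
    vals <- sample(seq(0.005, 0.12, length.out = n * (n - 1) / 2))
    D <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    D[upper.tri(D)] <- vals
    D[lower.tri(D)] <- t(D)[lower.tri(D)]
    dend <- linkage(D, "complete")
    for (h in seq(0.01, 0.06, by = 0.01)) {
      expect_equal(length(unique(cut_tree(dend, h))),
                   oracle_cut_count(D, "complete", h))
    }
  }
})

test_that("complete-linkage clusters never exceed the cut diameter", {
  set.seed(25)
  D <- rand_dist_matrix(12)
  dend <- linkage(D, "complete")
  for (h in c(0.05, 0.2, 0.5, 0.8)) {
    part <- cut_tree(dend, h)
    for (cl in split(names(part), part)) {
      if (length(cl) > 1) expect_lte(max(D[cl, cl]), h)
    }
  }
})

test_that("otu_table counts, normalizes and labels by size", {
  rec <- seq_records(sprintf("r%d", 1:10),
                     replicate(10, rand_dna(20)),
                     sample_id = rep(c("s1", "s2"), each = 5),
                     technology = "ccs")
  part <- stats::setNames(c(1, 1, 1, 1, 2, 1, 1, 2, 2, 3), rec$id)
  tab <- otu_table(part, rec)
  expect_equal(sum(tab$counts), 10)
  expect_equal(rownames(tab$counts), c("OTU_1", "OTU_2", "OTU_3"))
  expect_equal(unname(tab$totals), c(6, 3, 1))
  expect_equal(unname(tab$singleton), c(FALSE, FALSE, TRUE))
  expect_equal(colSums(tab$normalized), c(s1 = 1, s2 = 1))
  # 4 reads, 2 samples, 2 OTUs, balanced -> all normalized 0.5
  rec4 <- seq_records(letters[1:4], replicate(4, rand_dna(20)),
                      sample_id = c("s1", "s2", "s1", "s2"))
  part4 <- stats::setNames(c(1, 1, 2, 2), rec4$id)
  tab4 <- otu_table(part4, rec4)
  expect_true(all(tab4$counts == 1))
  expect_true(all(tab4$normalized == 0.5))
  # single OTU: normalized abundance 1 in every sample with reads
  part1 <- stats::setNames(rep(1, 4), rec4$id)
  expect_true(all(otu_table(part1, rec4)$normalized == 1))
  # errors
  expect_error(otu_table(stats::setNames(1, "zz"), rec4), "without record")
  rec_nos <- rec4; rec_nos$sample_id[1] <- ""
  expect_error(otu_table(part4, rec_nos), "sample_id")
})

test_that("filter_min_size is inclusive at the threshold and idempotent", {
  rec <- seq_records(sprintf("r%d", 1:20), replicate(20, rand_dna(20)),
                     sample_id = "s1")
  part <- stats::setNames(c(rep(1, 10), rep(2, 9), 3), rec$id)
  tab <- otu_table(part, rec)
  f10 <- filter_min_size(tab, 10)
  expect_equal(nrow(f10$counts), 1L)          # the 9-read OTU is removed
  expect_equal(unname(f10$totals), 10)        # exactly 10 reads kept
  expect_equal(f10$counts, filter_min_size(f10, 10)$counts)
  f1 <- filter_min_size(tab, 1)
  expect_equal(f1$counts, tab$counts)
  expect_error(filter_min_size(tab, 0), ">= 1")
})

test_that("count_singletons counts size-1 clusters", {
  expect_equal(count_singletons(stats::setNames(1:4, letters[1:4])), 4L)
  expect_equal(count_singletons(stats::setNames(rep(1, 4), letters[1:4])),
               0L)
  expect_equal(count_singletons(stats::setNames(c(1, 2, 2, 3),
                                                letters[1:4])), 2L)
})

test_that("representative minimizes mean distance with lexical ties", {
  D <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  D["a", "b"] <- D["b", "a"] <- 0.01
  D["a", "c"] <- D["c", "a"] <- 0.01
  D["b", "c"] <- D["c", "b"] <- 0.05
  expect_equal(representative(c("a", "b", "c"), D), "a")
  expect_equal(representative("zz", D), "zz")  # singleton
  Dt <- matrix(0.02, 3, 3, dimnames = dimnames(D)); diag(Dt) <- 0
  expect_equal(representative(c("c", "b", "a"), Dt), "a")
  expect_error(representative(c("a", "q"), D), "missing")
})

test_that("quality diagnostics separate low-quality small OTUs", {
  set.seed(26)
  n_small <- 30; n_large <- 30
  rec <- seq_records(
    sprintf("r%d", 1:(n_small + n_large)),
    replicate(n_small + n_large, rand_dna(30)),
    quals = c(lapply(seq_len(n_small), function(i)
                rep(20L, 30) + sample(-3:3, 30, TRUE)),
              lapply(seq_len(n_large), function(i)
                rep(40L, 30) + sample(-3:3, 30, TRUE)))
  )
  part <- stats::setNames(c(seq_len(n_small), rep(100, n_large)), rec$id)
  rep_ <- otu_quality_diagnostics(part, rec, size_cutoff = 10)
  expect_true(rep_$available)
  expect_lt(rep_$mean[["small"]], rep_$mean[["large"]])
  expect_lt(rep_$ks_p, 0.01)
  expect_lt(rep_$t_p, 0.01)
  # identical qualities: equal group means
  rec2 <- rec
  rec2$quals <- rep(list(rep(30L, 30)), nrow(rec))
  rep2 <- otu_quality_diagnostics(part, rec2, size_cutoff = 10)
  expect_equal(rep2$mean[["small"]], rep2$mean[["large"]])
  # cutoff larger than every OTU: large group empty, marked unavailable
  rep3 <- otu_quality_diagnostics(part, rec, size_cutoff = 1000)
  expect_false(rep3$available)
  expect_true(is.na(rep3$ks_p))
})
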