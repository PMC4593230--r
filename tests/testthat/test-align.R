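test_that("trivial alignments behave as expected", {
  a <- nw_align("ACGT", "ACGT")
  expect_equal(a$row_a, "ACGT")
  expect_equal(a$mismatches, 0L)
  expect_equal(a$indel_events, 0L)
  expect_equal(a$examined_columns, 4L)
  expect_error(nw_align("", "ACGT"), "non-empty")
  # prohibitive gap cost on equal-length inputs forces a gapless alignment
  g <- nw_align("ACGTTT", "TTTACG",
                scoring = list(match = 5, mismatch = -4,
                               gap_open = 1e6, gap_extend = 1))
  expect_false(grepl("-", g$row_a))
  expect_false(grepl("-", g$row_b))
})

test_that("nw_align matches an independent full-matrix DP on random pairs", {
  set.seed(11)
  for (i in 1:60) {
    a <- rand_dna(sample(1:10, 1))
    b <- rand_dna(sample(1:10, 1))
    aln <- nw_align(a, b)
    expect_equal(aln$score, oracle_nw_score(a, b), tolerance = 1e-12)
    # the emitted rows really attain the reported score
    expect_equal(score_alignment_rows(aln$row_a, aln$row_b), aln$score,
                 tolerance = 1e-12)
    # and decode back to the inputs
    expect_equal(gsub("-", "", aln$row_a), a)
    expect_equal(gsub("-", "", aln$row_b), b)
  }
})

test_that("alignment is deterministic and band-insensitive for close pairs", {
  set.seed(5)
  a <- rand_dna(300)
  b <- paste(substitute_chars(a, 6), collapse = "")
  a1 <- nw_align(a, b)
  a2 <- nw_align(a, b)
  expect_identical(a1, a2)
  ab <- nw_align(a, b, band = 30)
  expect_equal(ab$score, a1$score)
})

test_that("strip_terminal_gaps removes terminal runs in either row", {
  aln <- list(row_a = "--ACGT", row_b = "GGACGT", score = 0,
              scoring = longotu:::default_scoring())
  class(aln) <- "pairwise_alignment"
  out <- strip_terminal_gaps(aln)
  expect_equal(out$row_a, "ACGT")
  expect_equal(out$row_b, "ACGT")
  aln2 <- list(row_a = "AC--", row_b = "ACGT", score = 0,
               scoring = longotu:::default_scoring())
  class(aln2) <- "pairwise_alignment"
  out2 <- strip_terminal_gaps(aln2)
  expect_equal(out2$row_a, "AC")
  expect_equal(out2$row_b, "AC")
  gapless <- nw_align("ACGT", "ACGT")
  expect_equal(strip_terminal_gaps(gapless)$row_a, "ACGT")
  # non-overlapping pair collapses to nothing
  aln3 <- list(row_a = "AA--", row_b = "--TT", score = 0,
               scoring = longotu:::default_scoring())
  class(aln3) <- "pairwise_alignment"
  expect_error(strip_terminal_gaps(aln3), "overlap")
})

test_that("remove_single_base_indels drops length-1 runs only", {
  mk <- function(ra, rb) {
    x <- list(row_a = ra, row_b = rb, score = 0,
              scoring = longotu:::default_scoring())
    class(x) <- "pairwise_alignment"
    x
  }
  out <- remove_single_base_indels(mk("AC-GT", "ACTGT"))
  expect_equal(out$row_a, "ACGT")
  expect_equal(out$row_b, "ACGT")
  out2 <- remove_single_base_indels(mk("AC--GT", "ACTTGT"))
  expect_equal(out2$row_a, "AC--GT") # run of length 2 untouched
  out3 <- remove_single_base_indels(mk("ACGT", "ACGT"))
  expect_equal(out3$row_a, "ACGT")
})

test_that("genetic_distance implements the collapsed-indel definition", {
  # 8 gapless columns, 1 mismatch
  aln <- nw_align("ACGTACGT", "ACGTACTT")
  expect_equal(genetic_distance(aln), 1 / 8)
  # one internal single-base indel vanishes in post-processing
  d <- genetic_distance(postprocess_alignment(nw_align("ACGTTACGT",
                                                       "ACGTACGT")))
  expect_equal(d, 0)
  # identical sequences
  s <- rand_dna(100)
  expect_equal(genetic_distance(nw_align(s, s)), 0)
  # a surviving 3-base gap run counts once, denominator collapsed vs full
  mk <- function(ra, rb) {
    x <- list(row_a = ra, row_b = rb, score = 0,
              scoring = longotu:::default_scoring())
    class(x) <- "pairwise_alignment"
    x
  }
  aln3 <- mk("AAA---TTTT", "AAACCCTTTT")
  expect_equal(genetic_distance(aln3, collapse_runs = TRUE), 1 / 8)
  expect_equal(genetic_distance(aln3, collapse_runs = FALSE), 1 / 10)
  # N columns excluded from both counts
  alnN <- mk("ANGT", "ACGT")
  expect_equal(genetic_distance(alnN), 0)
  # swapping rows leaves the distance unchanged
  expect_equal(genetic_distance(mk("AC-GTA", "ACCGTT")),
               genetic_distance(mk("ACCGTT", "AC-GTA")))
})

test_that("k spread single-base indels yield distance 0, k substitutions k/n", {
  set.seed(19)
  base <- rand_dna(500)
  for (k in 1:5) {
    mutated <- delete_spread_bases(base, k)
    d <- genetic_distance(postprocess_alignment(nw_align(base, mutated)))
    expect_equal(d, 0)
    subbed <- paste(substitute_chars(base, k), collapse = "")
    d2 <- genetic_distance(postprocess_alignment(nw_align(base, subbed)))
    expect_equal(d2, k / 500)
  }
})

test_that("orient flips reverse-complemented records and keeps ties", {
  set.seed(3)
  anchors <- seq_records("anc", rand_dna(120))
  fwd <- seq_records("f", anchors$seq, quals = list(rep(40L, 120)))
  rc <- seq_records("r", revcomp(anchors$seq),
                    quals = list(seq_len(120) %% 41L))
  out_f <- orient(fwd, anchors = anchors)
  expect_equal(out_f$seq, fwd$seq)
  out_r <- orient(rc, anchors = anchors)
  expect_equal(out_r$seq, anchors$seq)
  expect_equal(out_r$quals[[1]], rev(rc$quals[[1]]))
})
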