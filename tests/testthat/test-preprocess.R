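test_that("merge_pairs trims, reverse-complements and inserts the spacer", {
  r1 <- seq_records("p", "ACGT", sample_id = "s1",
                    quals = list(c(40L, 40L, 40L, 40L)))
  r2 <- seq_records("p/2", "AAAAAATT", quals = list(rep(30L, 8)))
  m <- merge_pairs(r1, r2, trim_tail = 2, spacer_len = 3)
  expect_equal(m$seq, "ACGTNNNTTTTTT")
  expect_equal(nchar(m$seq), 13L)
  expect_equal(m$spacer_start, 5L)
  expect_equal(m$spacer_end, 7L)
  expect_equal(m$quals[[1]], c(rep(40L, 4), rep(0L, 3), rep(30L, 6)))
  expect_equal(m$technology, "short_merged")
  expect_equal(m$sample_id, "s1")
})

test_that("merged length follows the trim/spacer arithmetic", {
  r1 <- seq_records("a", rand_dna(250))
  r2 <- seq_records("b", rand_dna(250))
  m <- merge_pairs(r1, r2, trim_tail = 42, spacer_len = 42)
  expect_equal(nchar(m$seq), 250 + 42 + 208)
  # trim_tail = 0, spacer 0, r2 = revcomp(r1): merged is r1 twice
  r3 <- seq_records("c", revcomp(r1$seq))
  m2 <- merge_pairs(r1, r3, trim_tail = 0, spacer_len = 0)
  expect_equal(m2$seq, paste0(r1$seq, r1$seq))
  expect_true(is.na(m2$spacer_start))
  expect_error(merge_pairs(r1, seq_records("d", "ACG"), trim_tail = 3),
               "trim_tail")
})

test_that("quality_fraction_filter counts qualifying positions", {
  all40 <- seq_records("a", rand_dna(100), quals = list(rep(40L, 100)))
  expect_true(quality_fraction_filter(all40, 30, 0.9, strict = TRUE))
  # 15 positions at Q20, 85 at Q40: fails 90 %
  mixed <- seq_records("b", rand_dna(100),
                       quals = list(c(rep(20L, 15), rep(40L, 85))))
  expect_false(quality_fraction_filter(mixed, 30, 0.90, strict = TRUE))
  expect_true(quality_fraction_filter(mixed, 30, 0.85, strict = TRUE))
  # strict flag: exactly Q30 positions count only under >=
  q30 <- seq_records("c", rand_dna(10), quals = list(rep(30L, 10)))
  expect_false(quality_fraction_filter(q30, 30, 0.9, strict = TRUE))
  expect_true(quality_fraction_filter(q30, 30, 0.9, strict = FALSE))
  expect_error(quality_fraction_filter(seq_records("d", "ACGT"), 30, 0.9),
               "qualities")
})

test_that("spacer positions are excluded when requested", {
  # 100 real positions (97 at Q40, 3 at Q10) + 42-bp spacer at quality 0
  r1 <- seq_records("a", rand_dna(100),
                    quals = list(c(rep(40L, 97), rep(10L, 3))))
  r2 <- seq_records("b", rand_dna(42), quals = list(rep(40L, 42)))
  m <- merge_pairs(r1, r2, trim_tail = 0, spacer_len = 42)
  # merged: 100 + 42 spacer + 42; of the 142 real positions 139 are >= 30
  expect_true(quality_fraction_filter(m, 30, 139 / 142, strict = FALSE,
                                      exclude_spacer = TRUE))
  expect_false(quality_fraction_filter(m, 30, 139 / 142, strict = FALSE,
                                       exclude_spacer = FALSE))
})

test_that("quality filter is monotone in its thresholds", {
  set.seed(42)
  for (i in 1:20) {
    rec <- seq_records("x", rand_dna(50),
                       quals = list(sample(0:45, 50, replace = TRUE)))
    for (mq in c(20, 30)) {
      fr <- runif(1)
      pass_lo <- quality_fraction_filter(rec, mq, fr)
      pass_hi <- quality_fraction_filter(rec, mq, min(1, fr + 0.2))
      pass_q <- quality_fraction_filter(rec, mq + 10, fr)
      if (!pass_lo) {
        expect_false(pass_hi)
        expect_false(pass_q)
      }
    }
  }
})

test_that("length_filter uses inclusive +/- tolerance bounds", {
  rec <- seq_records(c("a", "b", "c"),
                     c(rand_dna(826), rand_dna(726), rand_dna(625)))
  expect_equal(length_filter(rec, 826, 100), c(TRUE, TRUE, FALSE))
  expect_error(length_filter(rec, 0), "positive")
})

test_that("demultiplex assigns by exact 5' barcode and partitions input", {
  specs <- data.frame(sample_id = c("s1", "s2"),
                      barcode = c("ACGTACGT", "TTTTAAAA"),
                      primer = c("GTGYCAGC", NA))
  payload <- rand_dna(30)
  rec <- seq_records(
    id = c("hit1", "hit_primer", "mismatch", "other"),
    seq = c(paste0("ACGTACGT", payload),
            paste0("ACGTACGT", "GTGCCAGC", payload),
            paste0("ACGTACGA", payload),   # 1 mismatch in barcode
            paste0("TTTTAAAA", payload)),
    quals = list(rep(40L, 38), rep(40L, 46), rep(40L, 38), rep(40L, 38))
  )
  res <- demultiplex(rec, specs)
  expect_equal(sort(res$samples$s1$id), c("hit1", "hit_primer"))
  expect_equal(res$samples$s1$seq[res$samples$s1$id == "hit1"], payload)
  # primer stripped too (IUPAC Y matches C)
  expect_equal(res$samples$s1$seq[res$samples$s1$id == "hit_primer"],
               payload)
  expect_equal(res$samples$s2$id, "other")
  expect_equal(res$unassigned$id, "mismatch")
  n_assigned <- sum(vapply(res$samples, nrow, 1L))
  expect_equal(n_assigned + nrow(res$unassigned), nrow(rec))
  # qualities trimmed along with the sequence
  expect_equal(lengths(res$samples$s1$quals),
               nchar(res$samples$s1$seq))
  dup <- specs; dup$barcode <- c("ACGTACGT", "ACGTACGT")
  expect_error(demultiplex(rec, dup), "duplicate")
})

test_that("shuffle_records is a seeded permutation", {
  rec <- seq_records(sprintf("r%02d", 1:20), replicate(20, rand_dna(15)))
  a <- shuffle_records(rec, seed = 7)
  b <- shuffle_records(rec, seed = 7)
  expect_identical(a, b)
  expect_setequal(a$id, rec$id)
  expect_false(identical(a$id, rec$id))
  one <- shuffle_records(rec[1, ], seed = 1)
  expect_identical(one$id, rec$id[1])
})
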