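test_that("synthetic reference databases are seeded and hierarchical", {
  db1 <- synth_reference_db(5, 4, seed = 2)
  db2 <- synth_reference_db(5, 4, seed = 2)
  db3 <- synth_reference_db(5, 4, seed = 3)
  expect_identical(db1, db2)
  expect_false(identical(db1$seq, db3$seq))
  expect_equal(nrow(db1), 20L)
  expect_true(all(nchar(db1$seq) > 1400))
  expect_false(anyDuplicated(db1$seq) > 0)
  expect_error(synth_reference_db(5, 4, genus_divergence = 0.6), "0.5")
  expect_error(synth_reference_db(5, 4, within_genus_divergence = 0),
               "0.5")
})

test_that("within-genus divergence matches its closed-form expectation", {
  q <- 0.03
  db <- synth_reference_db(10, 5, within_genus_divergence = q, seed = 4)
  genus <- sub("_.*$", "", db$id)
  # two leaves of one ancestor differ per site with prob 2q(1-q) + (2/3)q^2
  p_exp <- 2 * q * (1 - q) + (2 / 3) * q^2
  obs <- c()
  for (g in unique(genus)) {
    members <- db$seq[genus == g]
    m1 <- strsplit(members[1], "")[[1]]
    for (k in 2:length(members)) {
      obs <- c(obs, mean(m1 != strsplit(members[k], "")[[1]]))
    }
  }
  se <- sqrt(p_exp * (1 - p_exp) / 1500 / length(obs))
  expect_lt(abs(mean(obs) - p_exp), 3 * se + 1e-4)
})

test_that("filter_reference_db removes duplicates, shorts, oversized genera", {
  base <- synth_reference_db(2, 3, seed = 5)
  dup <- base[1, ]; dup$id <- "genus001_copy"
  shorty <- seq_records("genus002_short", rand_dna(1399))
  db <- bind_records(list(base, dup, shorty))
  out <- filter_reference_db(db)
  expect_equal(nrow(out), nrow(base))
  expect_false("genus002_short" %in% out$id)
  # genus with > max_per_genus members is down-sampled to downsample_to
  big <- seq_records(sprintf("genusX_g%04d", 1:12),
                     replicate(12, rand_dna(1450)))
  out2 <- filter_reference_db(big, max_per_genus = 10, downsample_to = 4,
                              seed = 1)
  expect_equal(nrow(out2), 4L)
})

test_that("build_mocks samples without replacement, deterministically", {
  db <- synth_reference_db(12, 10, seed = 6)
  mocks <- build_mocks(db, "low", n_replicates = 3, seed = 9)
  expect_length(mocks, 3L)
  for (m in mocks) {
    expect_equal(nrow(m$genomes), 100L)
    expect_false(anyDuplicated(m$genomes$id) > 0)
  }
  mocks2 <- build_mocks(db, "low", n_replicates = 3, seed = 9)
  expect_identical(mocks[[1]]$genomes$id, mocks2[[1]]$genomes$id)
  expect_error(build_mocks(db[1:50, ], "low"), "too small")
  small <- build_mocks(db, "low", 1, seed = 1, n_genomes = 10)
  expect_equal(nrow(small[[1]]$genomes), 10L)
})

test_that("extract_amplicon handles interval and primer modes", {
  g <- seq_records("g1", paste0("TTTT", "GTGCCAGCAGCCGCGGTAA",
                                rand_dna(80), "ATTAGATACCCTGGTAGTCC",
                                "GGGG"))
  whole <- extract_amplicon(g, amplicon_spec(start = 1,
                                             end = nchar(g$seq)))
  expect_equal(whole$seq, g$seq)
  expect_equal(whole$technology, "amplicon")
  # degenerate forward primer (M -> A) and reverse primer on minus strand
  sp <- amplicon_spec(forward = "GTGCCAGCMGCCGCGGTAA",
                      reverse = "GGACTACCAGGGTATCTAAT")
  amp <- extract_amplicon(g, sp)
  expect_equal(substr(amp$seq, 1, 19), "GTGCCAGCAGCCGCGGTAA")
  expect_true(endsWith(amp$seq, "ATTAGATACCCTGGTAGTCC"))
  # reverse-complemented genome yields the same product on the plus strand
  grc <- seq_records("g1rc", revcomp(g$seq))
  amp2 <- extract_amplicon(grc, sp)
  expect_equal(amp2$seq, amp$seq)
  expect_error(extract_amplicon(g, amplicon_spec(forward = "AAAAAAAAGG",
                                                 reverse = "CCTTTTTTTT")),
               "not found")
  expect_error(amplicon_spec(start = 1, forward = "ACGT"), "exactly one")
})

test_that("CCS reads at forced accuracy 1 reproduce the amplicon", {
  amp <- seq_records("a_amp", rand_dna(300), technology = "amplicon")
  model <- error_model_ccs(accuracy_mean = 1, accuracy_sd = 0)
  reads <- sim_ccs_reads(amp, 5, model = model, seed = 1)
  expect_true(all(reads$seq == amp$seq))
  expect_true(all(vapply(reads$quals, function(q) all(q == 93L), TRUE)))
  expect_true(all(reads$passes >= 1L))
})

test_that("CCS error rate and type ratio match the model", {
  amp <- seq_records("a_amp", rand_dna(1000), technology = "amplicon")
  model <- error_model_ccs(accuracy_mean = 0.99, accuracy_sd = 1e-9)
  reads <- sim_ccs_reads(amp, 60, model = model, seed = 2)
  # observed edit events per simulated base ~ Binomial(n*len, 0.01)
  nb <- 60 * 1000
  # count alignment differences without the single-indel collapse
  raw <- lapply(reads$seq, function(s)
    strip_terminal_gaps(nw_align(amp$seq, s, band = 60)))
  n_sub <- sum(vapply(raw, function(a) a$mismatches, 1L))
  gaps <- vapply(raw, function(a) {
    ch <- strsplit(c(a$row_a, a$row_b), "")
    ra <- rle(ch[[1]] == "-"); rb <- rle(ch[[2]] == "-")
    c(sum(ra$lengths[ra$values]), sum(rb$lengths[rb$values]))
  }, c(ins = 1, del = 1))
  n_ins <- sum(gaps[1, ]); n_del <- sum(gaps[2, ])
  n_err <- n_sub + n_ins + n_del
  se <- sqrt(nb * 0.01 * 0.99)
  expect_lt(abs(n_err - nb * 0.01), 4 * se)
  # 6:21:73 ratio: chi-square goodness of fit not rejected at alpha 0.01
  chi <- stats::chisq.test(c(n_sub, n_ins, n_del),
                           p = c(6, 21, 73) / 100)
  expect_gt(chi$p.value, 0.01)
  # deletions dominate insertions which dominate substitutions
  expect_gt(n_del, n_ins)
  expect_gt(n_ins, n_sub)
})

test_that("CCS error placement is uniform along the read", {
  amp <- seq_records("a_amp", rand_dna(500), technology = "amplicon")
  model <- error_model_ccs(accuracy_mean = 0.96, accuracy_sd = 1e-9)
  reads <- sim_ccs_reads(amp, 80, model = model, seed = 7)
  # recover error positions in template coordinates from the alignment
  pos <- unlist(lapply(reads$seq, function(s) {
    aln <- strip_terminal_gaps(nw_align(amp$seq, s, band = 60))
    ra <- strsplit(aln$row_a, "")[[1]]
    rb <- strsplit(aln$row_b, "")[[1]]
    tpos <- cumsum(ra != "-") # template coordinate per column
    tpos[ra == "-" | rb == "-" | ra != rb]
  }))
  # uniform placement: mean error position near the read midpoint
  se <- 500 / sqrt(12) / sqrt(length(pos))
  expect_lt(abs(mean(pos) - 250), 5 * se + 10)
})

test_that("merged short reads have fixed structure and length", {
  amp <- seq_records("a_amp", rand_dna(413), technology = "amplicon")
  model <- error_model_short(150, 1e-12, 1e-12)  # error-free limit
  reads <- sim_short_reads(amp, 3, model = model, seed = 3)
  expect_true(all(nchar(reads$seq) == 2 * 150 + 10))
  expected <- paste0(substr(amp$seq, 1, 150), strrep("N", 10),
                     substr(amp$seq, 413 - 150 + 1, 413))
  expect_true(all(reads$seq == expected))
  expect_equal(reads$spacer_start[1], 151L)
  expect_equal(reads$spacer_end[1], 160L)
  expect_error(sim_short_reads(seq_records("x", rand_dna(100)), 2,
                               model = model), "read length")
})

test_that("fused short-read merge equals the merge_pairs composition", {
  amp <- seq_records("a_amp", rand_dna(400), technology = "amplicon",
                     sample_id = "s1")
  model <- error_model_short(150, 1e-12, 1e-12)
  got <- sim_short_reads(amp, 1, model = model, seed = 4)
  q <- longotu:::phred_of(rep(model$base_rate, 150))
  r1 <- seq_records("m/1", substr(amp$seq, 1, 150), sample_id = "s1",
                    quals = list(rep(q[1], 150)))
  r2 <- seq_records("m/2", revcomp(substr(amp$seq, 251, 400)),
                    quals = list(rep(q[1], 150)))
  ref <- merge_pairs(r1, r2, trim_tail = 0, spacer_len = 10)
  expect_equal(got$seq, ref$seq)
  expect_equal(got$quals[[1]], ref$quals[[1]])
  expect_equal(got$spacer_start, ref$spacer_start)
})

test_that("downsample_per_genome keeps exactly k seeded reads per genome", {
  reads <- seq_records(sprintf("r%02d", 1:30), replicate(30, rand_dna(20)))
  truth <- data.frame(read_id = reads$id,
                      genome_id = rep(c("g1", "g2", "g3"), each = 10))
  out <- downsample_per_genome(reads, truth, k = 4, seed = 11)
  expect_equal(nrow(out$reads), 12L)
  expect_equal(unname(table(out$truth$genome_id)), rep(4L, 3),
               ignore_attr = TRUE)
  out2 <- downsample_per_genome(reads, truth, k = 4, seed = 11)
  expect_identical(out$reads$id, out2$reads$id)
  all10 <- downsample_per_genome(reads, truth, k = 10, seed = 1)
  expect_equal(all10$reads$id, reads$id)
  expect_error(downsample_per_genome(reads, truth, k = 11), "fewer than")
})

test_that("sim_community_reads tracks truth for every read", {
  db <- synth_reference_db(4, 3, seed = 8)
  mock <- build_mocks(db, "low", 1, seed = 2, n_genomes = 5)[[1]]
  sim <- sim_community_reads(mock, "ccs_450", reads_per_genome = 3,
                             seed = 5)
  expect_equal(nrow(sim$reads), 15L)
  expect_setequal(sim$truth$read_id, sim$reads$id)
  expect_true(all(sim$truth$genome_id %in% mock$genomes$id))
  expect_equal(unname(table(sim$truth$genome_id)), rep(3L, 5),
               ignore_attr = TRUE)
})
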