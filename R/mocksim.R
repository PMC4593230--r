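# Synthetic 16S-like reference databases, mock communities, in-silico
# amplicon extraction, and short-read / CCS read simulators.

BASES <- c("A", "C", "G", "T")

ALT_BASE <- matrix(c("C", "G", "T",   # alternatives to A
                     "A", "G", "T",   # C
                     "A", "C", "T",   # G
                     "A", "C", "G"),  # T
                   nrow = 3L, dimnames = list(NULL, c("A", "C", "G", "T")))

# replace bases at `hit` with a uniformly chosen different base
substitute_bases <- function(x, hit) {
  if (length(hit)) {
    x[hit] <- ALT_BASE[cbind(sample.int(3L, length(hit), replace = TRUE),
                             match(x[hit], colnames(ALT_BASE)))]
  }
  x
}

# substitute each site independently with probability `rate` (to a
# uniformly chosen different base); x is a character vector of bases
mutate_sites <- function(x, rate) {
  substitute_bases(x, which(runif(length(x)) < rate))
}

#' Generate a synthetic 16S-like reference database
#'
#' Evolves a random root sequence into `n_genera` genus ancestors (per-site
#' substitution probability `genus_divergence`), then each ancestor into
#' `genomes_per_genus` genome sequences (`within_genus_divergence`).
#' The resulting two-level divergence hierarchy makes clustering thresholds
#' of 1-6 % dissimilarity meaningful: within-genus pairwise distances
#' concentrate near `2q(1-q) + (2/3)q^2` for `q = within_genus_divergence`.
#' Ids encode the genus (`genus<g>_genome<k>`). All sequences are checked
#' unique; with divergence too low this fails with an informative error.
#'
#' @param n_genera number of genera.
#' @param genomes_per_genus genomes per genus.
#' @param genus_divergence per-site substitution probability root -> genus
#'   ancestor, in (0, 0.5).
#' @param within_genus_divergence per-site substitution probability genus
#'   ancestor -> genome, in (0, 0.5).
#' @param length sequence length (> 1400, the full-length 16S cutoff).
#' @param seed integer seed; the database is deterministic given it.
#' @return a [seq_records()] table with technology `"reference"`.
#' @export
synth_reference_db <- function(n_genera, genomes_per_genus,
                               genus_divergence = 0.10,
                               within_genus_divergence = 0.03,
                               length = 1500L, seed = 1L) {
  if (genus_divergence <= 0 || genus_divergence >= 0.5 ||
      within_genus_divergence <= 0 || within_genus_divergence >= 0.5)
    stop("divergences must lie in (0, 0.5)")
  if (length <= 1400L) stop("length must exceed 1400 bp")
  with_seed(seed, {
    root <- sample(BASES, length, replace = TRUE)
    seqs <- character(n_genera * genomes_per_genus)
    ids <- character(n_genera * genomes_per_genus)
    k <- 0L
    for (g in seq_len(n_genera)) {
      anc <- mutate_sites(root, genus_divergence)
      for (m in seq_len(genomes_per_genus)) {
        k <- k + 1L
        seqs[k] <- paste(mutate_sites(anc, within_genus_divergence),
                         collapse = "")
        ids[k] <- sprintf("genus%03d_genome%03d", g, m)
      }
    }
    if (anyDuplicated(seqs))
      stop("generated duplicate sequences; increase divergence above 0")
    seq_records(id = ids, seq = seqs, technology = "reference")
  })
}

#' Filter a reference database
#'
#' Removes exact duplicate sequences, enforces length > 1400 bp, and
#' down-samples any genus represented by more than 1000 genomes to 100
#' (seeded). The genus is read from the id prefix before the first `_`.
#'
#' @param records a [seq_records()] table of reference sequences.
#' @param max_per_genus genus size triggering down-sampling (default 1000).
#' @param downsample_to genomes kept for an oversized genus (default 100).
#' @param seed integer seed for the down-sampling.
#' @return the filtered [seq_records()] table.
#' @export
filter_reference_db <- function(records, max_per_genus = 1000L,
                                downsample_to = 100L, seed = 1L) {
  records <- records[!duplicated(records$seq), , drop = FALSE]
  records <- records[nchar(records$seq) > 1400L, , drop = FALSE]
  genus <- sub("_.*$", "", records$id)
  keep <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(records)), genus), function(idx) {
      if (length(idx) > max_per_genus) sample(idx, downsample_to) else idx
    }), use.names = FALSE)
  })
  records[sort(keep), , drop = FALSE]
}

mock_sizes <- c(low = 100L, medium = 250L, high = 500L)

#' Build mock communities
#'
#' Samples genomes without replacement from the reference database to form
#' `n_replicates` mock communities at the requested complexity (low = 100,
#' medium = 250, high = 500 genomes per community).
#'
#' @param db reference [seq_records()] table.
#' @param complexity `"low"`, `"medium"` or `"high"`.
#' @param n_replicates number of communities (default 10).
#' @param seed integer seed.
#' @param n_genomes optional override of the per-community genome count.
#' @return list of `mock_community` objects: `genomes` ([seq_records()]),
#'   `complexity`, `community_id`.
#' @export
build_mocks <- function(db, complexity = c("low", "medium", "high"),
                        n_replicates = 10L, seed = 1L, n_genomes = NULL) {
  complexity <- match.arg(complexity)
  size <- if (is.null(n_genomes)) mock_sizes[[complexity]] else
    as.integer(n_genomes)
  if (nrow(db) < size)
    stop("database too small: ", nrow(db), " genomes for community size ",
         size)
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      idx <- sample.int(nrow(db), size)
      structure(list(genomes = db[idx, , drop = FALSE],
                     complexity = complexity,
                     community_id = sprintf("%s_rep%02d", complexity, r)),
                class = "mock_community")
    })
  })
}

#' @export
print.mock_community <- function(x, ...) {
  cat(sprintf("<mock_community> %s: %d genomes\n",
              x$community_id, nrow(x$genomes)))
  invisible(x)
}

#' Amplicon specification
#'
#' Locates an amplicon either by alignment interval (`start`, `end`;
#' 1-based inclusive columns of the reference alignment) or by a
#' forward/reverse primer pair (IUPAC-degenerate, both 5'->3' on their
#' respective strands). Exactly one mode must be set.
#'
#' @param start,end alignment interval (interval mode).
#' @param forward,reverse primer sequences (primer mode).
#' @param expected_len expected amplicon length (for size filtering).
#' @return an `amplicon_spec` object.
#' @export
amplicon_spec <- function(start = NULL, end = NULL,
                          forward = NULL, reverse = NULL,
                          expected_len = NA_integer_) {
  interval <- !is.null(start) || !is.null(end)
  primer <- !is.null(forward) || !is.null(reverse)
  if (interval == primer)
    stop("set exactly one of interval (start/end) or primer pair")
  if (interval && (is.null(start) || is.null(end) || start < 1L || end < start))
    stop("invalid interval")
  if (primer && (is.null(forward) || is.null(reverse)))
    stop("primer mode needs both forward and reverse primers")
  structure(list(mode = if (interval) "interval" else "primer",
                 start = start, end = end,
                 forward = if (primer) toupper(forward) else NULL,
                 reverse = if (primer) toupper(reverse) else NULL,
                 expected_len = as.integer(expected_len)),
            class = "amplicon_spec")
}

#' Extract an amplicon from a genome
#'
#' Interval mode treats the genome sequence as a row of the reference
#' alignment: the requested columns are taken (end clamped to the row
#' length) and gaps removed. Primer mode scans both strands with IUPAC
#' matching and returns the product of the outermost matching primer pair,
#' primers included, reported on the plus strand of the matching
#' orientation.
#'
#' @param genome one-row [seq_records()] table.
#' @param spec an [amplicon_spec()].
#' @return a one-row [seq_records()] table with technology `"amplicon"`.
#' @export
extract_amplicon <- function(genome, spec) {
  stopifnot(nrow(genome) == 1L, inherits(spec, "amplicon_spec"))
  if (spec$mode == "interval") {
    len <- nchar(genome$seq)
    if (spec$start > len)
      stop("interval start ", spec$start, " beyond row length ", len)
    seg <- substr(genome$seq, spec$start, min(spec$end, len))
    seg <- gsub("-", "", seg, fixed = TRUE)
  } else {
    seg <- find_primer_product(genome$seq, spec$forward, spec$reverse,
                               genome$id)
  }
  seq_records(id = paste0(genome$id, "_amp"), seq = seg,
              sample_id = genome$sample_id, technology = "amplicon")
}

find_primer_product <- function(seq, forward, reverse, genome_id) {
  scan <- function(s) {
    subj <- Biostrings::DNAString(s)
    f <- Biostrings::matchPattern(Biostrings::DNAString(forward), subj,
                                  fixed = FALSE)
    r <- Biostrings::matchPattern(
      Biostrings::reverseComplement(Biostrings::DNAString(reverse)), subj,
      fixed = FALSE)
    if (length(f) == 0L || length(r) == 0L) return(NULL)
    from <- min(BiocGenerics::start(f))
    to <- max(BiocGenerics::end(r))
    if (to <= from) return(NULL)
    substr(s, from, to)
  }
  out <- scan(seq)
  if (is.null(out)) out <- scan(revcomp(seq))
  if (is.null(out))
    stop("primer pair ", forward, "/", reverse,
         " not found in genome ", genome_id)
  out
}

#' CCS error model
#'
#' Per-read accuracy is drawn from Normal(`accuracy_mean`, `accuracy_sd`)
#' truncated to (0, 1]; the read's error count is Binomial(length,
#' 1 - accuracy), apportioned among substitutions, insertions and deletions
#' in the ratio `diff_ratio` and placed uniformly along the read.
#' Defaults are the CCS simulation parameters: accuracy 0.99 +/- 0.01,
#' mismatch:insertion:deletion = 6:21:73.
#'
#' @param accuracy_mean,accuracy_sd accuracy distribution parameters.
#' @param diff_ratio positive length-3 vector (mismatch, insertion,
#'   deletion); normalized internally.
#' @return an `error_model` object of kind `"ccs"`.
#' @export
error_model_ccs <- function(accuracy_mean = 0.99, accuracy_sd = 0.01,
                            diff_ratio = c(mismatch = 6, insertion = 21,
                                           deletion = 73)) {
  if (length(diff_ratio) != 3L || any(diff_ratio <= 0))
    stop("diff_ratio must be 3 positive numbers")
  structure(list(kind = "ccs", accuracy_mean = accuracy_mean,
                 accuracy_sd = accuracy_sd,
                 diff_ratio = diff_ratio / sum(diff_ratio)),
            class = "error_model")
}

#' Short paired-end error model
#'
#' Substitution-only profile rising linearly from `base_rate` at the 5' end
#' to `end_rate` at the 3' end of each read of the pair, emulating the
#' quality decay of short-read sequencing-by-synthesis.
#'
#' @param read_len read length (150 or 250 in the benchmark).
#' @param base_rate substitution probability at the first cycle.
#' @param end_rate substitution probability at the last cycle.
#' @return an `error_model` object of kind `"short_paired"`.
#' @export
error_model_short <- function(read_len = 150L, base_rate = 0.001,
                              end_rate = 0.01) {
  stopifnot(read_len > 1L, base_rate > 0, end_rate >= base_rate)
  structure(list(kind = "short_paired", read_len = as.integer(read_len),
                 base_rate = base_rate, end_rate = end_rate),
            class = "error_model")
}

# phred value for an error probability, capped at 93
phred_of <- function(p) {
  as.integer(pmin(93L, round(-10 * log10(pmax(p, 10^-9.3)))))
}

# synthetic, documented monotone map accuracy -> pass count so that
# pass-binning recipes are exercisable on simulated data
passes_of_accuracy <- function(acc) {
  pmax(1L, as.integer(round(15 + (acc - 0.99) * 600)))
}

#' Simulate CCS reads from an amplicon
#'
#' @param amplicon one-row [seq_records()] table (see [extract_amplicon()]).
#' @param n number of reads.
#' @param model an [error_model_ccs()].
#' @param seed integer seed (`NULL` = current RNG stream).
#' @return a [seq_records()] table of `n` CCS reads; ids are
#'   `<amplicon_id>_ccs<i>`, per-base qualities encode the drawn accuracy,
#'   and `passes` carries the synthetic accuracy-to-passes annotation.
#' @export
sim_ccs_reads <- function(amplicon, n, model = error_model_ccs(),
                          seed = NULL) {
  stopifnot(nrow(amplicon) == 1L, n >= 1L, model$kind == "ccs")
  tmpl <- strsplit(toupper(amplicon$seq), "", fixed = TRUE)[[1L]]
  len <- length(tmpl)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  with_seed(seed, {
    seqs <- character(n); quals <- vector("list", n); pass <- integer(n)
    acc <- pmax(pmin(rnorm(n, model$accuracy_mean, model$accuracy_sd), 1),
                1e-3)
    n_err <- rbinom(n, len, 1 - acc)
    for (i in seq_len(n)) {
      x <- tmpl
      if (n_err[i] > 0L) {
        pos <- sample.int(len, min(n_err[i], len))
        type <- sample.int(3L, length(pos), replace = TRUE,
                           prob = model$diff_ratio)
        for (k in order(pos, decreasing = TRUE)) {
          p <- pos[k]
          if (type[k] == 1L) {          # substitution
            a <- alt[[x[p]]]
            x[p] <- a[sample.int(length(a), 1L)]
          } else if (type[k] == 3L) {   # deletion
            x <- x[-p]
          } else {                      # insertion after p
            x <- append(x, BASES[sample.int(4L, 1L)], after = p)
          }
        }
      }
      seqs[i] <- paste(x, collapse = "")
      quals[[i]] <- rep(phred_of(1 - acc[i]), length(x))
      pass[i] <- passes_of_accuracy(acc[i])
    }
    seq_records(id = paste0(amplicon$id, "_ccs", seq_len(n)), seq = seqs,
                sample_id = amplicon$sample_id, technology = "ccs",
                quals = quals, passes = pass)
  })
}

#' Simulate merged short read pairs from an amplicon
#'
#' Reads the first `read_len` bases (forward) and the last `read_len` bases
#' (reverse strand) of the amplicon under the position-dependent
#' substitution profile of `model`, then merges the pair with
#' [merge_pairs()] and a `spacer_len`-base `N` spacer. Merged length is
#' always `2 * read_len + spacer_len`.
#'
#' @param amplicon one-row [seq_records()] table.
#' @param n number of read pairs.
#' @param model an [error_model_short()]; its `read_len` is used.
#' @param spacer_len `N` spacer length (default 10).
#' @param seed integer seed (`NULL` = current RNG stream).
#' @return a [seq_records()] table of `n` merged reads with technology
#'   `"short_merged"` and recorded spacer intervals.
#' @export
sim_short_reads <- function(amplicon, n, model = error_model_short(),
                            spacer_len = 10L, seed = NULL) {
  stopifnot(nrow(amplicon) == 1L, n >= 1L, model$kind == "short_paired")
  len <- nchar(amplicon$seq)
  rl <- model$read_len
  if (len <= rl)
    stop("amplicon (", len, " bp) not longer than read length ", rl)
  rate <- model$base_rate +
    (model$end_rate - model$base_rate) * (seq_len(rl) - 1L) / (rl - 1L)
  q <- phred_of(rate)
  fwd_tmpl <- strsplit(substr(amplicon$seq, 1L, rl), "", fixed = TRUE)[[1L]]
  rev_tmpl <- strsplit(revcomp(substr(amplicon$seq, len - rl + 1L, len)),
                       "", fixed = TRUE)[[1L]]
  mq <- c(q, rep(0L, spacer_len), rev(q))
  with_seed(seed, {
    # the pair is simulated read-by-read and merged exactly as
    # merge_pairs(r1, r2, trim_tail = 0, spacer_len) would; the loop is
    # fused for speed (equivalence is asserted in the test suite)
    r1 <- vapply(seq_len(n), function(i)
      paste(mutate_profile(fwd_tmpl, rate), collapse = ""), "")
    r2 <- vapply(seq_len(n), function(i)
      paste(mutate_profile(rev_tmpl, rate), collapse = ""), "")
    seqs <- paste0(r1, strrep("N", spacer_len), revcomp(r2))
    seq_records(id = paste0(amplicon$id, "_sr", seq_len(n)), seq = seqs,
                sample_id = amplicon$sample_id,
                technology = "short_merged",
                quals = rep(list(mq), n),
                spacer_start = if (spacer_len > 0L) rl + 1L else NA_integer_,
                spacer_end = if (spacer_len > 0L) rl + spacer_len
                             else NA_integer_)
  })
}

# substitute base i with probability rate[i]
mutate_profile <- function(x, rate) {
  substitute_bases(x, which(runif(length(x)) < rate))
}

#' Down-sample reads to a fixed count per genome
#'
#' Keeps exactly `k` reads per genome of origin, sampled without
#' replacement under the seed; errors if any genome has fewer than `k`.
#'
#' @param reads a [seq_records()] table.
#' @param truth data.frame with columns `read_id`, `genome_id`.
#' @param k reads to keep per genome (default 20).
#' @param seed integer seed.
#' @return list with the down-sampled `reads` and matching `truth`.
#' @export
downsample_per_genome <- function(reads, truth, k = 20L, seed = 1L) {
  hit <- match(reads$id, truth$read_id)
  if (anyNA(hit)) stop("read without truth entry: ", reads$id[is.na(hit)][1L])
  genome <- truth$genome_id[hit]
  short <- table(genome)
  if (any(short < k))
    stop("genome with fewer than ", k, " reads: ",
         names(short)[short < k][1L])
  keep <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(reads)), genome), function(idx) {
      if (length(idx) == k) idx else sample(idx, k)
    }), use.names = FALSE)
  })
  keep <- sort(keep)
  list(reads = reads[keep, , drop = FALSE],
       truth = truth[match(reads$id[keep], truth$read_id), , drop = FALSE])
}
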