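# Simulation benchmark harness: technologies, per-community read sets,
# full bookkeeping runs, and the scaled-down directional comparison of
# long versus short reads.

#' Benchmark technology definitions
#'
#' The five simulated technologies with their amplicon intervals on the
#' reference alignment (1-based, end clamped to the row length) and, for
#' paired short reads, the read length: V4 (389-801) for 2 x 150, V3-V4
#' (227-801) for 2 x 250 and 450 bp CCS, V1-V4 (4-801) for 750 bp CCS, and
#' V1-V6 (4-1506) for 1450 bp CCS.
#'
#' @return named list of technology descriptors (`kind`, `start`, `end`,
#'   and `read_len` for short-read kinds).
#' @export
benchmark_technologies <- function() {
  list(
    miseq_2x150 = list(kind = "short", start = 389L, end = 801L,
                       read_len = 150L),
    miseq_2x250 = list(kind = "short", start = 227L, end = 801L,
                       read_len = 250L),
    ccs_450  = list(kind = "ccs", start = 227L, end = 801L),
    ccs_750  = list(kind = "ccs", start = 4L,   end = 801L),
    ccs_1450 = list(kind = "ccs", start = 4L,   end = 1506L)
  )
}

#' Approximate read lengths per technology
#'
#' Used by the ARI-versus-read-length regression helper.
#' @return named integer vector.
#' @export
technology_read_length <- function() {
  c(miseq_2x150 = 310L, miseq_2x250 = 510L, ccs_450 = 450L,
    ccs_750 = 750L, ccs_1450 = 1450L)
}

#' Simulate one technology's reads for one mock community
#'
#' Extracts the technology's amplicon from every genome of the community
#' and simulates `reads_per_genome` reads per genome (CCS or merged short
#' pairs). Read ids are prefixed with the community id; the truth table
#' maps every read to its genome of origin.
#'
#' @param mock a `mock_community` from [build_mocks()].
#' @param technology name from [benchmark_technologies()] or a descriptor
#'   list of the same shape.
#' @param reads_per_genome reads simulated per genome (default 20).
#' @param ccs_model an [error_model_ccs()].
#' @param short_rates base/end substitution rates for the short profile.
#' @param spacer_len `N` spacer for merged short pairs (default 10).
#' @param seed integer seed (`NULL` = current RNG stream).
#' @return list with `reads` ([seq_records()]) and `truth` (data.frame
#'   `read_id`, `genome_id`, `community_id`, `technology`).
#' @export
sim_community_reads <- function(mock, technology, reads_per_genome = 20L,
                                ccs_model = error_model_ccs(),
                                short_rates = c(0.001, 0.01),
                                spacer_len = 10L, seed = NULL) {
  tech <- if (is.character(technology)) {
    name <- technology
    spec <- benchmark_technologies()[[technology]]
    if (is.null(spec)) stop("unknown technology: ", technology)
    spec
  } else {
    name <- "custom"
    technology
  }
  aspec <- amplicon_spec(start = tech$start, end = tech$end)
  with_seed(seed, {
    sets <- vector("list", nrow(mock$genomes))
    for (g in seq_len(nrow(mock$genomes))) {
      amp <- extract_amplicon(mock$genomes[g, , drop = FALSE], aspec)
      amp$id <- paste0(mock$community_id, ".", amp$id)
      reads <- if (tech$kind == "ccs") {
        sim_ccs_reads(amp, reads_per_genome, model = ccs_model)
      } else {
        sim_short_reads(amp, reads_per_genome,
                        model = error_model_short(tech$read_len,
                                                  short_rates[1L],
                                                  short_rates[2L]),
                        spacer_len = spacer_len)
      }
      reads$sample_id <- mock$community_id
      sets[[g]] <- list(reads = reads,
                        truth = data.frame(
                          read_id = reads$id,
                          genome_id = mock$genomes$id[g],
                          community_id = mock$community_id,
                          technology = name))
    }
    list(reads = bind_records(lapply(sets, `[[`, "reads")),
         truth = do.call(rbind, lapply(sets, `[[`, "truth")))
  })
}

#' Benchmark configuration
#'
#' Bundles the full simulation-benchmark settings. The defaults are the
#' benchmark's printed configuration: 10 replicate communities per
#' complexity level (100/250/500 genomes for low/medium/high), five
#' technologies, 20 reads per genome — hence 100,000 reads for the full
#' low-complexity level and 500,000 for high.
#'
#' @param complexities subset of `c("low", "medium", "high")`.
#' @param technologies subset of `names(benchmark_technologies())`.
#' @param n_replicates communities per complexity (default 10).
#' @param reads_per_genome reads per genome per technology (default 20).
#' @param seed master integer seed.
#' @param n_genera,genomes_per_genus reference-database shape (the database
#'   must hold at least the largest community size).
#' @param genus_divergence,within_genus_divergence database divergences.
#' @param n_genomes optional override of genomes per community.
#' @return a `benchmark_config` list.
#' @export
benchmark_config <- function(complexities = c("low", "medium", "high"),
                             technologies = names(benchmark_technologies()),
                             n_replicates = 10L, reads_per_genome = 20L,
                             seed = 1L, n_genera = 60L,
                             genomes_per_genus = 10L,
                             genus_divergence = 0.10,
                             within_genus_divergence = 0.03,
                             n_genomes = NULL) {
  structure(list(complexities = complexities, technologies = technologies,
                 n_replicates = as.integer(n_replicates),
                 reads_per_genome = as.integer(reads_per_genome),
                 seed = as.integer(seed), n_genera = as.integer(n_genera),
                 genomes_per_genus = as.integer(genomes_per_genus),
                 genus_divergence = genus_divergence,
                 within_genus_divergence = within_genus_divergence,
                 n_genomes = n_genomes),
            class = "benchmark_config")
}

#' Run the simulation benchmark
#'
#' Builds the synthetic reference database, the mock communities, and the
#' per-(complexity, technology, replicate) read sets (shuffled, per
#' [shuffle_records()]), returning a bookkeeping count table. Total reads
#' per complexity = replicates x genomes x reads_per_genome x technologies.
#'
#' @param config a [benchmark_config()].
#' @param out_dir optional directory: every read set is written as FASTQ
#'   and each complexity's truth as TSV.
#' @param keep_reads keep the read sets in the returned object (default:
#'   only when no `out_dir` is given; large configurations should use
#'   `FALSE`).
#' @return list with `counts` (data.frame `complexity`, `technology`,
#'   `replicate`, `n_reads`), `total_reads`, `truth` (per complexity, only
#'   when `keep_reads`), and `reads` (named list, only when `keep_reads`).
#' @export
run_benchmark <- function(config, out_dir = NULL,
                          keep_reads = is.null(out_dir)) {
  stopifnot(inherits(config, "benchmark_config"))
  ctr <- 0L
  next_seed <- function() {
    ctr <<- ctr + 1L
    (config$seed * 10007L + ctr) %% 2147483647L
  }
  db <- synth_reference_db(config$n_genera, config$genomes_per_genus,
                           config$genus_divergence,
                           config$within_genus_divergence,
                           seed = next_seed())
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  counts <- list(); reads_out <- list(); truth_out <- list()
  for (cx in config$complexities) {
    mocks <- build_mocks(db, cx, config$n_replicates, seed = next_seed(),
                         n_genomes = config$n_genomes)
    truth_cx <- list()
    for (r in seq_along(mocks)) {
      for (tech in config$technologies) {
        sim <- sim_community_reads(mocks[[r]], tech,
                                   config$reads_per_genome,
                                   seed = next_seed())
        reads <- shuffle_records(sim$reads, seed = next_seed())
        set_name <- sprintf("%s.rep%02d.%s", cx, r, tech)
        counts[[set_name]] <- data.frame(complexity = cx, technology = tech,
                                         replicate = r,
                                         n_reads = nrow(reads))
        truth_cx[[set_name]] <- sim$truth
        if (!is.null(out_dir))
          write_fastq(reads, file.path(out_dir, paste0(set_name, ".fastq")))
        if (keep_reads) reads_out[[set_name]] <- reads
      }
    }
    truth_cx <- do.call(rbind, truth_cx)
    rownames(truth_cx) <- NULL
    if (!is.null(out_dir))
      utils::write.table(truth_cx, file.path(out_dir,
                                             paste0(cx, ".truth.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (keep_reads) truth_out[[cx]] <- truth_cx
  }
  counts <- do.call(rbind, counts)
  rownames(counts) <- NULL
  out <- list(counts = counts, total_reads = sum(counts$n_reads))
  if (keep_reads) {
    out$reads <- reads_out
    out$truth <- truth_out
  }
  out
}

#' Directional benchmark: long CCS versus merged short reads
#'
#' The scaled-down version of the simulation headline: on a few mock
#' communities, simulate full-length (1450 bp) CCS reads and merged
#' 2 x 150 short reads, cluster each set with pairwise distances and
#' complete linkage, sweep thresholds 1-6 %, and compare the per-replicate
#' best-threshold ARI. Longer reads should cluster at least as well as
#' short reads (median over replicates).
#'
#' @param n_mock replicate communities (default 3).
#' @param n_genomes genomes per community (default 25).
#' @param reads_per_genome reads per genome (default 10; kept modest so the
#'   all-versus-all alignments run in minutes).
#' @param technologies two or more technology names to compare.
#' @param h_list thresholds for the sweep.
#' @param seed master seed.
#' @param band alignment band half-width passed to [distance_matrix()]
#'   (default 50; reads of one amplicon differ by scattered indels whose
#'   net path drift stays far below this, so the banded optimum equals the
#'   full search).
#' @param jobs parallel workers for [distance_matrix()].
#' @param n_genera,genomes_per_genus,genus_divergence,within_genus_divergence
#'   reference-database shape (defaults: 10 genera of 5 genomes, 10 % /
#'   3 % divergence).
#' @return list with `results` (per technology x replicate: best ARI and
#'   threshold) and `medians` (named vector of per-technology median best
#'   ARI).
#' @export
benchmark_directional <- function(n_mock = 3L, n_genomes = 25L,
                                  reads_per_genome = 10L,
                                  technologies = c("miseq_2x150",
                                                   "ccs_1450"),
                                  h_list = seq(0.01, 0.06, by = 0.01),
                                  seed = 1L, band = 50L, jobs = 1L,
                                  n_genera = 10L, genomes_per_genus = 5L,
                                  genus_divergence = 0.10,
                                  within_genus_divergence = 0.03) {
  db <- synth_reference_db(n_genera, genomes_per_genus, genus_divergence,
                           within_genus_divergence, seed = seed)
  mocks <- build_mocks(db, "low", n_mock, seed = seed + 1L,
                       n_genomes = n_genomes)
  rows <- list()
  ctr <- 0L
  for (r in seq_along(mocks)) {
    for (tech in technologies) {
      ctr <- ctr + 1L
      sim <- sim_community_reads(mocks[[r]], tech, reads_per_genome,
                                 seed = seed + 100L + ctr)
      reads <- shuffle_records(sim$reads, seed = seed + 500L + ctr)
      D <- distance_matrix(reads, band = band, jobs = jobs)
      truth <- stats::setNames(sim$truth$genome_id, sim$truth$read_id)
      sweep <- threshold_sweep(D, truth, h_list = h_list)
      best <- attr(sweep, "best")
      rows[[ctr]] <- data.frame(technology = tech, replicate = r,
                                best_h = best$h, best_ari = best$ari,
                                n_otus = best$n_otus)
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  medians <- vapply(split(results$best_ari, results$technology), median, 1.0)
  list(results = results, medians = medians)
}
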