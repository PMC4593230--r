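# Configuration, logging and pipeline orchestration behind the command-line
# front-end (exec/longotu). Every run writes a manifest (inputs, parameters,
# seed, package version) and a timestamped log next to its outputs.

#' Read a flat key=value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Values are kept
#' as strings; list-valued keys (e.g. `thresholds`) are comma-separated.
#'
#' @param path config file.
#' @return named character vector.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  stats::setNames(trimws(vapply(kv, `[[`, "", 3L)),
                  trimws(vapply(kv, `[[`, "", 2L)))
}

#' Assemble a run configuration
#'
#' Merges a config file (optional) with explicit overrides (overrides win)
#' and fills workflow defaults: thresholds 0.01-0.06 by 0.01, `min_reads`
#' 10, complete linkage, the default alignment scoring, seed 1.
#'
#' @param workflow one of `preprocess`, `dist`, `cluster`, `hybrid`,
#'   `simulate`, `evaluate`, `entropy`.
#' @param config_file optional key=value file (see [read_run_config()]).
#' @param overrides named list of parameter overrides.
#' @return a `run_config` list with `workflow` and `params`.
#' @export
run_config <- function(workflow, config_file = NULL, overrides = list()) {
  workflows <- c("preprocess", "dist", "cluster", "hybrid", "simulate",
                 "evaluate", "entropy")
  if (!workflow %in% workflows)
    stop("unknown workflow '", workflow, "'; expected one of: ",
         paste(workflows, collapse = ", "))
  params <- list(thresholds = "0.01,0.02,0.03,0.04,0.05,0.06",
                 min_reads = "10", linkage = "complete", seed = "1",
                 match = "5", mismatch = "-4", gap_open = "10",
                 gap_extend = "0.5", band = "", jobs = "1")
  if (!is.null(config_file)) {
    file_kv <- as.list(read_run_config(config_file))
    params[names(file_kv)] <- file_kv
  }
  overrides <- overrides[!vapply(overrides, is.null, TRUE)]
  params[names(overrides)] <- lapply(overrides, as.character)
  th <- as.numeric(strsplit(params$thresholds, ",")[[1L]])
  if (any(is.na(th)) || any(th <= 0 | th >= 1) || is.unsorted(th))
    stop("thresholds must be sorted numbers in (0, 1)")
  structure(list(workflow = workflow, params = params),
            class = "run_config")
}

cfg_num <- function(config, key) as.numeric(config$params[[key]])
cfg_int <- function(config, key) as.integer(config$params[[key]])
cfg_chr <- function(config, key) config$params[[key]]
cfg_scoring <- function(config) {
  list(match = cfg_num(config, "match"),
       mismatch = cfg_num(config, "mismatch"),
       gap_open = cfg_num(config, "gap_open"),
       gap_extend = cfg_num(config, "gap_extend"))
}
cfg_band <- function(config) {
  b <- config$params[["band"]]
  if (is.null(b) || !nzchar(b)) NULL else as.integer(b)
}
cfg_thresholds <- function(config) {
  as.numeric(strsplit(config$params$thresholds, ",")[[1L]])
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", ...)
  writeLines(msg, con)
}

read_any <- function(path) {
  if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) read_fastq(path)
  else read_fasta(path)
}

#' Execute a workflow run
#'
#' Dispatches the configured workflow, writes its artifacts under
#' `out_dir`, and records a `manifest.json` (workflow, parameters, inputs,
#' seed, package version) plus a `run.log`. Outputs are deterministic
#' given the configured seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of the artifact paths written.
#' @export
run_workflow <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(logf))
  log_line(logf, "workflow=", config$workflow, " seed=",
           cfg_chr(config, "seed"))
  artifacts <- switch(config$workflow,
    preprocess = wf_preprocess(config, out_dir, logf),
    dist = wf_dist(config, out_dir, logf),
    cluster = wf_cluster(config, out_dir, logf),
    simulate = wf_simulate(config, out_dir, logf),
    evaluate = wf_evaluate(config, out_dir, logf),
    entropy = wf_entropy(config, out_dir, logf),
    hybrid = wf_hybrid(config, out_dir, logf))
  manifest <- list(workflow = config$workflow, params = config$params,
                   artifacts = artifacts,
                   version = as.character(utils::packageVersion("longotu")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_line(logf, "done: ", length(artifacts), " artifact(s)")
  invisible(artifacts)
}

wf_preprocess <- function(config, out_dir, logf) {
  rec <- read_fastq(cfg_chr(config, "input"))
  n0 <- nrow(rec)
  keep <- quality_fraction_filter(
    rec, min_q = cfg_int(config, "min_q"),
    min_fraction = cfg_num(config, "min_fraction"),
    strict = identical(cfg_chr(config, "strict"), "true"),
    exclude_spacer = !identical(cfg_chr(config, "exclude_spacer"), "false"))
  rec <- rec[keep, , drop = FALSE]
  el <- config$params[["expected_len"]]
  if (!is.null(el) && nzchar(el)) {
    tol <- config$params[["tolerance"]]
    rec <- rec[length_filter(rec, as.integer(el),
                             if (nzchar(tol %||% "")) as.integer(tol)
                             else 100L), , drop = FALSE]
  }
  log_line(logf, "kept ", nrow(rec), "/", n0, " reads")
  out <- file.path(out_dir, "filtered.fastq")
  write_fastq(rec, out)
  list(filtered = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

wf_dist <- function(config, out_dir, logf) {
  rec <- read_any(cfg_chr(config, "input"))
  D <- distance_matrix(rec, scoring = cfg_scoring(config),
                       jobs = cfg_int(config, "jobs"),
                       band = cfg_band(config))
  out <- file.path(out_dir, "distances.tsv")
  write_dist_tsv(D, out)
  log_line(logf, nrow(rec), " sequences, ",
           nrow(rec) * (nrow(rec) - 1L) / 2L, " pairs")
  list(distances = out)
}

wf_cluster <- function(config, out_dir, logf) {
  D <- read_dist_tsv(cfg_chr(config, "distances"))
  dend <- linkage(D, method = cfg_chr(config, "linkage"))
  arts <- list()
  reads_file <- config$params[["reads"]]
  rec <- if (!is.null(reads_file) && nzchar(reads_file))
    read_any(reads_file) else NULL
  for (h in cfg_thresholds(config)) {
    part <- cut_tree(dend, h)
    f <- file.path(out_dir, sprintf("membership_h%.2f.tsv", h))
    write_membership_tsv(part, f)
    arts[[sprintf("membership_h%.2f", h)]] <- f
    log_line(logf, "h=", h, ": ", length(unique(part)), " clusters, ",
             count_singletons(part), " singletons")
    if (!is.null(rec) && all(nzchar(rec$sample_id))) {
      tab <- filter_min_size(otu_table(part, rec),
                             cfg_int(config, "min_reads"))
      ft <- file.path(out_dir, sprintf("otu_table_h%.2f.tsv", h))
      utils::write.table(tab$counts, ft, sep = "\t", quote = FALSE)
      arts[[sprintf("otu_table_h%.2f", h)]] <- ft
    }
  }
  arts
}

wf_simulate <- function(config, out_dir, logf) {
  cfg <- benchmark_config(
    complexities = strsplit(cfg_chr(config, "complexities") %||%
                              "low", ",")[[1L]],
    technologies = strsplit(config$params[["technologies"]] %||%
                              paste(names(benchmark_technologies()),
                                    collapse = ","), ",")[[1L]],
    n_replicates = cfg_int(config, "n_replicates"),
    reads_per_genome = as.integer(config$params[["reads_per_genome"]] %||%
                                    "20"),
    seed = cfg_int(config, "seed"))
  res <- run_benchmark(cfg, out_dir = out_dir, keep_reads = FALSE)
  cf <- file.path(out_dir, "read_counts.tsv")
  utils::write.table(res$counts, cf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log_line(logf, "total reads: ", res$total_reads)
  list(read_counts = cf)
}

wf_evaluate <- function(config, out_dir, logf) {
  D <- read_dist_tsv(cfg_chr(config, "distances"))
  tt <- utils::read.delim(cfg_chr(config, "truth"),
                          stringsAsFactors = FALSE)
  truth <- stats::setNames(tt$genome_id, tt$read_id)[rownames(D)]
  sweep <- threshold_sweep(D, truth, h_list = cfg_thresholds(config))
  out <- file.path(out_dir, "evaluation.tsv")
  utils::write.table(sweep, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  best <- attr(sweep, "best")
  log_line(logf, "best h=", best$h, " ARI=", round(best$ari, 4))
  list(evaluation = out)
}

wf_entropy <- function(config, out_dir, logf) {
  msa <- read_msa(cfg_chr(config, "input"))
  prof <- entropy_profile(msa, cfg_chr(config, "reference"),
                          window = as.integer(config$params[["window"]] %||%
                                                "10"))
  out <- file.path(out_dir, "entropy.tsv")
  write_entropy_tsv(prof, out)
  log_line(logf, nrow(prof), " windows")
  list(entropy = out)
}

wf_hybrid <- function(config, out_dir, logf) {
  ccs <- read_any(cfg_chr(config, "ccs"))
  short <- read_any(cfg_chr(config, "short"))
  region <- amplicon_spec(start = cfg_int(config, "region_start"),
                          end = cfg_int(config, "region_end"))
  res <- hybrid_analysis(ccs, short, region,
                         h_list = cfg_thresholds(config),
                         min_reads = cfg_int(config, "min_reads"),
                         seed = cfg_int(config, "seed"),
                         band = cfg_band(config),
                         jobs = cfg_int(config, "jobs"))
  counts <- do.call(rbind, lapply(res[names(res) != "dropped_ccs"],
                                  `[[`, "counts"))
  out <- file.path(out_dir, "hybrid_summary.tsv")
  utils::write.table(counts, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  log_line(logf, "dropped CCS reads: ", res$dropped_ccs)
  list(hybrid_summary = out)
}
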