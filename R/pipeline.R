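#' Run the full simulate-demux-assign-quantify pipeline
#'
#' One reproducible end-to-end run: simulates a multiplexed run, applies
#' the quality filter and demultiplexes, assigns inserts to the panel,
#' builds the contamination matrix and report, computes neighbor sharing
#' and (optionally) a Q30 filter sweep, and writes every stage output with
#' a checksum manifest. Rerunning with the same configuration reproduces
#' the outputs byte for byte.
#'
#' @param config A `run_config`.
#' @param set The run's `index_set`.
#' @param out_dir Output directory (created if missing); NULL skips all
#'   file output.
#' @param demux A `demux_params`.
#' @param mode Report mode, "wgs" or "hpv" (see
#'   [contamination_report()]).
#' @param sweep_thresholds Optional Q30 thresholds for [filter_sweep()].
#' @param exclude Optional index id excluded from the matrix before
#'   reporting (see [exclude_index()]).
#' @param max_distance_fraction Panel-assignment ceiling.
#' @return List: `run`, `demux`, `assignments` (data frame with target
#'   ids), `matrix`, `report`, `neighbor_sharing`, `sweep`, `qc`,
#'   `split_report`, and `files` when `out_dir` is given.
#' @export
run_pipeline <- function(config, set, out_dir = NULL,
                         demux = demux_params(),
                         mode = "wgs", sweep_thresholds = NULL,
                         exclude = NULL, max_distance_fraction = 0.1) {
  run <- simulate_run(config, set)
  dm <- demux_run(run$reads, set, demux)
  asg <- dm$assignments
  asg$target_id <- assign_target(run$reads$insert_seq, config$panel,
                                 max_distance_fraction)
  M <- build_count_matrix(asg$index_id, asg$target_id, config$sheet,
                          targets = config$panel$target_id)
  excluded <- character(0)
  if (!is.null(exclude)) {
    M <- exclude_index(M, exclude)
    excluded <- exclude
  }
  ctrl <- config$sheet$index_id[config$sheet$role == "balancing"]
  ctrl <- setdiff(ctrl, excluded)
  rep_ <- contamination_report(M, mode = mode,
                               control_indexes =
                                 if (length(ctrl)) ctrl else NULL,
                               excluded_indexes = excluded)
  correct <- asg$index_id == run$truth$true_index_id
  binned <- !(asg$index_id %in% c("unassigned", "ambiguous",
                                  "filtered_out"))
  ns <- neighbor_sharing(run$reads$x[binned], run$reads$y[binned],
                         asg$index_id[binned], correct[binned])
  qc <- panel_qc(asg$target_id[binned], config$panel,
                 n_total_reads = nrow(run$reads),
                 uid = run$reads$uid[binned])
  sweep <- if (!is.null(sweep_thresholds))
    filter_sweep(run, sweep_thresholds, demux$max_mismatch,
                 max_distance_fraction) else NULL
  split_report <- data.frame(index_id = names(dm$split_rate),
                             reads = as.numeric(dm$bin_counts),
                             split_rate = as.numeric(dm$split_rate),
                             stringsAsFactors = FALSE)
  out <- list(run = run, demux = dm, assignments = asg, matrix = M,
              report = rep_, neighbor_sharing = ns, sweep = sweep, qc = qc,
              split_report = split_report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_run_fastq(run, p("run"))
    write_truth_table(run$truth, p("truth.tsv"))
    utils::write.table(split_report, p("split_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(M$counts, p("contamination_matrix.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    pm <- matrix_percentages(M)
    pmc <- matrix(fmt_pct(pm), nrow(pm), ncol(pm), dimnames = dimnames(pm))
    utils::write.table(pmc, p("contamination_matrix_pct.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    if (!is.null(sweep))
      utils::write.table(sweep, p("filter_sweep.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    ns_df <- data.frame(stratum = c("correct", "misassigned"),
                        pct_sharing = c(ns$pct_correct_sharing,
                                        ns$pct_misassigned_sharing),
                        n = c(ns$n_correct, ns$n_misassigned))
    utils::write.table(ns_df, p("neighbor_sharing.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    rj <- list(seed = config$seed, mode = mode,
               total_rate = rep_$total_rate,
               total_rate_display = fmt_sci(rep_$total_rate),
               one_in_n = rep_$one_in_n_total,
               per_index_rate = rep_$per_index_rate,
               sample_to_sample_avg = rep_$sample_to_sample_avg,
               n_total_reads = rep_$n_total_reads,
               n_hopped_reads = rep_$n_hopped_reads,
               excluded_indexes = excluded,
               retained_fraction = dm$retained_fraction,
               q30_region = demux$q30_region,
               q30_threshold = demux$q30_threshold,
               mapping_rate = qc$mapping_rate,
               capture_rate = qc$capture_rate,
               uniformity = qc$uniformity)
    jsonlite::write_json(rj, p("report.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    files <- list.files(out_dir, full.names = TRUE)
    files <- files[!endsWith(files, "manifest.tsv")]
    manifest <- data.frame(file = basename(files),
                           md5 = as.character(tools::md5sum(files)),
                           stringsAsFactors = FALSE)
    utils::write.table(manifest, p("manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$files <- c(files, p("manifest.tsv"))
  }
  out
}

## Thin command-line front end (used by exec/indexleak).

cli_usage <- function() {
  cat("usage: indexleak <verb> [options]\n",
      "verbs:\n",
      "  design          --n N --length L --min-dist D --seed S --out FILE\n",
      "  validate-indexes FILE [--min-dist D]\n",
      "  simulate        --n-reads N --n-targets T --seed S --out-prefix P\n",
      "  run             --n-reads N --n-targets T --seed S --out DIR\n",
      "                  [--q30 F] [--max-mismatch M] [--pooling STAGE]\n",
      "  check-examples\n", sep = "")
}

cli_opt <- function(args, name, default = NULL) {
  i <- match(paste0("--", name), args)
  if (is.na(i)) return(default)
  if (i == length(args)) stop("missing value for --", name)
  args[i + 1]
}

#' Command-line entry point
#'
#' Dispatches the `indexleak` shell verbs (see `exec/indexleak`) onto the
#' package functions. Not intended for interactive use.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
indexleak_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) { cli_usage(); return(invisible(1L)) }
  verb <- args[1]; args <- args[-1]
  num <- function(name, default = NULL) {
    v <- cli_opt(args, name, default); if (is.null(v)) NULL else
      as.numeric(v)
  }
  if (verb == "design") {
    rules <- design_rules(min_pairwise_hamming = num("min-dist", 4))
    set <- generate_index_set(num("n", 8), num("length", 10), rules,
                              seed = num("seed", 1))
    out <- cli_opt(args, "out")
    if (is.null(out)) print(set) else write_index_set(set, out)
  } else if (verb == "validate-indexes") {
    set <- read_index_set(args[1])
    print(validate_index_set(set, design_rules(
      min_pairwise_hamming = num("min-dist", 4))))
  } else if (verb %in% c("simulate", "run")) {
    panel <- make_panel(num("n-targets", 8), 400, seed = num("seed", 1))
    rules <- design_rules()
    set <- generate_index_set(num("n-targets", 8), 10, rules,
                              seed = num("seed", 1))
    sheet <- default_sample_sheet(set, panel)
    cfg <- run_config(num("n-reads", 10000), panel, sheet,
                      pooling_stage = cli_opt(args, "pooling", "post_pcr"),
                      seed = num("seed", 1))
    if (verb == "simulate") {
      run <- simulate_run(cfg, set)
      prefix <- cli_opt(args, "out-prefix", "sim")
      write_run_fastq(run, prefix)
      write_truth_table(run$truth, paste0(prefix, "_truth.tsv"))
    } else {
      q30 <- num("q30")
      res <- run_pipeline(cfg, set, out_dir = cli_opt(args, "out", "out"),
                          demux = demux_params(
                            max_mismatch = num("max-mismatch", 1),
                            q30_threshold = q30))
      print(res$report)
    }
  } else if (verb == "check-examples") {
    ck <- worked_example_checks()
    print(ck, row.names = FALSE)
    if (!all(ck$pass)) return(invisible(1L))
  } else {
    cli_usage(); return(invisible(1L))
  }
  invisible(0L)
}
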