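#' Index-by-target count matrix with proper-cell annotation
#'
#' The central object of contamination analysis: read counts per (index,
#' target) cell, with a logical mask marking proper combinations (the
#' index's own expected target(s) from the sample sheet). Everything off
#' the mask is a mis-assigned read.
#'
#' @param counts Non-negative numeric matrix, rows = indexes, columns =
#'   targets, with dimnames.
#' @param proper Logical matrix of the same shape marking expected cells.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(counts, proper) {
  counts <- as.matrix(counts)
  proper <- as.matrix(proper)
  if (!identical(dim(counts), dim(proper)))
    stop("counts and proper mask differ in shape")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have index ids as rownames and target ids as colnames")
  storage.mode(proper) <- "logical"
  dimnames(proper) <- dimnames(counts)
  structure(list(counts = counts, proper = proper), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d indexes x %d targets, %s reads (%s improper)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ","),
              format(sum(x$counts[!x$proper]), big.mark = ",")))
  print(x$counts)
  invisible(x)
}

#' Build a count matrix from read assignments
#'
#' Tallies demultiplexed, panel-assigned reads per (index, target) cell.
#' Unmapped, unassigned, ambiguous and filtered-out reads are excluded, so
#' the matrix total equals the number of reads that passed every step.
#' Proper cells are the sheet's expected index-to-target pairs; targets
#' listed in `internal_control_target` are additionally proper for every
#' index with at least one proper cell (the internal-control amplicon
#' present in every sample).
#'
#' @param index_id,target_id Per-read assignment vectors (equal length).
#' @param sheet A `sample_sheet`; every assigned index must appear in it.
#' @param targets Target universe for the columns; defaults to the sheet's
#'   non-NA targets plus any assigned target.
#' @param internal_control_target Optional target id(s) proper for all
#'   sample indexes.
#' @return A `count_matrix`.
#' @export
build_count_matrix <- function(index_id, target_id, sheet, targets = NULL,
                               internal_control_target = NULL) {
  stopifnot(length(index_id) == length(target_id))
  keep <- !(index_id %in% c("unassigned", "ambiguous", "filtered_out")) &
    target_id != "unmapped" & !is.na(target_id)
  index_id <- index_id[keep]; target_id <- target_id[keep]
  if (any(!index_id %in% sheet$index_id))
    stop("assigned index not present in the sample sheet: ",
         paste(unique(setdiff(index_id, sheet$index_id)), collapse = ", "))
  if (is.null(targets))
    targets <- unique(c(stats::na.omit(sheet$target_id),
                        unique(target_id)))
  counts <- matrix(0, nrow(sheet), length(targets),
                   dimnames = list(sheet$index_id, targets))
  if (length(index_id)) {
    tab <- table(factor(index_id, levels = sheet$index_id),
                 factor(target_id, levels = targets))
    counts[] <- as.numeric(tab)
  }
  proper <- matrix(FALSE, nrow(sheet), length(targets),
                   dimnames = dimnames(counts))
  for (i in seq_len(nrow(sheet)))
    if (!is.na(sheet$target_id[i]) && sheet$target_id[i] %in% targets)
      proper[i, sheet$target_id[i]] <- TRUE
  if (!is.null(internal_control_target)) {
    sample_rows <- rowSums(proper) > 0
    proper[sample_rows, intersect(internal_control_target, targets)] <- TRUE
  }
  count_matrix(counts, proper)
}

#' Total index contamination rate
#'
#' Sum of all improper-cell reads divided by the total reads of all
#' indexes in the matrix.
#'
#' @param M A `count_matrix`.
#' @return Fraction in [0, 1].
#' @export
total_contamination_rate <- function(M) {
  stopifnot(inherits(M, "count_matrix"))
  tot <- sum(M$counts)
  if (tot == 0) stop("undefined rate: empty count matrix")
  sum(M$counts[!M$proper]) / tot
}

#' Average per-index mis-assignment rate of control indexes
#'
#' Reads of the control indexes landing on experimental targets, divided by
#' the total reads of all indexes, divided by the number of control
#' indexes — the per-index rate convention used for balancing-library and
#' empty controls.
#'
#' @param M A `count_matrix`.
#' @param control_indexes Row ids whose reads are counted (must have no
#'   proper cells).
#' @param n_indexes Divisor; defaults to `length(control_indexes)`.
#' @return Fraction.
#' @export
per_index_control_rate <- function(M, control_indexes,
                                   n_indexes = length(control_indexes)) {
  stopifnot(inherits(M, "count_matrix"))
  if (n_indexes == 0) stop("n_indexes must be positive")
  if (any(!control_indexes %in% rownames(M$counts)))
    stop("unknown control index")
  if (any(M$proper[control_indexes, ]))
    stop("control indexes must have no proper cells")
  sum(M$counts[control_indexes, , drop = FALSE]) / sum(M$counts) / n_indexes
}

#' Leakage of a control index into one target
#'
#' Control-index reads on `reference_target` divided by all reads on that
#' target across every index (the control's own reads included in the
#' denominator).
#'
#' @param M A `count_matrix`.
#' @param control_index Row id with no proper cells.
#' @param reference_target Column id.
#' @return Fraction.
#' @export
leakage_rate <- function(M, control_index, reference_target) {
  stopifnot(inherits(M, "count_matrix"))
  if (!control_index %in% rownames(M$counts)) stop("unknown control index")
  if (!reference_target %in% colnames(M$counts)) stop("unknown target")
  if (any(M$proper[control_index, ]))
    stop("control index must have no proper cells")
  denom <- sum(M$counts[, reference_target])
  if (denom == 0) stop("undefined rate: no reads on reference target")
  M$counts[control_index, reference_target] / denom
}

#' Average sample-to-sample mis-assignment rate
#'
#' Mean over improper cells of (cell count / denominator), where the
#' denominator is the total reads on the included target columns across all
#' rows (proper and improper). Columns listed in `exclude_targets` (for
#' instance an internal-control amplicon present in every sample) are left
#' out entirely. Rows without any proper cell (empty controls) contribute
#' to the denominator but are excluded from the averaged cells unless
#' `include_empty_rows` is TRUE — the statistic is about sample-to-sample
#' leakage.
#'
#' @param M A `count_matrix`.
#' @param exclude_targets Target columns to drop (default none).
#' @param include_empty_rows Also average over cells of rows with no proper
#'   cell (default FALSE).
#' @return Fraction.
#' @export
sample_to_sample_avg <- function(M, exclude_targets = character(0),
                                 include_empty_rows = FALSE) {
  stopifnot(inherits(M, "count_matrix"))
  cols <- setdiff(colnames(M$counts), exclude_targets)
  if (!length(cols)) stop("no target columns left")
  counts <- M$counts[, cols, drop = FALSE]
  proper <- M$proper[, cols, drop = FALSE]
  denom <- sum(counts)
  if (denom == 0) stop("undefined rate: no reads on included targets")
  rows <- if (include_empty_rows) seq_len(nrow(counts)) else
    which(rowSums(M$proper) > 0)
  cells <- !proper[rows, , drop = FALSE]
  if (!any(cells)) stop("no improper cells defined")
  mean(counts[rows, , drop = FALSE][cells]) / denom
}

#' Remove one index (and its targets) from a count matrix
#'
#' Drops the index's row and every column that is proper for it, removing
#' its contribution from both numerators and denominators of all
#' subsequently computed rates. Equivalent to recomputing the matrix from
#' an assignment list with that index's reads and targets excluded.
#'
#' @param M A `count_matrix`.
#' @param index_id Row id to exclude.
#' @return A reduced `count_matrix`.
#' @export
exclude_index <- function(M, index_id) {
  stopifnot(inherits(M, "count_matrix"))
  if (!index_id %in% rownames(M$counts)) stop("unknown index: ", index_id)
  drop_cols <- colnames(M$counts)[M$proper[index_id, ]]
  keep_r <- setdiff(rownames(M$counts), index_id)
  keep_c <- setdiff(colnames(M$counts), drop_cols)
  if (!length(keep_r) || !length(keep_c))
    stop("exclusion would empty the matrix")
  count_matrix(M$counts[keep_r, keep_c, drop = FALSE],
               M$proper[keep_r, keep_c, drop = FALSE])
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

signif_half_up <- function(x, digits = 2) {
  if (x == 0) return(0)
  e <- floor(log10(abs(x)))
  round_half_up(x, digits - 1 - e)
}

#' "1 in N" formatting of a rate
#'
#' Reciprocal-rate phrasing: above 100,000 the reciprocal is expressed in
#' millions (2 significant figures, half-up, when at or above 10 million;
#' one decimal of a million below that); smaller reciprocals are rounded to
#' the nearest integer. A zero rate returns the sentinel "0 observed".
#'
#' @param rate Fraction (>= 0).
#' @return Character string, e.g. "1 in 36 million" or "1 in 2".
#' @export
one_in_n <- function(rate) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return("0 observed")
  n <- 1 / rate
  if (n >= 1e5) {
    m <- if (n >= 1e7) signif_half_up(n / 1e6, 2) else
      round_half_up(n / 1e6, 1)
    sprintf("1 in %s million", format(m, drop0trailing = TRUE))
  } else {
    sprintf("1 in %s", format(round_half_up(n), big.mark = ",",
                              scientific = FALSE))
  }
}

#' Display formatting for rates
#'
#' `fmt_pct` renders a fraction as a percentage with 4 decimals (the
#' convention for matrix percentages like "0.0002%"); `fmt_sci` renders it
#' in scientific notation at 3 significant figures ("2.16E-07"). Internal
#' computation is never rounded; these are display conventions only.
#'
#' @param x Numeric fraction(s).
#' @param digits Decimal places for `fmt_pct` (default 4).
#' @return Character vector.
#' @export
fmt_pct <- function(x, digits = 4) sprintf(paste0("%.", digits, "f%%"),
                                           100 * x)

#' @rdname fmt_pct
#' @export
fmt_sci <- function(x) toupper(sprintf("%.2e", x))

#' Neighbor index sharing on the spot array
#'
#' For each read, whether at least one of its (up to four) von-Neumann
#' neighbors on the array was assigned the same index. When a correctness
#' stratification is given, the sharing fraction is reported separately for
#' correctly and mis-assigned reads — bled spots inherit a neighbor's
#' index, so mis-assigned reads share far more often than the baseline
#' produced by index frequency alone.
#'
#' @param x,y Integer coordinates (unique pairs).
#' @param index_id Assigned index per read.
#' @param correct Optional logical: read's assigned index equals its true
#'   index.
#' @return List: `sharing` per-read logical, `pct_sharing` overall, and
#'   (with `correct`) `pct_correct_sharing`, `pct_misassigned_sharing`,
#'   `n_correct`, `n_misassigned`.
#' @export
neighbor_sharing <- function(x, y, index_id, correct = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, length(index_id) == n)
  key <- paste(x, y)
  if (anyDuplicated(key)) stop("duplicate array coordinates")
  share <- rep(FALSE, n)
  for (off in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- match(paste(x + off[1], y + off[2]), key)
    hit <- !is.na(nb)
    share[hit] <- share[hit] | (index_id[hit] == index_id[nb[hit]])
  }
  out <- list(sharing = share, pct_sharing = mean(share))
  if (!is.null(correct)) {
    stopifnot(length(correct) == n)
    out$pct_correct_sharing <- mean(share[correct])
    out$pct_misassigned_sharing <- mean(share[!correct])
    out$n_correct <- sum(correct)
    out$n_misassigned <- sum(!correct)
  }
  out
}

#' Quality profile of correctly vs mis-assigned reads
#'
#' Mean Q30 fraction of the index and insert regions, stratified by
#' whether the read's assigned index matches its true index. Mis-assigned
#' reads dominated by signal bleeding show a sharply lower index-region
#' Q30.
#'
#' @param assignments `assignments` data frame of a [demux_run()] result.
#' @param truth Truth table of a [simulate_run()] result.
#' @return Data frame with one row per stratum: n, mean_q30_index,
#'   mean_q30_insert.
#' @export
misassignment_diagnostics <- function(assignments, truth) {
  m <- merge(assignments, truth[, c("read_id", "true_index_id")],
             by = "read_id")
  m <- m[!(m$index_id %in% c("unassigned", "ambiguous", "filtered_out")), ]
  correct <- m$index_id == m$true_index_id
  agg <- function(rows) data.frame(
    n = sum(rows),
    mean_q30_index = mean(m$q30_index[rows]),
    mean_q30_insert = mean(m$q30_insert[rows]))
  out <- rbind(cbind(stratum = "correct", agg(correct)),
               cbind(stratum = "misassigned", agg(!correct)))
  out
}

#' Q30-threshold filter sweep
#'
#' Reruns demultiplex, panel assignment and contamination quantification at
#' each Q30 threshold (applied to the index region, strictly greater; a
#' zero threshold means no filtering).
#' Matching and assignment are computed once; thresholds only subset reads,
#' which is equivalent to rerunning the pipeline per threshold.
#'
#' @param run A `sim_run`.
#' @param thresholds Ascending numeric vector of Q30 fractions.
#' @param max_mismatch Demultiplexing mismatch allowance.
#' @param max_distance_fraction Panel assignment ceiling.
#' @return Data frame: threshold, total_rate, retained_fraction.
#' @export
filter_sweep <- function(run, thresholds, max_mismatch = 1L,
                         max_distance_fraction = 0.1) {
  stopifnot(inherits(run, "sim_run"), !is.unsorted(thresholds))
  set <- run$index_set
  q30 <- q30_fraction(run$reads$index_quals)
  idx <- match_index_fast(run$reads$index_seq, set, max_mismatch)
  tgt <- assign_target(run$reads$insert_seq, run$config$panel,
                       max_distance_fraction)
  out <- lapply(thresholds, function(th) {
    keep <- if (th > 0) q30 > th else rep(TRUE, length(q30))
    M <- build_count_matrix(idx[keep], tgt[keep], run$config$sheet,
                            targets = run$config$panel$target_id)
    data.frame(threshold = th, total_rate = total_contamination_rate(M),
               retained_fraction = mean(keep))
  })
  do.call(rbind, out)
}

#' Consolidated contamination report
#'
#' Assembles every rate convention from a count matrix: the total
#' contamination rate, optional per-index control rate (balancing or empty
#' controls), sample-to-sample average, and per-control leakage against an
#' internal-control target, each with its "1 in N" phrasing. The
#' denominator conventions are fixed by `mode`: "wgs" uses all matrix
#' reads; "hpv" drops the internal-control column from the matrix rates
#' (its reads only serve leakage denominators).
#'
#' @param M A `count_matrix`.
#' @param mode "wgs" or "hpv".
#' @param control_indexes Optional ids for [per_index_control_rate()].
#' @param empty_indexes Optional ids for per-control leakage.
#' @param internal_control_target Target used for leakage denominators and
#'   excluded from hpv-mode matrix rates.
#' @param excluded_indexes Ids already excluded upstream (recorded only).
#' @return Object of class `contamination_report`.
#' @export
contamination_report <- function(M, mode = c("wgs", "hpv"),
                                 control_indexes = NULL,
                                 empty_indexes = NULL,
                                 internal_control_target = NULL,
                                 excluded_indexes = character(0)) {
  mode <- match.arg(mode)
  stopifnot(inherits(M, "count_matrix"))
  excl <- if (mode == "hpv" && !is.null(internal_control_target))
    internal_control_target else character(0)
  cols <- setdiff(colnames(M$counts), excl)
  Msub <- count_matrix(M$counts[, cols, drop = FALSE],
                       M$proper[, cols, drop = FALSE])
  total <- total_contamination_rate(Msub)
  per_index <- if (!is.null(control_indexes))
    per_index_control_rate(M, control_indexes) else NA_real_
  s2s <- tryCatch(sample_to_sample_avg(M, exclude_targets = excl),
                  error = function(e) NA_real_)
  leak <- NULL
  if (!is.null(empty_indexes) && !is.null(internal_control_target)) {
    leak <- vapply(empty_indexes, function(i)
      leakage_rate(M, i, internal_control_target), numeric(1))
    names(leak) <- empty_indexes
  }
  structure(list(total_rate = total, per_index_rate = per_index,
                 sample_to_sample_avg = s2s, leakage = leak,
                 one_in_n_total = one_in_n(total),
                 one_in_n_per_index =
                   if (!is.na(per_index)) one_in_n(per_index) else NA,
                 n_total_reads = sum(M$counts),
                 n_hopped_reads = sum(M$counts[!M$proper]),
                 excluded_indexes = excluded_indexes, mode = mode,
                 internal_control_target = internal_control_target),
            class = "contamination_report")
}

#' @export
print.contamination_report <- function(x, ...) {
  cat(sprintf("contamination report (%s mode)\n", x$mode))
  cat(sprintf("  total reads: %s; mis-assigned: %s\n",
              format(x$n_total_reads, big.mark = ","),
              format(x$n_hopped_reads, big.mark = ",")))
  cat(sprintf("  total contamination rate: %s (%s; %s)\n",
              fmt_sci(x$total_rate), fmt_pct(x$total_rate),
              x$one_in_n_total))
  if (!is.na(x$per_index_rate))
    cat(sprintf("  per-index control rate: %s (%s)\n",
                fmt_sci(x$per_index_rate), x$one_in_n_per_index))
  if (!is.na(x$sample_to_sample_avg))
    cat(sprintf("  sample-to-sample average: %s\n",
                fmt_pct(x$sample_to_sample_avg)))
  if (!is.null(x$leakage))
    for (i in names(x$leakage))
      cat(sprintf("  leakage %s -> %s: %s\n", i, x$internal_control_target,
                  fmt_pct(x$leakage[[i]])))
  if (length(x$excluded_indexes))
    cat("  excluded indexes:", paste(x$excluded_indexes, collapse = ", "),
        "\n")
  invisible(x)
}
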