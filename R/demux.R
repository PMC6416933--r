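#' Fraction of bases at or above Q30
#'
#' Fraction of bases in a Phred+33 quality string with quality >= 30.
#' Vectorised over strings.
#'
#' @param quals Character vector of non-empty Phred+33 quality strings.
#' @return Numeric vector of fractions in [0, 1].
#' @export
q30_fraction <- function(quals) {
  if (length(quals) == 0L) return(numeric(0))
  if (any(!nzchar(quals)) || anyNA(quals)) stop("empty quality string")
  L <- nchar(quals)
  r <- as.integer(charToRaw(paste(quals, collapse = "")))
  if (any(r < 33L) || any(r > 126L))
    stop("quality character outside Phred+33 range ('!'..'~')")
  grp <- rep.int(seq_along(quals), L)
  as.numeric(rowsum(as.numeric(r - 33L >= 30L), grp, reorder = FALSE)) / L
}

#' Demultiplexing parameters
#'
#' @param max_mismatch Allowed mismatches between observed and designed
#'   index (0 or 1 in normal use; higher values are accepted with a
#'   warning).
#' @param q30_threshold Optional Q30-fraction filter; reads whose fraction
#'   is not strictly greater than the threshold are filtered out before
#'   matching. NULL or 0 disables (a zero threshold is "without any
#'   filtering").
#' @param q30_region Region the filter applies to: "index" (default),
#'   "insert" or "both".
#' @return Object of class `demux_params`.
#' @export
demux_params <- function(max_mismatch = 1L, q30_threshold = NULL,
                         q30_region = c("index", "insert", "both")) {
  q30_region <- match.arg(q30_region)
  max_mismatch <- as.integer(max_mismatch)
  stopifnot(max_mismatch >= 0L)
  if (max_mismatch > 1L)
    warning("max_mismatch > 1 is unusual; check decode_capacity() first")
  if (!is.null(q30_threshold))
    stopifnot(q30_threshold >= 0, q30_threshold <= 1)
  structure(list(max_mismatch = max_mismatch, q30_threshold = q30_threshold,
                 q30_region = q30_region), class = "demux_params")
}

#' Match observed index reads against an index set
#'
#' Nearest designed index within `max_mismatch` mismatches. A unique best
#' hit gives its id; no index within the radius gives "unassigned"; two or
#' more indexes tied at the minimal distance within the radius give
#' "ambiguous". Any non-ACGT character (e.g. N) mismatches every base.
#' Vectorised over observations.
#'
#' @param observed Character vector of observed index sequences, same
#'   length as the set's indexes.
#' @param set An `index_set`.
#' @param max_mismatch Allowed mismatch count.
#' @return Character vector of index ids, "unassigned" or "ambiguous".
#' @export
match_index <- function(observed, set, max_mismatch = 1L) {
  stopifnot(inherits(set, "index_set"))
  if (any(nchar(observed) != set$width))
    stop("observed index length differs from index set width")
  n <- length(observed); k <- length(set)
  L <- set$width
  # char matrix of observations against each index sequence
  obs_mat <- matrix(unlist(strsplit(observed, "")), nrow = n, ncol = L,
                    byrow = TRUE)
  D <- matrix(0L, n, k)
  for (j in seq_len(k)) {
    ref <- strsplit(set$sequence[j], "")[[1]]
    D[, j] <- as.integer(rowSums(obs_mat != rep(ref, each = n)))
  }
  best <- D[cbind(seq_len(n), max.col(-D, ties.method = "first"))]
  n_at_best <- rowSums(D == best)
  out <- rep("unassigned", n)
  within <- best <= max_mismatch
  out[within & n_at_best == 1L] <-
    set$index_id[max.col(-D, ties.method = "first")[within & n_at_best == 1L]]
  out[within & n_at_best > 1L] <- "ambiguous"
  out
}

# fast path used on large runs: exact dictionary hit, full scan on the rest
match_index_fast <- function(observed, set, max_mismatch = 1L) {
  out <- set$index_id[match(observed, set$sequence)]
  miss <- which(is.na(out))
  if (length(miss)) {
    if (max_mismatch >= 1L) {
      um <- unique(observed[miss])
      res <- match_index(um, set, max_mismatch)
      out[miss] <- res[match(observed[miss], um)]
    } else out[miss] <- "unassigned"
  }
  out
}

#' Demultiplex a set of reads
#'
#' Applies the Q30-fraction filter (strictly-greater comparison) before
#' index matching, then bins reads per index. Split rates are computed over
#' all input reads, so they sum to at most 1.
#'
#' @param reads Data frame with at least `read_id`, `index_seq`,
#'   `index_quals` and (for insert-region filtering) `insert_quals`; the
#'   `reads` element of a [simulate_run()] result works directly.
#' @param set An `index_set`.
#' @param params A `demux_params`.
#' @return Object of class `demux_result`: `assignments` data frame
#'   (read_id, index_id with "unassigned"/"ambiguous"/"filtered_out",
#'   q30_index, q30_insert), `split_rate` table, `bin_counts`, counts of
#'   unassigned/ambiguous/filtered_out, `retained_fraction`, `n_input`,
#'   `params`.
#' @export
demux_run <- function(reads, set, params = demux_params()) {
  stopifnot(inherits(set, "index_set"), inherits(params, "demux_params"))
  n <- nrow(reads)
  q30_idx <- q30_fraction(reads$index_quals)
  q30_ins <- if ("insert_quals" %in% names(reads))
    q30_fraction(reads$insert_quals) else rep(NA_real_, n)
  keep <- rep(TRUE, n)
  # threshold 0 means "without any filtering"; positive thresholds are
  # strict (a read exactly at the threshold is filtered out)
  if (!is.null(params$q30_threshold) && params$q30_threshold > 0) {
    keep <- switch(params$q30_region,
      index  = q30_idx > params$q30_threshold,
      insert = q30_ins > params$q30_threshold,
      both   = q30_idx > params$q30_threshold &
               q30_ins > params$q30_threshold)
  }
  assigned <- rep("filtered_out", n)
  if (any(keep))
    assigned[keep] <- match_index_fast(reads$index_seq[keep], set,
                                       params$max_mismatch)
  bins <- vapply(set$index_id, function(id) sum(assigned == id), integer(1))
  split_rate <- bins / n
  structure(list(
    assignments = data.frame(read_id = reads$read_id, index_id = assigned,
                             q30_index = q30_idx, q30_insert = q30_ins,
                             stringsAsFactors = FALSE),
    bin_counts = bins, split_rate = split_rate,
    n_unassigned = sum(assigned == "unassigned"),
    n_ambiguous = sum(assigned == "ambiguous"),
    n_filtered_out = sum(!keep),
    retained_fraction = mean(keep),
    n_input = n, params = params), class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  cat(sprintf("demux_result: %d reads (max_mismatch %d%s)\n", x$n_input,
              x$params$max_mismatch,
              if (!is.null(x$params$q30_threshold))
                sprintf(", Q30 > %.0f%% on %s", 100 * x$params$q30_threshold,
                        x$params$q30_region) else ""))
  cat(sprintf("  assigned %d | unassigned %d | ambiguous %d | filtered %d\n",
              sum(x$bin_counts), x$n_unassigned, x$n_ambiguous,
              x$n_filtered_out))
  invisible(x)
}
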