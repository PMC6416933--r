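#' Assign insert reads to amplicon panel targets
#'
#' Anchored matching: reads are amplicon-anchored, so each insert is
#' compared against the same-length prefix of every panel reference by
#' hamming distance. The best target wins unless its distance exceeds
#' `max_distance_fraction` of the read length, or two targets tie at the
#' best distance — both give "unmapped". Deterministic and invariant to
#' panel order.
#'
#' @param inserts Character vector of insert sequences (equal lengths).
#' @param panel An `amplicon_panel` (non-empty).
#' @param max_distance_fraction Distance ceiling as a fraction of read
#'   length (default 0.1).
#' @return Character vector of target ids or "unmapped".
#' @export
assign_target <- function(inserts, panel, max_distance_fraction = 0.1) {
  if (is.null(panel) || nrow(panel) == 0L) stop("empty panel")
  n <- length(inserts)
  if (n == 0L) return(character(0))
  L <- unique(nchar(inserts))
  if (length(L) != 1L) stop("inserts must share one length")
  prefix <- substr(panel$sequence, 1L, L)
  if (any(nchar(prefix) < L)) stop("reads longer than a panel reference")
  out <- rep(NA_character_, n)
  # exact-prefix fast path (sorted so ties at distance 0 cannot arise:
  # make_panel guarantees distinct prefixes at any usable length)
  hit <- match(inserts, prefix)
  out[!is.na(hit)] <- panel$target_id[hit[!is.na(hit)]]
  miss <- which(is.na(out))
  if (length(miss)) {
    um <- unique(inserts[miss])
    obs <- matrix(unlist(strsplit(um, "")), nrow = length(um), ncol = L,
                  byrow = TRUE)
    D <- matrix(0L, length(um), nrow(panel))
    for (j in seq_len(nrow(panel))) {
      ref <- strsplit(prefix[j], "")[[1]]
      D[, j] <- as.integer(rowSums(obs != rep(ref, each = length(um))))
    }
    best_j <- max.col(-D, ties.method = "first")
    best <- D[cbind(seq_len(length(um)), best_j)]
    ties <- rowSums(D == best) > 1L
    res <- ifelse(best <= floor(max_distance_fraction * L) & !ties,
                  panel$target_id[best_j], "unmapped")
    out[miss] <- res[match(inserts[miss], um)]
  }
  out
}

#' Panel-level quality control
#'
#' Summary statistics over a table of per-read target assignments:
#' mapping rate (assigned / assignments supplied), capture rate (assigned /
#' all input reads, when `n_total_reads` including filtered or undetermined
#' reads is supplied), uniformity (fraction of panel targets whose depth
#' exceeds 20% of the mean target depth), and, when UIDs are present,
#' duplication rate (1 - unique templates / reads).
#'
#' @param target_id Character vector of per-read target ids ("unmapped"
#'   allowed).
#' @param panel An `amplicon_panel` defining the target universe.
#' @param n_total_reads Optional total input reads for the capture rate;
#'   defaults to `length(target_id)`.
#' @param uid Optional per-read UID vector for the duplication rate.
#' @return List: mapping_rate, capture_rate, uniformity, duplication_rate
#'   (NA without UIDs), depth (named per-target vector).
#' @export
panel_qc <- function(target_id, panel, n_total_reads = NULL, uid = NULL) {
  if (length(target_id) == 0L) stop("no assignments")
  mapped <- target_id != "unmapped"
  if (is.null(n_total_reads)) n_total_reads <- length(target_id)
  depth <- vapply(panel$target_id, function(t) sum(target_id == t),
                  numeric(1))
  uniformity <- mean(depth > 0.2 * mean(depth))
  dup <- NA_real_
  if (!is.null(uid) && !all(is.na(uid))) {
    keep <- mapped & !is.na(uid)
    dup <- 1 - length(unique(paste(target_id[keep], uid[keep]))) / sum(keep)
  }
  list(mapping_rate = mean(mapped),
       capture_rate = sum(mapped) / n_total_reads,
       uniformity = uniformity, duplication_rate = dup, depth = depth)
}

#' Threshold-based panel genotype calls with a 0-10 score
#'
#' A target is called positive when its read count reaches the configured
#' cutoff. The accompanying 0-10 score is a saturating read-count scale —
#' `round(10 * min(1, reads / saturation))` — provided as a reporting
#' convenience; the score formula is a package convention, not a published
#' definition.
#'
#' @param counts Named numeric vector: reads per genotype target.
#' @param cutoffs Named numeric vector of per-target cutoffs; every target
#'   in `counts` must have one.
#' @param saturation Read count at which the score saturates at 10
#'   (default: 10x the target's cutoff).
#' @return Data frame: target_id, reads, cutoff, call
#'   ("positive"/"negative"), score.
#' @export
call_panel_genotypes <- function(counts, cutoffs, saturation = NULL) {
  targets <- names(counts)
  if (is.null(targets)) stop("counts must be named by target")
  if (any(!targets %in% names(cutoffs)))
    stop("missing cutoff for target(s): ",
         paste(setdiff(targets, names(cutoffs)), collapse = ", "))
  co <- cutoffs[targets]
  sat <- if (is.null(saturation)) 10 * co else rep_len(saturation,
                                                       length(counts))
  score <- floor(10 * pmin(1, counts / sat) + 0.5)
  data.frame(target_id = targets, reads = as.numeric(counts),
             cutoff = as.numeric(co),
             call = ifelse(counts >= co, "positive", "negative"),
             score = as.integer(score), row.names = NULL,
             stringsAsFactors = FALSE)
}
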