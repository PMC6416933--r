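## Shared base/quality machinery for the read simulator.

.BASES <- c("A", "C", "G", "T")
.QCHARS <- vapply(0:93, function(q) rawToChar(as.raw(q + 33L)), character(1))

# string vector -> integer code matrix (n x L), codes 1..4
encode_bases <- function(seqs) {
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1L)
  m <- matrix(match(unlist(strsplit(seqs, "")), .BASES),
              nrow = length(seqs), ncol = L, byrow = TRUE)
  if (anyNA(m)) stop("non-ACGT character in sequence")
  m
}

# integer code matrix -> string vector (row-wise)
decode_bases <- function(codes) {
  cols <- lapply(seq_len(ncol(codes)), function(j) .BASES[codes[, j]])
  do.call(paste0, cols)
}

quals_to_string <- function(Q) {
  cols <- lapply(seq_len(ncol(Q)), function(j) .QCHARS[Q[, j] + 1L])
  do.call(paste0, cols)
}

# Two-component per-base quality model with quality-linked substitution
# errors. Per-base error probability is seq_error * 10^(-Q/10) normalised by
# the model's mean error, so errors concentrate on low-quality bases while
# the marginal per-base error rate stays equal to seq_error (and seq_error
# = 0 produces no errors at all).
apply_seq_model <- function(codes, p_low, q_high, q_low, seq_error,
                            p_low_model = NULL) {
  n <- nrow(codes); L <- ncol(codes)
  if (n == 0L)
    return(list(seq = character(0), qual = character(0),
                n_errors = integer(0)))
  if (is.null(p_low_model)) p_low_model <- mean(p_low)
  low <- matrix(stats::runif(n * L) < p_low, n, L)
  Q <- matrix(ifelse(low, q_low, q_high), n, L)
  n_err <- integer(n)
  if (seq_error > 0) {
    err_norm <- (1 - p_low_model) * 10^(-q_high / 10) +
      p_low_model * 10^(-q_low / 10)
    perr <- pmin(1, seq_error * 10^(-Q / 10) / err_norm)
    err <- matrix(stats::runif(n * L) < perr, n, L)
    k <- sum(err)
    if (k > 0) {
      shift <- sample.int(3L, k, replace = TRUE)
      codes[err] <- ((codes[err] - 1L + shift) %% 4L) + 1L
    }
    n_err <- as.integer(rowSums(err))
  }
  list(seq = decode_bases(codes), qual = quals_to_string(Q), n_errors = n_err)
}

random_dna <- function(n, length) {
  decode_bases(matrix(sample.int(4L, n * length, replace = TRUE), n, length))
}

#' Generate a synthetic amplicon reference panel
#'
#' Random references with pairwise hamming distance at least a quarter of
#' their length, so that panel assignment by distance is unambiguous for
#' realistic error rates. Deterministic under `seed`.
#'
#' @param n_targets Number of amplicons (>= 1).
#' @param length Reference length in bases (>= 50; ~400 bp amplicons are the
#'   typical use).
#' @param seed Integer RNG seed.
#' @param max_attempts Resampling budget per target.
#' @return Object of class `amplicon_panel`: data frame with `target_id`
#'   and `sequence`.
#' @export
make_panel <- function(n_targets, length = 400L, seed = 1L,
                       max_attempts = 1000L) {
  stopifnot(n_targets >= 1L, length >= 50L)
  set.seed(seed)
  min_d <- ceiling(0.25 * length)
  seqs <- character(0); raws <- list()
  for (i in seq_len(n_targets)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      cand <- random_dna(1L, length)
      cr <- charToRaw(cand)
      if (!length(raws) ||
          min(vapply(raws, function(r) sum(r != cr), integer(1))) >= min_d) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("make_panel: could not satisfy pairwise distance constraint")
    seqs <- c(seqs, cand); raws <- c(raws, list(cr))
  }
  structure(data.frame(target_id = sprintf("target%02d", seq_len(n_targets)),
                       sequence = seqs, stringsAsFactors = FALSE),
            class = c("amplicon_panel", "data.frame"))
}

#' Write / read an amplicon panel as FASTA
#'
#' @param panel An `amplicon_panel` (data frame with `target_id`, `sequence`).
#' @param path File path.
#' @return `read_panel_fasta` returns an `amplicon_panel`.
#' @export
write_panel_fasta <- function(panel, path) {
  ss <- Biostrings::DNAStringSet(panel$sequence)
  names(ss) <- panel$target_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_panel_fasta
#' @export
read_panel_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  structure(data.frame(target_id = names(ss), sequence = as.character(ss),
                       stringsAsFactors = FALSE),
            class = c("amplicon_panel", "data.frame"))
}

#' Construct a sample sheet
#'
#' One row per library in the pool: experimental samples carry a target and
#' a positive weight; empty/water controls have no target and weight zero
#' (their indexed adapters are in the pool, but they contribute no reads of
#' their own); balancing libraries have positive weight but no panel target
#' (their inserts are off-panel genomic sequence).
#'
#' @param sample_id,index_id Character vectors.
#' @param target_id Character vector; NA for controls and balancing rows.
#' @param role One of "experimental", "empty_control", "water_control",
#'   "balancing" per row.
#' @param weight Relative abundance; must be > 0 for experimental/balancing
#'   and 0 for empty/water controls.
#' @return Object of class `sample_sheet` (a data frame).
#' @export
sample_sheet <- function(sample_id, index_id, target_id, role, weight) {
  role <- match.arg(role, c("experimental", "empty_control", "water_control",
                            "balancing"), several.ok = TRUE)
  df <- data.frame(sample_id = as.character(sample_id),
                   index_id = as.character(index_id),
                   target_id = as.character(target_id),
                   role = role, weight = as.numeric(weight),
                   stringsAsFactors = FALSE)
  ctrl <- df$role %in% c("empty_control", "water_control")
  if (any(df$weight[ctrl] != 0))
    stop("empty/water controls must have weight 0")
  if (any(df$weight[!ctrl] <= 0))
    stop("experimental/balancing rows must have weight > 0")
  if (any(!is.na(df$target_id[ctrl])))
    stop("empty/water controls cannot have a target")
  if (anyDuplicated(df$index_id)) stop("index_id must be unique in the sheet")
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Build the standard control-experiment sample sheet
#'
#' Convenience layout mirroring a multiplexed control run: `n_experimental`
#' samples assigned one panel target each, plus optional empty controls and
#' balancing libraries, drawn in order from `set`.
#'
#' @param set An `index_set` with enough indexes.
#' @param panel An `amplicon_panel`; its first `n_experimental` targets are
#'   assigned in order.
#' @param n_experimental,n_empty,n_balancing Row counts per role.
#' @return A `sample_sheet`.
#' @export
default_sample_sheet <- function(set, panel, n_experimental = nrow(panel),
                                 n_empty = 0L, n_balancing = 0L) {
  need <- n_experimental + n_empty + n_balancing
  if (length(set) < need) stop("index set too small for requested sheet")
  if (n_experimental > nrow(panel)) stop("panel too small")
  ids <- set$index_id
  k <- 0L
  rows <- list()
  if (n_experimental > 0) {
    rows$exp <- data.frame(
      sample_id = sprintf("sample%02d", seq_len(n_experimental)),
      index_id = ids[k + seq_len(n_experimental)],
      target_id = panel$target_id[seq_len(n_experimental)],
      role = "experimental", weight = 1, stringsAsFactors = FALSE)
    k <- k + n_experimental
  }
  if (n_empty > 0) {
    rows$empty <- data.frame(
      sample_id = sprintf("empty%02d", seq_len(n_empty)),
      index_id = ids[k + seq_len(n_empty)],
      target_id = NA_character_, role = "empty_control", weight = 0,
      stringsAsFactors = FALSE)
    k <- k + n_empty
  }
  if (n_balancing > 0) {
    rows$bal <- data.frame(
      sample_id = sprintf("balancing%02d", seq_len(n_balancing)),
      index_id = ids[k + seq_len(n_balancing)],
      target_id = NA_character_, role = "balancing", weight = 1,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Simulation run configuration
#'
#' All knobs of the synthetic-run generator. Contamination mechanisms are
#' applied per read in a fixed order: sample draw, oligo-synthesis index
#' swap, template switching (ligation-stage pooling only; doubled for
#' single-bead purification), amplification-stage index hopping (direct in
#' linear rolling-circle mode, accumulating majority-vote mis-calls in
#' exponential mode), neighbor signal bleeding on the spot array, and
#' finally per-base sequencing error with emitted quality strings.
#'
#' Free-oligo hopping (`p_hop`) is only active when pooling occurs before
#' circularisation (`ligation_1bead`, `ligation_2bead`, `post_pcr`):
#' exonuclease digestion after single-strand circle formation removes free
#' indexed oligos, so pools formed at `post_sscir`/`post_dnb` are not
#' exposed to them.
#'
#' @param n_reads Total reads to emit.
#' @param panel An `amplicon_panel`.
#' @param sheet A `sample_sheet` over indexes present in the run's
#'   `index_set`.
#' @param p_hop Per-read (linear) or per-duplication-per-cycle (exponential)
#'   free-index hopping probability.
#' @param oligo_contam Optional square matrix, rows = sheet rows, columns =
#'   sheet indexes: probability a molecule of sample i carries index j from
#'   synthesis contamination. Rows must sum to 1. NULL means no
#'   contamination (identity).
#' @param p_template_switch Per-read chimera probability; active only for
#'   ligation-stage pooling and doubled for `ligation_1bead`.
#' @param p_bleed Per-spot probability that the index read is overwritten by
#'   a uniformly chosen occupied 4-neighbor's index, with degraded qualities.
#' @param seq_error Mean per-base substitution probability.
#' @param q_high,q_low,p_lowq_base Two-component Phred quality model: each
#'   base is `q_low` with probability `p_lowq_base`, else `q_high`.
#' @param p_lowq_bleed Low-quality base fraction used for the index read of
#'   bled spots (their true signal is not detected; default 0.8, mean
#'   quality around Q17).
#' @param pooling_stage One of "ligation_1bead", "ligation_2bead",
#'   "post_pcr", "post_sscir", "post_dnb".
#' @param amplification_mode "linear_rcr" (rolling circle: copies made
#'   independently from the original template) or "exponential" (each copy
#'   is duplicated every cycle and wrong copies propagate).
#' @param cycles Amplification cycle count (exponential mode; <= 20).
#' @param read_length Insert read length in bases.
#' @param array_dims Integer (width, height) of the spot array; NULL picks
#'   the smallest square holding `n_reads`.
#' @param uid_length UID length in bases appended to each read's record
#'   (0 disables).
#' @param seed Integer RNG seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(n_reads, panel, sheet,
                       p_hop = 0.002, oligo_contam = NULL,
                       p_template_switch = 0.02, p_bleed = 0.003,
                       seq_error = 0.001,
                       q_high = 37L, q_low = 12L, p_lowq_base = 0.05,
                       p_lowq_bleed = 0.8,
                       pooling_stage = "post_pcr",
                       amplification_mode = "linear_rcr",
                       cycles = 10L, read_length = 30L,
                       array_dims = NULL, uid_length = 0L, seed = 1L) {
  pooling_stage <- match.arg(pooling_stage,
    c("ligation_1bead", "ligation_2bead", "post_pcr", "post_sscir",
      "post_dnb"))
  amplification_mode <- match.arg(amplification_mode,
                                  c("linear_rcr", "exponential"))
  stopifnot(inherits(sheet, "sample_sheet"), n_reads >= 1)
  probs <- c(p_hop, p_template_switch, p_bleed, seq_error, p_lowq_base,
             p_lowq_bleed)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!is.null(oligo_contam)) {
    oligo_contam <- as.matrix(oligo_contam)
    if (nrow(oligo_contam) != nrow(sheet) ||
        ncol(oligo_contam) != nrow(sheet))
      stop("oligo_contam must be square over the sheet rows")
    if (any(abs(rowSums(oligo_contam) - 1) > 1e-9))
      stop("oligo_contam rows must sum to 1")
  }
  if (amplification_mode == "exponential" && cycles > 20L)
    stop("cycles > 20 not supported in exponential mode (2^cycles copies)")
  if (is.null(array_dims)) {
    side <- ceiling(sqrt(n_reads))
    array_dims <- c(side, side)
  }
  if (prod(as.numeric(array_dims)) < n_reads)
    stop("array smaller than n_reads")
  structure(list(n_reads = as.integer(n_reads), panel = panel, sheet = sheet,
                 p_hop = p_hop, oligo_contam = oligo_contam,
                 p_template_switch = p_template_switch, p_bleed = p_bleed,
                 seq_error = seq_error, q_high = as.integer(q_high),
                 q_low = as.integer(q_low), p_lowq_base = p_lowq_base,
                 p_lowq_bleed = p_lowq_bleed, pooling_stage = pooling_stage,
                 amplification_mode = amplification_mode,
                 cycles = as.integer(cycles),
                 read_length = as.integer(read_length),
                 array_dims = as.integer(array_dims),
                 uid_length = as.integer(uid_length),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Linear (rolling-circle) amplification of one spot
#'
#' Every copy is made independently from the same original template, so a
#' hopping error affects only that copy: the expected wrong fraction is `h`
#' regardless of copy number.
#'
#' @param h Per-copy hop probability.
#' @param n_copies Copies made.
#' @param seed Optional RNG seed.
#' @return Empirical fraction of copies carrying a wrong index.
#' @export
amplify_linear <- function(h, n_copies, seed = NULL) {
  stopifnot(h >= 0, h <= 1, n_copies >= 1)
  if (!is.null(seed)) set.seed(seed)
  stats::rbinom(1L, n_copies, h) / n_copies
}

#' Exponential amplification of one spot
#'
#' Branching process: each cycle every existing copy is duplicated, each
#' duplication independently hops with probability `h`, and the descendants
#' of a wrong copy stay wrong. Errors therefore accumulate with cycle
#' count: the expected wrong fraction is `1 - (1 - h/2)^cycles`, roughly
#' `cycles * h / 2` for small `h` — strictly above the linear-mode
#' expectation `h` from 3 cycles on.
#'
#' @param h Per-duplication hop probability.
#' @param cycles Cycle count (<= 20).
#' @param seed Optional RNG seed.
#' @return Empirical wrong fraction among the final `2^cycles` copies.
#' @export
amplify_exponential <- function(h, cycles, seed = NULL) {
  stopifnot(h >= 0, h <= 1, cycles >= 1)
  if (cycles > 20L) stop("cycles > 20 not supported (2^cycles copies)")
  if (!is.null(seed)) set.seed(seed)
  w <- exponential_wrong_counts(1L, h, cycles)
  w / 2^cycles
}

# Vectorised branching-process recursion over n spots. Each cycle:
# wrong' = 2 * wrong + Binom(right, h); total doubles. Exact distribution
# of the explicit binary amplification tree, at any cycle count.
exponential_wrong_counts <- function(n, h, cycles) {
  w <- numeric(n); tot <- 1
  for (k in seq_len(cycles)) {
    w <- 2 * w + stats::rbinom(n, tot - w, h)
    tot <- 2 * tot
  }
  w
}

#' Expected wrong fraction after exponential amplification
#'
#' Closed form of the branching-process recursion:
#' `1 - (1 - h/2)^cycles`.
#'
#' @param h Per-duplication hop probability.
#' @param cycles Cycle count.
#' @return Expected wrong-copy fraction.
#' @export
expected_exponential_wrong_fraction <- function(h, cycles) {
  1 - (1 - h / 2)^cycles
}

#' Majority call of a spot's copy population
#'
#' The base caller reads the majority species of a spot. Ties are broken
#' toward the wrong index (conservative).
#'
#' @param n_right,n_wrong Copy counts (vectorised; total must be > 0).
#' @return Data frame with `call` ("right"/"wrong") and `purity`
#'   (majority count / total).
#' @export
call_spot_index <- function(n_right, n_wrong) {
  tot <- n_right + n_wrong
  if (any(tot <= 0)) stop("empty copy population")
  wrong <- n_wrong >= n_right  # tie -> wrong
  data.frame(call = ifelse(wrong, "wrong", "right"),
             purity = pmax(n_right, n_wrong) / tot,
             stringsAsFactors = FALSE)
}

# uniform draw of an index different from `cur`, from pool positions `pool`
draw_other_index <- function(cur, pool) {
  k <- length(pool)
  if (k < 2L) return(cur)
  u <- sample.int(k - 1L, length(cur), replace = TRUE)
  pos <- match(cur, pool)
  # shift draws at/after own position; current index may be outside pool
  out <- ifelse(!is.na(pos) & u >= pos, u + 1L, u)
  pool[out]
}

#' Simulate a multiplexed sequencing run with ground truth
#'
#' Emits reads (insert + index read, with Phred+33 qualities and array
#' coordinates) and a truth table tagging every read with the mechanism
#' that set its observed index: `clean`, `oligo_contam`, `template_switch`,
#' `hop`, `bleed`, or `seq_error_only` (no identity-changing event but at
#' least one sequencing error inside the index read). Later mechanisms
#' override earlier tags. Deterministic under the config seed.
#'
#' @param config A `run_config`.
#' @param set The run's `index_set`; all sheet indexes must be present.
#' @return Object of class `sim_run`: list with `reads` (data frame:
#'   read_id, insert_seq, insert_quals, index_seq, index_quals, x, y, uid),
#'   `truth` (read_id, true_sample_id, true_index_id, true_target_id,
#'   observed_index_id, mechanism), `config`, `index_set`.
#' @export
simulate_run <- function(config, set) {
  stopifnot(inherits(config, "run_config"), inherits(set, "index_set"))
  sheet <- config$sheet
  if (!all(sheet$index_id %in% set$index_id))
    stop("sample sheet uses indexes absent from the index set")
  n <- config$n_reads
  set.seed(config$seed)

  src <- which(sheet$weight > 0)
  if (!length(src)) stop("sample sheet has no rows with weight > 0")
  samp <- src[sample.int(length(src), n, replace = TRUE,
                         prob = sheet$weight[src])]

  # index identity as position in the sheet
  own <- samp
  pool <- seq_len(nrow(sheet))  # every sheet index is physically in the pool

  # (2) oligo-synthesis contamination
  idx <- own
  if (!is.null(config$oligo_contam)) {
    for (i in unique(samp)) {
      rows <- which(samp == i)
      idx[rows] <- sample.int(nrow(sheet), length(rows), replace = TRUE,
                              prob = config$oligo_contam[i, ])
    }
  }
  tag_oligo <- idx != own

  # (3) template switching at ligation-stage pooling
  tag_ts <- rep(FALSE, n)
  if (config$pooling_stage %in% c("ligation_1bead", "ligation_2bead")) {
    p_ts <- config$p_template_switch *
      if (config$pooling_stage == "ligation_1bead") 2 else 1
    tag_ts <- stats::runif(n) < min(1, p_ts)
    if (any(tag_ts)) idx[tag_ts] <- draw_other_index(idx[tag_ts], pool)
  }

  # (4) amplification: free-oligo hopping, gated by pooling stage
  hop_active <- config$pooling_stage %in%
    c("ligation_1bead", "ligation_2bead", "post_pcr")
  h <- if (hop_active) config$p_hop else 0
  if (config$amplification_mode == "exponential" && h > 0) {
    w <- exponential_wrong_counts(n, h, config$cycles)
    tag_hop <- w >= 2^config$cycles / 2  # majority call, tie -> wrong
  } else {
    tag_hop <- stats::runif(n) < h
  }
  if (any(tag_hop)) idx[tag_hop] <- draw_other_index(idx[tag_hop], pool)

  # (5) array placement, then neighbor signal bleeding
  W <- config$array_dims[1]; H <- config$array_dims[2]
  cell <- sample.int(n) - 1L       # read -> occupied cell (0-based row-major)
  x <- cell %% W; y <- cell %/% W
  read_at <- integer(n); read_at[cell + 1L] <- seq_len(n)
  tag_bleed <- stats::runif(n) < config$p_bleed
  pre_bleed_idx <- idx
  bleed_rows <- which(tag_bleed)
  if (length(bleed_rows)) {
    cand <- cbind(ifelse(x[bleed_rows] > 0,      cell[bleed_rows] - 1L, NA),
                  ifelse(x[bleed_rows] < W - 1L, cell[bleed_rows] + 1L, NA),
                  ifelse(y[bleed_rows] > 0,      cell[bleed_rows] - W,  NA),
                  ifelse(y[bleed_rows] < H - 1L, cell[bleed_rows] + W,  NA))
    cand[!is.na(cand) & cand >= n] <- NA  # unoccupied cells
    nv <- rowSums(!is.na(cand))
    pick <- ceiling(stats::runif(length(bleed_rows)) * pmax(nv, 1L))
    nb_cell <- vapply(seq_along(bleed_rows), function(i) {
      v <- cand[i, !is.na(cand[i, ])]
      if (!length(v)) NA_integer_ else v[pick[i]]
    }, integer(1))
    ok <- !is.na(nb_cell)
    idx[bleed_rows[ok]] <- pre_bleed_idx[read_at[nb_cell[ok] + 1L]]
    tag_bleed[bleed_rows[!ok]] <- FALSE
  }

  # (6) emission: qualities + sequencing errors, chunked
  idx_codes_all <- encode_bases(set$sequence)
  sheet_pos_in_set <- match(sheet$index_id, set$index_id)
  read_len <- config$read_length
  tgt_prefix <- substr(config$panel$sequence, 1L, read_len)
  if (any(nchar(tgt_prefix) < read_len))
    stop("read_length exceeds panel reference length")
  tgt_codes <- encode_bases(tgt_prefix)
  tgt_of_sheet <- match(sheet$target_id, config$panel$target_id)

  chunk <- 200000L
  idx_seq <- character(n); idx_qual <- character(n)
  ins_seq <- character(n); ins_qual <- character(n)
  idx_nerr <- integer(n)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n); rows <- lo:hi
    # index read
    im <- idx_codes_all[sheet_pos_in_set[idx[rows]], , drop = FALSE]
    p_low <- ifelse(tag_bleed[rows], config$p_lowq_bleed, config$p_lowq_base)
    em <- apply_seq_model(im, p_low, config$q_high, config$q_low,
                          config$seq_error, p_low_model = config$p_lowq_base)
    idx_seq[rows] <- em$seq; idx_qual[rows] <- em$qual
    idx_nerr[rows] <- em$n_errors
    # insert read: panel prefix for targeted samples, random for balancing
    ti <- tgt_of_sheet[samp[rows]]
    bm <- matrix(0L, length(rows), read_len)
    has_t <- !is.na(ti)
    if (any(has_t)) bm[has_t, ] <- tgt_codes[ti[has_t], , drop = FALSE]
    if (any(!has_t))
      bm[!has_t, ] <- matrix(sample.int(4L, sum(!has_t) * read_len,
                                        replace = TRUE),
                             sum(!has_t), read_len)
    em2 <- apply_seq_model(bm, config$p_lowq_base, config$q_high,
                           config$q_low, config$seq_error)
    ins_seq[rows] <- em2$seq; ins_qual[rows] <- em2$qual
  }

  uid <- if (config$uid_length > 0) random_dna(n, config$uid_length) else
    rep(NA_character_, n)

  mech <- rep("clean", n)
  mech[idx_nerr > 0] <- "seq_error_only"
  mech[tag_oligo] <- "oligo_contam"
  mech[tag_ts] <- "template_switch"
  mech[tag_hop] <- "hop"
  mech[tag_bleed] <- "bleed"

  read_id <- sprintf("read%07d", seq_len(n))
  reads <- data.frame(read_id = read_id, insert_seq = ins_seq,
                      insert_quals = ins_qual, index_seq = idx_seq,
                      index_quals = idx_qual, x = x, y = y, uid = uid,
                      stringsAsFactors = FALSE)
  truth <- data.frame(read_id = read_id,
                      true_sample_id = sheet$sample_id[samp],
                      true_index_id = sheet$index_id[own],
                      true_target_id = sheet$target_id[samp],
                      observed_index_id = sheet$index_id[idx],
                      mechanism = mech, stringsAsFactors = FALSE)
  structure(list(reads = reads, truth = truth, config = config,
                 index_set = set), class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("sim_run: %d reads (%s pooling, %s amplification, seed %d)\n",
              nrow(x$reads), x$config$pooling_stage,
              x$config$amplification_mode, x$config$seed))
  print(table(x$truth$mechanism))
  invisible(x)
}

#' Generate template molecules with a spiked mutant fraction
#'
#' Molecules are read-length copies of one panel reference; a `fraction`
#' of them carry a single substitution (`mut_base`) at `position`. This is
#' the template pool of a two-step PCR library in which sample index and
#' UID are introduced during amplification.
#'
#' @param panel An `amplicon_panel`.
#' @param target_id Reference to draw molecules from.
#' @param position 1-based variant position within the read span.
#' @param mut_base Mutant base (must differ from the reference base).
#' @param fraction Mutant molecule fraction in [0, 1].
#' @param n_molecules Number of template molecules.
#' @param read_length Molecule/read length (default: full reference).
#' @param seed Optional RNG seed.
#' @return Data frame: molecule_id, target_id, allele ("ref"/"mut"),
#'   insert_seq.
#' @export
spike_mutants <- function(panel, target_id, position, mut_base, fraction,
                          n_molecules, read_length = NULL, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1, n_molecules >= 1)
  if (!is.null(seed)) set.seed(seed)
  i <- match(target_id, panel$target_id)
  if (is.na(i)) stop("unknown target_id")
  ref <- panel$sequence[i]
  if (is.null(read_length)) read_length <- nchar(ref)
  if (position < 1 || position > read_length)
    stop("variant position outside the read span")
  ref_read <- substr(ref, 1L, read_length)
  ref_base <- substr(ref_read, position, position)
  if (identical(mut_base, ref_base))
    stop("mut_base equals the reference base")
  mut_read <- ref_read
  substr(mut_read, position, position) <- mut_base
  is_mut <- stats::runif(n_molecules) < fraction
  data.frame(molecule_id = sprintf("mol%07d", seq_len(n_molecules)),
             target_id = target_id,
             allele = ifelse(is_mut, "mut", "ref"),
             insert_seq = ifelse(is_mut, mut_read, ref_read),
             stringsAsFactors = FALSE)
}

#' Tag molecules with UIDs and emit duplicate reads
#'
#' Each molecule receives a random UID and is emitted as D duplicate reads,
#' with D drawn from `duplication` (default 1 + Poisson(2)). Sequencing
#' error and qualities are applied per read via the same model as
#' [simulate_run()], so duplicates of one molecule can disagree at the
#' variant position — the situation UID consensus is meant to repair.
#'
#' @param molecules Data frame from [spike_mutants()].
#' @param uid_length UID length in bases (>= 6 recommended for collision
#'   safety at desk scale).
#' @param duplication Function n -> integer vector of duplicate counts
#'   (each >= 1).
#' @param seq_error,q_high,q_low,p_lowq_base Sequencing model, as in
#'   [run_config()].
#' @param seed Optional RNG seed.
#' @return Data frame: read_id, molecule_id, uid, target_id, true_allele,
#'   insert_seq, insert_quals.
#' @export
attach_uids <- function(molecules, uid_length = 10L,
                        duplication = function(n) 1L + stats::rpois(n, 2),
                        seq_error = 0.001, q_high = 37L, q_low = 12L,
                        p_lowq_base = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (uid_length < 1L) stop("uid_length must be >= 1")
  nm <- nrow(molecules)
  uid <- random_dna(nm, uid_length)
  d <- duplication(nm)
  if (any(d < 1L)) stop("duplication counts must be >= 1")
  rows <- rep(seq_len(nm), d)
  codes <- encode_bases(molecules$insert_seq)[rows, , drop = FALSE]
  em <- apply_seq_model(codes, p_lowq_base, q_high, q_low, seq_error)
  data.frame(read_id = sprintf("uread%07d", seq_along(rows)),
             molecule_id = molecules$molecule_id[rows],
             uid = uid[rows],
             target_id = molecules$target_id[rows],
             true_allele = molecules$allele[rows],
             insert_seq = em$seq, insert_quals = em$qual,
             stringsAsFactors = FALSE)
}
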