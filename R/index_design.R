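#' Construct an index (barcode) set
#'
#' An index set is the collection of sample barcodes sequenced alongside each
#' read in a multiplexed run. All sequences must share one length, be unique,
#' and use only A/C/G/T.
#'
#' @param sequences Character vector of DNA sequences (A/C/G/T only).
#' @param index_id Optional labels; defaults to `idx01`, `idx02`, ...
#' @return An object of class `index_set` with elements `index_id`,
#'   `sequence` and `width` (bases per index).
#' @examples
#' index_set(c("ACGTACGTAC", "TGCATGCATG"))
#' @export
index_set <- function(sequences, index_id = NULL) {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0L) stop("index set must contain at least one sequence")
  if (any(!grepl("^[ACGT]+$", sequences)))
    stop("index sequences must use only A, C, G, T")
  w <- unique(nchar(sequences))
  if (length(w) != 1L) stop("all index sequences must have the same length")
  if (anyDuplicated(sequences))
    stop("index sequences must be unique: ",
         paste(unique(sequences[duplicated(sequences)]), collapse = ", "))
  if (is.null(index_id)) index_id <- sprintf("idx%02d", seq_along(sequences))
  index_id <- as.character(index_id)
  if (anyDuplicated(index_id)) stop("index_id labels must be unique")
  if (length(index_id) != length(sequences))
    stop("index_id and sequences lengths differ")
  structure(list(index_id = index_id, sequence = sequences, width = w),
            class = "index_set")
}

#' @export
length.index_set <- function(x) length(x$sequence)

#' @export
print.index_set <- function(x, ...) {
  cat(sprintf("index_set: %d indexes of %d bp\n", length(x), x$width))
  n <- min(length(x), 10L)
  for (i in seq_len(n)) cat(sprintf("  %-8s %s\n", x$index_id[i], x$sequence[i]))
  if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  invisible(x)
}

#' @export
as.data.frame.index_set <- function(x, ...) {
  data.frame(index_id = x$index_id, sequence = x$sequence,
             stringsAsFactors = FALSE)
}

#' Barcode design rules
#'
#' Rule set applied when generating or validating an index set: a minimum
#' pairwise hamming distance, a GC-content window, a forbidden homopolymer
#' run length, distinctness from every reverse complement, and (optionally)
#' a ban on any 3-base motif repeated back-to-back.
#'
#' @param min_pairwise_hamming Minimum hamming distance between any two
#'   indexes (>= 1).
#' @param gc_min,gc_max GC-content window as fractions in [0, 1].
#' @param forbid_homopolymer_run Shortest forbidden single-base run
#'   (default 3: "AAA" is rejected).
#' @param require_rc_distinct If TRUE, the reverse complement of every index
#'   must differ from every index in the set, including itself (a
#'   palindromic index fails).
#' @param forbid_tandem_motif If TRUE, additionally reject any 3-base motif
#'   repeated twice in a row (e.g. "ACGACG"); off by default.
#' @return Object of class `design_rules`.
#' @export
design_rules <- function(min_pairwise_hamming = 4L, gc_min = 0.4, gc_max = 0.6,
                         forbid_homopolymer_run = 3L, require_rc_distinct = TRUE,
                         forbid_tandem_motif = FALSE) {
  stopifnot(min_pairwise_hamming >= 1L, gc_min <= gc_max,
            gc_min >= 0, gc_max <= 1, forbid_homopolymer_run >= 2L)
  structure(list(min_pairwise_hamming = as.integer(min_pairwise_hamming),
                 gc_min = gc_min, gc_max = gc_max,
                 forbid_homopolymer_run = as.integer(forbid_homopolymer_run),
                 require_rc_distinct = isTRUE(require_rc_distinct),
                 forbid_tandem_motif = isTRUE(forbid_tandem_motif)),
            class = "design_rules")
}

#' Hamming distance between equal-length DNA strings
#'
#' Number of positions at which two sequences differ. Vectorised over pairs
#' (arguments are recycled to a common length).
#'
#' @param a,b Character vectors of equal-length strings.
#' @return Integer vector of distances.
#' @examples
#' hamming_distance("ACGT", "ACGA")  # 1
#' @export
hamming_distance <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b)))
    stop("hamming_distance: sequences must have equal length")
  vapply(seq_len(n),
         function(i) sum(charToRaw(a[i]) != charToRaw(b[i])),
         integer(1))
}

#' Pairwise hamming-distance matrix of an index set
#'
#' @param set An `index_set` or character vector of equal-length sequences.
#' @return Symmetric integer matrix with index ids as dimnames.
#' @export
hamming_matrix <- function(set) {
  if (inherits(set, "index_set")) {
    seqs <- set$sequence; ids <- set$index_id
  } else {
    seqs <- as.character(set); ids <- names(set)
    if (is.null(ids)) ids <- seqs
  }
  n <- length(seqs)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    raws <- lapply(seqs, charToRaw)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- sum(raws[[i]] != raws[[j]])
      m[i, j] <- d; m[j, i] <- d
    }
  }
  m
}

#' GC content of DNA strings
#'
#' @param seq Character vector of DNA strings.
#' @return Numeric vector of G+C fractions.
#' @export
gc_content <- function(seq) {
  n <- nchar(seq)
  gc <- nchar(gsub("[^GCgc]", "", seq))
  gc / n
}

#' Test a sequence for a forbidden homopolymer run
#'
#' TRUE iff `seq` contains the same base `run` or more times consecutively.
#' This is the default reading of a "no 3-base tandem repeat" barcode rule;
#' the alternative reading (a 3-base motif repeated back to back) is
#' available via [violates_motif_rule()].
#'
#' @param seq Character vector of DNA strings (non-empty).
#' @param run Minimum forbidden run length (>= 2).
#' @return Logical vector.
#' @examples
#' violates_repeat_rule("AAAT", 3)    # TRUE
#' violates_repeat_rule("ATATAT", 3)  # FALSE
#' @export
violates_repeat_rule <- function(seq, run = 3L) {
  if (any(!nzchar(seq)) || any(is.na(seq)))
    stop("violates_repeat_rule: empty or missing sequence")
  if (run < 2L) stop("run length must be >= 2")
  grepl(sprintf("(.)\\1{%d,}", as.integer(run) - 1L), seq)
}

#' Test for a 3-base motif repeated back to back
#'
#' TRUE iff a 3-base motif occurs twice consecutively (e.g. "ACGACG").
#'
#' @param seq Character vector of DNA strings.
#' @param motif_length Motif length (default 3).
#' @return Logical vector.
#' @export
violates_motif_rule <- function(seq, motif_length = 3L) {
  if (any(!nzchar(seq)) || any(is.na(seq)))
    stop("violates_motif_rule: empty or missing sequence")
  grepl(sprintf("([ACGT]{%d})\\1", as.integer(motif_length)), seq)
}

reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Validate an index set against design rules
#'
#' Checks every rule and reports all violations instead of raising: per-index
#' GC window, homopolymer run, optional tandem-motif rule, reverse-complement
#' collisions (against the whole set, including self), plus set-level
#' uniqueness and the minimum pairwise hamming distance.
#'
#' @param set An `index_set`.
#' @param rules A `design_rules` object.
#' @return Object of class `index_validation`: `per_index` data frame
#'   (index_id, gc, and pass flags with reasons), `hamming` pairwise matrix,
#'   `min_distance`, `rc_collisions` (data frame of offending pairs),
#'   `n_violations` and overall `pass`.
#' @export
validate_index_set <- function(set, rules = design_rules()) {
  stopifnot(inherits(set, "index_set"), inherits(rules, "design_rules"))
  seqs <- set$sequence
  gc <- gc_content(seqs)
  gc_ok <- gc >= rules$gc_min & gc <= rules$gc_max
  rep_ok <- !violates_repeat_rule(seqs, rules$forbid_homopolymer_run)
  motif_ok <- if (rules$forbid_tandem_motif) !violates_motif_rule(seqs) else
    rep(TRUE, length(seqs))
  hm <- hamming_matrix(set)
  min_d <- if (length(set) > 1L) min(hm[upper.tri(hm)]) else NA_integer_
  dist_ok <- length(set) == 1L || min_d >= rules$min_pairwise_hamming

  rc_coll <- data.frame(index_id = character(0), collides_with = character(0),
                        stringsAsFactors = FALSE)
  rc_ok <- rep(TRUE, length(seqs))
  if (rules$require_rc_distinct) {
    rc <- reverse_complement(seqs)
    for (i in seq_along(seqs)) {
      hit <- which(seqs == rc[i])
      if (length(hit)) {
        rc_ok[i] <- FALSE
        rc_coll <- rbind(rc_coll, data.frame(
          index_id = set$index_id[i], collides_with = set$index_id[hit[1]],
          stringsAsFactors = FALSE))
      }
    }
  }

  reasons <- vapply(seq_along(seqs), function(i) {
    r <- character(0)
    if (!gc_ok[i]) r <- c(r, sprintf("GC %.2f outside [%.2f, %.2f]",
                                     gc[i], rules$gc_min, rules$gc_max))
    if (!rep_ok[i]) r <- c(r, sprintf("homopolymer run >= %d",
                                      rules$forbid_homopolymer_run))
    if (!motif_ok[i]) r <- c(r, "tandem 3-base motif")
    if (!rc_ok[i]) r <- c(r, "reverse-complement collision")
    paste(r, collapse = "; ")
  }, character(1))

  per_index <- data.frame(index_id = set$index_id, sequence = seqs, gc = gc,
                          gc_ok = gc_ok, repeat_ok = rep_ok,
                          motif_ok = motif_ok, rc_ok = rc_ok,
                          pass = gc_ok & rep_ok & motif_ok & rc_ok,
                          reasons = reasons, stringsAsFactors = FALSE)
  n_viol <- sum(!per_index$pass) + as.integer(!dist_ok)
  structure(list(per_index = per_index, hamming = hm, min_distance = min_d,
                 min_distance_ok = dist_ok, rc_collisions = rc_coll,
                 n_violations = n_viol, pass = n_viol == 0L, rules = rules),
            class = "index_validation")
}

#' @export
print.index_validation <- function(x, ...) {
  cat(sprintf("index set validation: %s (%d violation%s)\n",
              if (x$pass) "PASS" else "FAIL", x$n_violations,
              if (x$n_violations == 1L) "" else "s"))
  cat(sprintf("  min pairwise hamming distance: %s (required >= %d)\n",
              x$min_distance, x$rules$min_pairwise_hamming))
  bad <- x$per_index[!x$per_index$pass, , drop = FALSE]
  if (nrow(bad))
    for (i in seq_len(nrow(bad)))
      cat(sprintf("  %s: %s\n", bad$index_id[i], bad$reasons[i]))
  invisible(x)
}

#' Generate a rule-satisfying index set
#'
#' Rejection sampling with greedy accumulation: random candidates of the
#' requested length are kept when they satisfy all per-sequence rules and
#' the minimum hamming distance against every index accepted so far.
#' Deterministic for a fixed seed; fails explicitly if the search budget is
#' exhausted (as it must, e.g., when more sequences are requested than the
#' alphabet admits).
#'
#' @param n Number of indexes (>= 1).
#' @param length Bases per index (default 10).
#' @param rules A `design_rules` object.
#' @param seed Integer RNG seed.
#' @param max_attempts Search budget (default 1e5 candidate draws).
#' @return An `index_set` passing [validate_index_set()] with zero violations.
#' @export
generate_index_set <- function(n, length = 10L, rules = design_rules(),
                               seed = 1L, max_attempts = 1e5L) {
  stopifnot(n >= 1L, length >= 1L)
  if (rules$min_pairwise_hamming > length)
    stop("min_pairwise_hamming exceeds index length")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  accepted <- character(0)
  accepted_raw <- list()
  attempts <- 0L
  while (length(accepted) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    cand <- paste(sample(bases, length, replace = TRUE), collapse = "")
    if (cand %in% accepted) next
    gc <- gc_content(cand)
    if (gc < rules$gc_min || gc > rules$gc_max) next
    if (violates_repeat_rule(cand, rules$forbid_homopolymer_run)) next
    if (rules$forbid_tandem_motif && violates_motif_rule(cand)) next
    cr <- charToRaw(cand)
    if (length(accepted)) {
      d <- vapply(accepted_raw, function(r) sum(r != cr), integer(1))
      if (min(d) < rules$min_pairwise_hamming) next
    }
    if (rules$require_rc_distinct) {
      rc <- reverse_complement(cand)
      if (rc == cand || rc %in% accepted) next
      if (any(reverse_complement(accepted) == cand)) next
    }
    accepted <- c(accepted, cand)
    accepted_raw <- c(accepted_raw, list(cr))
  }
  if (length(accepted) < n)
    stop(sprintf("no set found: %d of %d indexes after %d attempts",
                 length(accepted), n, attempts))
  index_set(accepted)
}

#' Can a set be demultiplexed unambiguously at a mismatch radius?
#'
#' TRUE iff the minimum pairwise hamming distance is at least
#' `2 * max_mismatch + 1`, so every observed read within `max_mismatch` of
#' one index is within that radius of no other index.
#'
#' @param set An `index_set`.
#' @param max_mismatch Mismatch radius allowed at demultiplexing.
#' @return Logical scalar.
#' @export
decode_capacity <- function(set, max_mismatch) {
  stopifnot(inherits(set, "index_set"), max_mismatch >= 0L)
  if (length(set) == 1L) return(TRUE)
  hm <- hamming_matrix(set)
  min(hm[upper.tri(hm)]) >= 2L * max_mismatch + 1L
}

#' Read an index set from TSV or FASTA
#'
#' TSV must have two columns, `index_id` and `sequence` (header optional);
#' FASTA is detected by a leading `>`.
#'
#' @param path File path.
#' @return An `index_set`.
#' @export
read_index_set <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    ss <- Biostrings::readDNAStringSet(path)
    return(index_set(as.character(ss), index_id = names(ss)))
  }
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(df[1, 1]), "index_id")) df <- df[-1, , drop = FALSE]
  index_set(df[[2]], index_id = df[[1]])
}

#' Write an index set as 2-column TSV
#'
#' @param set An `index_set`.
#' @param path Output path.
#' @export
write_index_set <- function(set, path) {
  stopifnot(inherits(set, "index_set"))
  utils::write.table(as.data.frame(set), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
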