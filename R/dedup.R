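#' Classify the allele a read carries at a variant position
#'
#' Reads the base at `position` and classifies it against the reference and
#' mutant base; any third base is "other". Vectorised over reads.
#'
#' @param insert_seq Character vector of read sequences.
#' @param reference Reference sequence (used to check `ref_base`).
#' @param position 1-based variant position; must lie within every read.
#' @param ref_base,mut_base Single bases, distinct.
#' @return Character vector over {"ref", "mut", "other"}.
#' @export
observe_allele <- function(insert_seq, reference, position, ref_base,
                           mut_base) {
  if (position < 1 || position > min(nchar(insert_seq)))
    stop("variant position outside the read span")
  if (position <= nchar(reference) &&
      substr(reference, position, position) != ref_base)
    stop("ref_base does not match the reference at this position")
  if (identical(ref_base, mut_base)) stop("ref and mut base are identical")
  b <- substr(insert_seq, position, position)
  ifelse(b == ref_base, "ref", ifelse(b == mut_base, "mut", "other"))
}

#' Collapse UID read groups to template consensus alleles
#'
#' Groups reads by (uid, target), takes the strict majority of their
#' ref/mut observations as the template's consensus, and drops groups with
#' a ref/mut tie or with a majority of unclassifiable ("other") bases.
#' PCR duplicates thereby collapse to one template each, and isolated
#' sequencing errors inside a duplicate group are outvoted.
#'
#' @param uid Per-read UID (no missing values).
#' @param allele Per-read classification from [observe_allele()].
#' @param target_id Optional per-read target; groups are formed within
#'   target when given.
#' @return Object of class `uid_groups`: data frame `groups` (uid,
#'   target_id, n_reads, n_ref, n_mut, n_other, consensus in
#'   {"ref","mut","dropped"}) and `templates`, the named consensus tally
#'   (ref, mut, dropped).
#' @export
collapse_uids <- function(uid, allele, target_id = NULL) {
  if (anyNA(uid) || any(!nzchar(uid))) stop("missing UID on a read")
  stopifnot(length(allele) == length(uid),
            all(allele %in% c("ref", "mut", "other")))
  if (is.null(target_id)) target_id <- rep("target", length(uid))
  key <- paste(target_id, uid, sep = "\r")
  n_ref <- rowsum(as.numeric(allele == "ref"), key)
  n_mut <- rowsum(as.numeric(allele == "mut"), key)
  n_oth <- rowsum(as.numeric(allele == "other"), key)
  keys <- rownames(n_ref)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  consensus <- ifelse(n_oth > n_ref + n_mut, "dropped",
               ifelse(n_mut > n_ref, "mut",
               ifelse(n_ref > n_mut, "ref", "dropped")))
  groups <- data.frame(
    uid = vapply(parts, `[`, character(1), 2L),
    target_id = vapply(parts, `[`, character(1), 1L),
    n_reads = as.numeric(n_ref + n_mut + n_oth),
    n_ref = as.numeric(n_ref), n_mut = as.numeric(n_mut),
    n_other = as.numeric(n_oth), consensus = as.character(consensus),
    row.names = NULL, stringsAsFactors = FALSE)
  templates <- c(ref = sum(groups$consensus == "ref"),
                 mut = sum(groups$consensus == "mut"),
                 dropped = sum(groups$consensus == "dropped"))
  structure(list(groups = groups, templates = templates),
            class = "uid_groups")
}

#' @export
print.uid_groups <- function(x, ...) {
  cat(sprintf("uid_groups: %d templates from %d reads (ref %d, mut %d, dropped %d)\n",
              nrow(x$groups), sum(x$groups$n_reads), x$templates[["ref"]],
              x$templates[["mut"]], x$templates[["dropped"]]))
  invisible(x)
}

#' Mutant allele rate
#'
#' Mutant observations divided by the sum of mutant and reference
#' observations (reads before deduplication, templates after).
#'
#' @param mut,ref Non-negative counts; `mut + ref` must be > 0.
#' @return Fraction.
#' @export
allele_rate <- function(mut, ref) {
  stopifnot(mut >= 0, ref >= 0)
  if (any(mut + ref == 0)) stop("undefined allele rate: no observations")
  mut / (mut + ref)
}

#' Call a variant positive or negative
#'
#' Positive iff the allele rate reaches `min_rate` and the mutant template
#' count reaches `min_mut_templates`. The defaults (0.5% and 3 templates)
#' sit between the contamination-level rates observed in negative
#' libraries (at or below 0.05%) and the 1% sensitivity a spike-in series
#' should still call.
#'
#' @param rate Allele rate fraction.
#' @param mut_templates Mutant template (or read) count.
#' @param min_rate,min_mut_templates Calling thresholds.
#' @return "positive" or "negative" (vectorised).
#' @export
call_variant <- function(rate, mut_templates, min_rate = 0.005,
                         min_mut_templates = 3) {
  ifelse(rate >= min_rate & mut_templates >= min_mut_templates,
         "positive", "negative")
}
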