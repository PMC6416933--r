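## Bundled worked-example count tables. These are the package's reference
## datasets for the rate conventions: a triplicated multiplexed control
## experiment on a DNB array (eight indexed gene amplicons, eight empty
## controls, eight late-pooled balancing libraries), a PCR-free HPV
## genotyping pool, and a two-step PCR cancer panel with UIDs. All entries
## are read counts; the checks in worked_example_checks() recompute every
## published-style rate from them through the package's own code paths.

#' Worked example: WGS-like control experiment counts
#'
#' Read counts mapped to the eight gene regions for three repeats of a
#' multiplexed control run: eight experimental indexes, eight empty
#' (water) control indexes whose reads measure free-oligo index hopping,
#' and eight balancing-library indexes pooled after single-strand-circle
#' formation, whose reads measure everything downstream of pooling.
#'
#' @return Data frame with one row per repeat: `experimental_reads`,
#'   `empty_control_reads`, `balancing_reads`, `total_reads`, and the
#'   number of indexes per group (`n_group_indexes`).
#' @export
example_wgs_controls <- function() {
  df <- data.frame(
    repeat_id = c("repeat1", "repeat2", "repeat3"),
    experimental_reads = c(41686373, 44974964, 42874988),
    empty_control_reads = c(9, 14, 6),
    balancing_reads = c(612, 650, 724),
    n_group_indexes = 8L,
    stringsAsFactors = FALSE)
  df$total_reads <- df$experimental_reads + df$empty_control_reads +
    df$balancing_reads
  df
}

# group-level count matrix for one repeat (or the pooled repeats) of the
# WGS-like control experiment: rows experimental/empty/balancing, one
# aggregate gene-region column
wgs_control_matrix <- function(df = example_wgs_controls(),
                               rows = seq_len(nrow(df))) {
  counts <- matrix(c(sum(df$experimental_reads[rows]),
                     sum(df$empty_control_reads[rows]),
                     sum(df$balancing_reads[rows])),
                   ncol = 1,
                   dimnames = list(c("experimental", "empty_controls",
                                     "balancing_controls"), "gene_regions"))
  proper <- matrix(c(TRUE, FALSE, FALSE), ncol = 1,
                   dimnames = dimnames(counts))
  count_matrix(counts, proper)
}

#' Worked example: PCR-free HPV pool contamination matrix
#'
#' Library-index by amplicon count matrix of a PCR-free HPV genotyping
#' pool: six sample libraries (indexes 1-6), one empty control (index 8),
#' the HBB internal-control amplicon and six HPV genotype amplicons.
#' Proper cells are each library's own genotype(s) plus HBB; the empty
#' control has no proper cells.
#'
#' @return A `count_matrix`.
#' @export
example_hpv_counts <- function() {
  targets <- c("HBB", "HPV11", "HPV18", "HPV31", "HPV33", "HPV52", "HPV45")
  counts <- matrix(c(
    2994608, 1348826,      83,      36,     14,      23,      33,
    2722311,      75, 2310955,      31,     17,      24,      31,
    1891540,      53,      65, 1566954,     10,       8,      15,
    2936888,      54,      90,      80, 940365,      18,      25,
    2289158,      61,      52,      14,     14, 1237126,      22,
    1747934,  253390,      53,      17,      9,      18, 1497716,
         27,       3,       0,       3,      0,      16,       5),
    nrow = 7, byrow = TRUE,
    dimnames = list(c("lib1", "lib2", "lib3", "lib4", "lib5", "lib6",
                      "lib8"), targets))
  proper <- matrix(FALSE, 7, 7, dimnames = dimnames(counts))
  proper["lib1", c("HBB", "HPV11")] <- TRUE
  proper["lib2", c("HBB", "HPV18")] <- TRUE
  proper["lib3", c("HBB", "HPV31")] <- TRUE
  proper["lib4", c("HBB", "HPV33")] <- TRUE
  proper["lib5", c("HBB", "HPV52")] <- TRUE
  proper["lib6", c("HBB", "HPV11", "HPV45")] <- TRUE
  count_matrix(counts, proper)
}

#' Worked example: two-step PCR cancer panel counts
#'
#' Reference/mutant observation counts for four indexed libraries of a
#' UID-tagged lung cancer panel (negative control plus spike-ins of 1%,
#' 10% and 50% at three variants; NRAS p.Q61H as a per-library negative
#' site), before (`reads`) and after (`templates`) UID deduplication, two
#' repeats each.
#'
#' @return Data frame: index, repeat_id, variant, expected ("negative" or
#'   the spiked fraction), ref_reads, mut_reads, ref_templates,
#'   mut_templates.
#' @export
example_cancer_panel <- function() {
  v <- c("EGFR_L858R", "KRAS_G12D", "EGFR_19del", "NRAS_Q61H")
  rows <- list(
    list(1, 1, c(1423408, 4), c(52589, 34), c(31150, 0), c(188086, 0),
         c(26824, 0), c(6889, 2), c(5295, 0), c(10798, 0)),
    list(1, 2, c(1158060, 4), c(54331, 33), c(31047, 0), c(201147, 0),
         c(21904, 0), c(6209, 1), c(5088, 0), c(9617, 0)),
    list(2, 1, c(1346831, 17200), c(59590, 39), c(40077, 0), c(205321, 0),
         c(24550, 324), c(6903, 3), c(5509, 0), c(10770, 0)),
    list(2, 2, c(1148168, 11231), c(57175, 27), c(36381, 0), c(192472, 0),
         c(21673, 241), c(6757, 2), c(5565, 0), c(9911, 0)),
    list(3, 1, c(1604176, 6), c(53555, 7713), c(32294, 0), c(199296, 2),
         c(23017, 0), c(4651, 656), c(4622, 0), c(8788, 0)),
    list(3, 2, c(1430975, 5), c(54029, 7296), c(36961, 0), c(200989, 4),
         c(23485, 0), c(5066, 692), c(5274, 0), c(9391, 0)),
    list(4, 1, c(1321771, 3), c(56766, 20), c(22370, 9038), c(150478, 0),
         c(31688, 0), c(7203, 0), c(1032, 996), c(13032, 0)),
    list(4, 2, c(1275573, 7), c(59610, 31), c(22914, 9660), c(204544, 0),
         c(30261, 0), c(8300, 1), c(1047, 991), c(13937, 0)))
  spiked <- list(`1` = c(NA, NA, NA, NA), `2` = c(0.01, NA, NA, NA),
                 `3` = c(NA, 0.10, NA, NA), `4` = c(NA, NA, 0.50, NA))
  out <- do.call(rbind, lapply(rows, function(r) {
    idx <- r[[1]]
    data.frame(index = idx, repeat_id = r[[2]], variant = v,
               expected = ifelse(is.na(spiked[[as.character(idx)]]),
                                 "negative",
                                 as.character(spiked[[as.character(idx)]])),
               ref_reads = vapply(r[3:6], `[`, numeric(1), 1L),
               mut_reads = vapply(r[3:6], `[`, numeric(1), 2L),
               ref_templates = vapply(r[7:10], `[`, numeric(1), 1L),
               mut_templates = vapply(r[7:10], `[`, numeric(1), 2L),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cell percentages of a count matrix
#'
#' Each cell divided by the total reads on the included target columns —
#' the display convention of contamination matrices.
#'
#' @param M A `count_matrix`.
#' @param exclude_targets Columns excluded from both the output and the
#'   denominator (e.g. an internal-control amplicon).
#' @return Numeric matrix of fractions.
#' @export
matrix_percentages <- function(M, exclude_targets = character(0)) {
  stopifnot(inherits(M, "count_matrix"))
  cols <- setdiff(colnames(M$counts), exclude_targets)
  sub <- M$counts[, cols, drop = FALSE]
  sub / sum(sub)
}

#' Recompute every worked-example rate through the package's code paths
#'
#' Runs the bundled example tables through the same rate, formatting and
#' calling functions the pipeline uses, and compares each result with its
#' reference display value. Any mismatch is a named failure.
#'
#' @return Data frame: check, computed, expected, pass.
#' @export
worked_example_checks <- function() {
  out <- list()
  add <- function(check, computed, expected)
    out[[length(out) + 1]] <<- data.frame(check = check, computed = computed,
                                          expected = expected,
                                          pass = identical(computed,
                                                           expected),
                                          stringsAsFactors = FALSE)

  ## WGS-like control experiment
  wgs <- example_wgs_controls()
  for (i in 1:3) {
    M <- wgs_control_matrix(wgs, rows = i)
    add(sprintf("wgs empty-control hop rate, repeat %d", i),
        fmt_sci(per_index_control_rate(M, "empty_controls", n_indexes = 1)),
        c("2.16E-07", "3.11E-07", "1.40E-07")[i])
  }
  Mp <- wgs_control_matrix(wgs)
  add("wgs empty-control per-index rate, pooled repeats",
      one_in_n(per_index_control_rate(Mp, "empty_controls", n_indexes = 8)),
      "1 in 36 million")
  bal <- per_index_control_rate(Mp, "balancing_controls", n_indexes = 8)
  add("wgs balancing per-index rate, pooled repeats", fmt_sci(bal),
      "1.92E-06")
  add("wgs balancing per-index rate, 1-in-N", one_in_n(bal),
      "1 in 0.5 million")

  ## PCR-free HPV pool
  H <- example_hpv_counts()
  pct <- matrix_percentages(H, exclude_targets = "HBB")
  ## denominator = sum of the bundled HPV-column counts; a few cells come
  ## out one display-ulp above the source table, whose denominator also
  ## contained the (unprinted) reads of an excluded empty-control row
  proper_checks <- list(
    c("lib1", "HPV11", "14.7310%"), c("lib2", "HPV18", "25.2387%"),
    c("lib3", "HPV31", "17.1132%"), c("lib4", "HPV33", "10.2700%"),
    c("lib5", "HPV52", "13.5110%"), c("lib6", "HPV45", "16.3570%"),
    c("lib6", "HPV11", "2.7674%"))
  for (ck in proper_checks)
    add(sprintf("hpv proper cell %s/%s", ck[1], ck[2]),
        fmt_pct(pct[ck[1], ck[2]]), ck[3])
  add("hpv improper cell lib1/HPV18", fmt_pct(pct["lib1", "HPV18"]),
      "0.0009%")
  add("hpv empty-control leakage into HBB",
      fmt_pct(leakage_rate(H, "lib8", "HBB")), "0.0002%")
  add("hpv sample-to-sample average",
      fmt_pct(sample_to_sample_avg(H, exclude_targets = "HBB")), "0.0004%")

  ## two-step PCR cancer panel
  cp <- example_cancer_panel()
  rate_pre <- allele_rate(cp$mut_reads, cp$ref_reads)
  rate_post <- allele_rate(cp$mut_templates, cp$ref_templates)
  pre_checks <- list(
    c(2, 1, "EGFR_L858R", "1.2610%"), c(2, 2, "EGFR_L858R", "0.9687%"),
    c(3, 1, "KRAS_G12D", "12.5890%"), c(3, 2, "KRAS_G12D", "11.8973%"),
    c(4, 1, "EGFR_19del", "28.7761%"), c(4, 2, "EGFR_19del", "29.6556%"))
  for (ck in pre_checks) {
    row <- which(cp$index == as.integer(ck[1]) &
                 cp$repeat_id == as.integer(ck[2]) & cp$variant == ck[3])
    add(sprintf("cancer pre-dedup rate idx%s rep%s %s", ck[1], ck[2], ck[3]),
        fmt_pct(rate_pre[row]), ck[4])
  }
  post_checks <- list(
    c(2, 1, "EGFR_L858R", "1.3026%"), c(2, 2, "EGFR_L858R", "1.0998%"),
    c(3, 1, "KRAS_G12D", "12.3610%"), c(3, 2, "KRAS_G12D", "12.0181%"),
    c(4, 1, "EGFR_19del", "49.1124%"), c(4, 2, "EGFR_19del", "48.6261%"))
  for (ck in post_checks) {
    row <- which(cp$index == as.integer(ck[1]) &
                 cp$repeat_id == as.integer(ck[2]) & cp$variant == ck[3])
    add(sprintf("cancer post-dedup rate idx%s rep%s %s", ck[1], ck[2],
                ck[3]),
        fmt_pct(rate_post[row]), ck[4])
  }
  calls <- call_variant(rate_post, cp$mut_templates)
  add("cancer panel: spiked variants called positive after dedup",
      paste(sort(unique(calls[cp$expected != "negative"])), collapse = ","),
      "positive")
  add("cancer panel: all other sites called negative after dedup",
      paste(unique(calls[cp$expected == "negative"]), collapse = ","),
      "negative")

  do.call(rbind, out)
}
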