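toy_matrix <- function() {
  counts <- matrix(c(100, 1, 2, 97), 2, 2, byrow = TRUE,
                   dimnames = list(c("i1", "i2"), c("t1", "t2")))
  count_matrix(counts, diag(2) == 1)
}

test_that("count matrices tally assignments and conserve reads", {
  set <- fix_set(); panel <- fix_panel()
  sheet <- default_sample_sheet(set, panel)
  idx <- c(set$index_id[c(1, 1, 2, 2, 2, 3)])
  tgt <- c(panel$target_id[c(1, 2, 2, 2, 1, 3)])
  M <- build_count_matrix(idx, tgt, sheet, targets = panel$target_id)
  expect_equal(M$counts[set$index_id[1], panel$target_id[1]], 1)
  expect_equal(M$counts[set$index_id[1], panel$target_id[2]], 1)
  expect_equal(M$counts[set$index_id[2], panel$target_id[2]], 2)
  expect_equal(sum(M$counts), 6)
  expect_error(build_count_matrix("nope", panel$target_id[1], sheet),
               "not present")
  # unmapped and filtered reads never enter the matrix
  M2 <- build_count_matrix(c(idx, "filtered_out", set$index_id[1]),
                           c(tgt, panel$target_id[1], "unmapped"), sheet,
                           targets = panel$target_id)
  expect_equal(sum(M2$counts), 6)
})

test_that("total contamination is the improper share of all reads", {
  expect_equal(total_contamination_rate(toy_matrix()), 3 / 200)
  allp <- count_matrix(matrix(5, 2, 2, dimnames = list(c("a", "b"),
                                                       c("x", "y"))),
                       matrix(TRUE, 2, 2))
  expect_equal(total_contamination_rate(allp), 0)
})

test_that("control-index rates reproduce the worked control experiment", {
  counts <- matrix(c(1000, 2, 4), ncol = 1,
                   dimnames = list(c("exp", "ctlA", "ctlB"), "genes"))
  M <- count_matrix(counts, matrix(c(TRUE, FALSE, FALSE), ncol = 1))
  expect_equal(per_index_control_rate(M, c("ctlA", "ctlB"), 2),
               6 / 1006 / 2)
  expect_equal(per_index_control_rate(M, "ctlA", 1), 2 / 1006)
  # bundled triplicate control experiment, through the same code path
  ck <- worked_example_checks()
  wgs <- ck[grepl("^wgs", ck$check), ]
  expect_true(all(wgs$pass))
})

test_that("leakage divides control reads by the target column total", {
  counts <- matrix(c(960, 5, 40, 0), 2, 2,
                   dimnames = list(c("s1", "empty"), c("hbb", "hpv")))
  M <- count_matrix(counts, matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2))
  expect_equal(leakage_rate(M, "empty", "hbb"), 5 / 965)
  expect_equal(leakage_rate(M, "empty", "hpv"), 0)
  expect_error(leakage_rate(M, "s1", "hbb"), "no proper cells")
})

test_that("sample-to-sample average matches hand arithmetic on a toy", {
  counts <- matrix(c(900, 3, 6,
                     9, 800, 12,
                     0, 0, 700), 3, 3, byrow = TRUE,
                   dimnames = list(c("a", "b", "c"), c("ta", "tb", "tc")))
  M <- count_matrix(counts, diag(3) == 1)
  expect_equal(sample_to_sample_avg(M),
               mean(c(3, 6, 9, 12, 0, 0)) / sum(counts))
  diagM <- count_matrix(diag(c(10, 10, 10)) +
                          matrix(0, 3, 3,
                                 dimnames = list(letters[1:3],
                                                 LETTERS[1:3])),
                        diag(3) == 1)
  expect_equal(sample_to_sample_avg(diagM), 0)
})

test_that("one_in_n follows the reciprocal phrasing conventions", {
  expect_identical(one_in_n(0.5), "1 in 2")
  expect_identical(one_in_n(0), "0 observed")
  expect_identical(one_in_n(1 / 1223), "1 in 1,223")
  expect_identical(one_in_n(29 / (129538340 * 8)), "1 in 36 million")
  expect_identical(one_in_n(1.92e-6), "1 in 0.5 million")
})

test_that("display formats render rates the way reports print them", {
  expect_identical(fmt_sci(9 / 41686994), "2.16E-07")
  expect_identical(fmt_pct(27 / 14582466), "0.0002%")
  expect_identical(fmt_pct(0.147309), "14.7309%")
})

test_that("excluding an index equals recomputation from reduced data", {
  set <- fix_set(); panel <- fix_panel()
  sheet <- default_sample_sheet(set, panel)
  set.seed(61)
  n <- 5000
  idx <- sample(set$index_id, n, TRUE)
  tgt <- ifelse(stats::runif(n) < 0.9,
                panel$target_id[match(idx, set$index_id)],
                sample(panel$target_id, n, TRUE))
  M <- build_count_matrix(idx, tgt, sheet, targets = panel$target_id)
  Mx <- exclude_index(M, set$index_id[7])
  keep <- idx != set$index_id[7] & tgt != panel$target_id[7]
  Mr <- build_count_matrix(idx[keep], tgt[keep], sheet[-7, ],
                           targets = panel$target_id[-7])
  expect_equal(Mx$counts, Mr$counts)
  expect_equal(total_contamination_rate(Mx), total_contamination_rate(Mr))
  # an all-zero control row changes nothing when dropped
  M0 <- count_matrix(rbind(toy_matrix()$counts, zero = c(0, 0)),
                     rbind(toy_matrix()$proper, zero = c(FALSE, FALSE)))
  expect_equal(total_contamination_rate(exclude_index(M0, "zero")),
               total_contamination_rate(toy_matrix()))
})

test_that("excluding a heavily contaminated index lowers the total rate", {
  set <- fix_set(); panel <- fix_panel()
  sheet <- default_sample_sheet(set, panel)
  # index 7's oligo pool contaminates every other sample at 1%
  oc <- diag(nrow(sheet))
  for (i in seq_len(nrow(sheet))[-7]) { oc[i, i] <- 0.99; oc[i, 7] <- 0.01 }
  cfg <- run_config(40000, panel, sheet, p_hop = 0, p_template_switch = 0,
                    p_bleed = 0, seq_error = 0, oligo_contam = oc,
                    seed = 67)
  run <- simulate_run(cfg, set)
  dm <- demux_run(run$reads, set, demux_params(max_mismatch = 0))
  tgt <- assign_target(run$reads$insert_seq, panel)
  M <- build_count_matrix(dm$assignments$index_id, tgt, sheet,
                          targets = panel$target_id)
  r0 <- total_contamination_rate(M)
  r1 <- total_contamination_rate(exclude_index(M, set$index_id[7]))
  expect_lt(r1, r0)
  # contaminated share: 7/8 of reads leak at 1% into index 7
  expect_lt(abs(r0 - 0.01 * 7 / 8), binom_3sigma(40000, 0.01 * 7 / 8))
  expect_lt(r1, 0.1 * r0)
})

test_that("neighbor sharing handles borders, strata and degenerate arrays", {
  expect_equal(neighbor_sharing(0, 0, "i1")$pct_sharing, 0)
  ns2 <- neighbor_sharing(c(0, 1), c(0, 0), c("i1", "i1"))
  expect_equal(ns2$pct_sharing, 1)
  expect_error(neighbor_sharing(c(0, 0), c(0, 0), c("a", "b")),
               "duplicate")
  ns <- neighbor_sharing(c(0, 1, 2), c(0, 0, 0), c("a", "a", "b"),
                         correct = c(TRUE, TRUE, FALSE))
  expect_equal(ns$pct_correct_sharing, 1)
  expect_equal(ns$pct_misassigned_sharing, 0)
})

test_that("the Q30 filter sweep retains monotonically and cuts bleed", {
  fx <- fix_config(n_reads = 30000, seed = 71, p_hop = 0,
                   p_template_switch = 0, p_bleed = 0.01)
  run <- simulate_run(fx$config, fx$set)
  sw <- filter_sweep(run, c(0, 0.2, 0.4, 0.6, 0.8))
  expect_equal(sw$retained_fraction[1], 1)
  expect_true(all(diff(sw$retained_fraction) <= 0))
  # bled spots carry low-quality index reads, so the filter removes them
  expect_lt(sw$total_rate[sw$threshold == 0.6],
            sw$total_rate[sw$threshold == 0])
})

test_that("mis-assigned reads show the low-quality index signature", {
  fx <- fix_config(n_reads = 30000, seed = 73, p_hop = 0,
                   p_template_switch = 0, p_bleed = 0.01)
  run <- simulate_run(fx$config, fx$set)
  dm <- demux_run(run$reads, fx$set, demux_params(max_mismatch = 1))
  diag_ <- misassignment_diagnostics(dm$assignments, run$truth)
  expect_lt(diag_$mean_q30_index[diag_$stratum == "misassigned"],
            diag_$mean_q30_index[diag_$stratum == "correct"])
})
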