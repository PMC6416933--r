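test_that("make_panel keeps references distant and is seed-stable", {
  p <- make_panel(8, 400, seed = 2)
  expect_equal(nrow(p), 8)
  hm <- hamming_matrix(stats::setNames(p$sequence, p$target_id))
  expect_gte(min(hm[upper.tri(hm)]), 100)
  expect_identical(p$sequence, make_panel(8, 400, seed = 2)$sequence)
  expect_equal(nrow(make_panel(1, 60, seed = 1)), 1)
})

test_that("linear amplification keeps the wrong fraction at h", {
  expect_equal(amplify_linear(0, 1000, seed = 1), 0)
  expect_equal(amplify_linear(1, 1000, seed = 1), 1)
  f <- amplify_linear(0.01, 1e5, seed = 3)
  expect_lt(abs(f - 0.01), binom_3sigma(1e5, 0.01))
})

test_that("exponential amplification matches the branching recursion", {
  expect_equal(amplify_exponential(0, 8, seed = 1), 0)
  # one cycle: population 2, the new copy is wrong with prob h, so the
  # expected wrong fraction enumerates to h / 2
  set.seed(4)
  fr <- replicate(4000, amplify_exponential(0.5, 1))
  expect_true(all(fr %in% c(0, 0.5)))
  expect_lt(abs(mean(fr) - 0.25), 3 * stats::sd(fr) / sqrt(length(fr)))
  # closed-form expectation as the oracle for deep amplification
  set.seed(5)
  fr10 <- replicate(1000, amplify_exponential(0.01, 10))
  exp10 <- expected_exponential_wrong_fraction(0.01, 10)
  expect_lt(abs(mean(fr10) - exp10), 3 * stats::sd(fr10) / sqrt(1000))
  expect_error(amplify_exponential(0.01, 25), "cycles")
})

test_that("spot majority calls are conservative on ties", {
  r <- call_spot_index(c(99, 1, 50), c(1, 3, 50))
  expect_identical(r$call, c("right", "wrong", "wrong"))
  expect_equal(r$purity, c(0.99, 0.75, 0.5))
  # linear mode with h < 0.5: no spot of many copies reaches wrong majority
  set.seed(8)
  wrong <- stats::rbinom(1e4, 100, 0.05)
  expect_identical(unique(call_spot_index(100 - wrong, wrong)$call), "right")
})

test_that("the null configuration produces zero contamination", {
  fx <- fix_null_config(n_reads = 4000)
  run <- simulate_run(fx$config, fx$set)
  expect_identical(unique(run$truth$mechanism), "clean")
  expect_identical(run$truth$observed_index_id, run$truth$true_index_id)
  dm <- demux_run(run$reads, fx$set, demux_params(max_mismatch = 0))
  tgt <- assign_target(run$reads$insert_seq, fx$panel)
  M <- build_count_matrix(dm$assignments$index_id, tgt, fx$sheet,
                          targets = fx$panel$target_id)
  expect_equal(total_contamination_rate(M), 0)
  expect_equal(sum(M$counts), 4000)
})

test_that("mechanism tags occur at their configured probabilities", {
  fx <- fix_config(n_reads = 1e5, seed = 21, p_hop = 0.002,
                   p_template_switch = 0, p_bleed = 0.004,
                   seq_error = 0)
  run <- simulate_run(fx$config, fx$set)
  tab <- table(factor(run$truth$mechanism,
                      levels = c("clean", "hop", "bleed")))
  n <- 1e5
  # bleeding overrides the hop tag, so P(hop tag) = p_hop * (1 - p_bleed)
  expect_lt(abs(tab[["bleed"]] / n - 0.004), binom_3sigma(n, 0.004))
  p_hop_tag <- 0.002 * (1 - 0.004)
  expect_lt(abs(tab[["hop"]] / n - p_hop_tag), binom_3sigma(n, p_hop_tag))
  expect_equal(sum(tab), n)  # tags partition the reads
})

test_that("oligo contamination surfaces in the count matrix at its rate", {
  set <- fix_set(); panel <- fix_panel()
  sheet <- default_sample_sheet(set, panel)
  oc <- diag(nrow(sheet))
  oc[1, ] <- c(0.99, 0.01, rep(0, nrow(sheet) - 2))  # sample 1 leaks to idx 2
  fx_cfg <- run_config(1e5, panel, sheet, p_hop = 0, p_template_switch = 0,
                       p_bleed = 0, seq_error = 0, oligo_contam = oc,
                       seed = 31)
  run <- simulate_run(fx_cfg, set)
  dm <- demux_run(run$reads, set, demux_params(max_mismatch = 0))
  tgt <- assign_target(run$reads$insert_seq, panel)
  M <- build_count_matrix(dm$assignments$index_id, tgt, sheet,
                          targets = panel$target_id)
  n1 <- sum(run$truth$true_sample_id == sheet$sample_id[1])
  leak <- M$counts[set$index_id[2], panel$target_id[1]]
  expect_lt(abs(leak / n1 - 0.01), binom_3sigma(n1, 0.01))
  expect_identical(sort(unique(run$truth$mechanism)),
                   c("clean", "oligo_contam"))
})

test_that("identical seeds give byte-identical FASTQ output", {
  fx <- fix_config(n_reads = 1500, seed = 77)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_run_fastq(simulate_run(fx$config, fx$set), d1)
  p2 <- write_run_fastq(simulate_run(fx$config, fx$set), d2)
  expect_identical(unname(tools::md5sum(p1[["reads"]])),
                   unname(tools::md5sum(p2[["reads"]])))
  expect_identical(unname(tools::md5sum(p1[["index"]])),
                   unname(tools::md5sum(p2[["index"]])))
})

test_that("FASTQ output round-trips through the paired reader", {
  fx <- fix_config(n_reads = 300, seed = 13, uid_length = 8)
  run <- simulate_run(fx$config, fx$set)
  paths <- write_run_fastq(run, tempfile())
  back <- read_run_fastq(paths[["reads"]], paths[["index"]])
  expect_identical(back$insert_seq, run$reads$insert_seq)
  expect_identical(back$index_quals, run$reads$index_quals)
  expect_identical(back$x, run$reads$x)
  expect_identical(back$uid, run$reads$uid)
})

test_that("mutant spiking and UID duplication keep their books", {
  panel <- fix_panel(n = 1, len = 120, seed = 17)
  m0 <- spike_mutants(panel, panel$target_id[1], 30, mut_base = "A",
                      fraction = 0, n_molecules = 500, seed = 1)
  skip_base <- substr(panel$sequence[1], 30, 30)
  if (skip_base == "A")  # pick a base that differs from the reference
    m0 <- spike_mutants(panel, panel$target_id[1], 30, mut_base = "C",
                        fraction = 0, n_molecules = 500, seed = 1)
  expect_identical(unique(m0$allele), "ref")
  mut_base <- setdiff(c("A", "C", "G", "T"),
                      substr(panel$sequence[1], 30, 30))[1]
  m5 <- spike_mutants(panel, panel$target_id[1], 30, mut_base = mut_base,
                      fraction = 0.5, n_molecules = 1e4, seed = 2)
  expect_lt(abs(mean(m5$allele == "mut") - 0.5), binom_3sigma(1e4, 0.5))
  reads <- attach_uids(m5[1:200, ], uid_length = 10,
                       duplication = function(n) rep(3L, n),
                       seq_error = 0, seed = 3)
  expect_equal(nrow(reads), 600)
  expect_equal(length(unique(reads$uid)), 200)
})
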