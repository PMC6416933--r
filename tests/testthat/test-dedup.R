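test_that("observe_allele classifies the base at the variant position", {
  ref <- "ACGTACGTAC"
  expect_identical(observe_allele("ACGTACGTAC", ref, 4, "T", "G"), "ref")
  expect_identical(observe_allele("ACGGACGTAC", ref, 4, "T", "G"), "mut")
  expect_identical(observe_allele("ACGAACGTAC", ref, 4, "T", "G"), "other")
  expect_error(observe_allele("ACGT", ref, 9, "A", "C"), "outside")
  expect_error(observe_allele("ACGTACGTAC", ref, 4, "A", "C"),
               "does not match")
})

test_that("UID collapse takes strict majorities and drops ties", {
  g <- collapse_uids(rep("u1", 3), c("mut", "mut", "ref"))
  expect_equal(g$templates[["mut"]], 1)
  g2 <- collapse_uids(c("u1", "u1"), c("mut", "ref"))
  expect_identical(g2$groups$consensus, "dropped")
  g3 <- collapse_uids(c("u1", "u1", "u1"), c("other", "other", "ref"))
  expect_identical(g3$groups$consensus, "dropped")
  expect_error(collapse_uids(c("u1", NA), c("ref", "ref")), "missing UID")
  # templates never exceed reads, per target and allele
  set.seed(3)
  uid <- sample(sprintf("u%02d", 1:20), 100, TRUE)
  al <- sample(c("ref", "mut"), 100, TRUE, prob = c(0.9, 0.1))
  g4 <- collapse_uids(uid, al)
  expect_lte(g4$templates[["mut"]], sum(al == "mut"))
  expect_lte(sum(g4$templates), 100)
  # idempotence: collapsing the consensus templates changes nothing
  kept <- g4$groups[g4$groups$consensus != "dropped", ]
  g5 <- collapse_uids(kept$uid, kept$consensus)
  expect_equal(g5$templates[["mut"]], g4$templates[["mut"]])
  expect_equal(g5$templates[["ref"]], g4$templates[["ref"]])
})

test_that("allele rates reproduce the worked cancer-panel arithmetic", {
  expect_identical(fmt_pct(allele_rate(17200, 1346831)), "1.2610%")
  expect_identical(fmt_pct(allele_rate(324, 24550)), "1.3026%")
  expect_identical(fmt_pct(allele_rate(996, 1032)), "49.1124%")
  expect_equal(allele_rate(0, 100), 0)
  expect_error(allele_rate(0, 0), "undefined")
})

test_that("variant calling needs both rate and template support", {
  expect_identical(call_variant(0.0005, 1000), "negative")  # 0.05% level
  expect_identical(call_variant(0.013026, 324), "positive")
  expect_identical(call_variant(0, 0), "negative")
  expect_identical(call_variant(0.5, 2), "negative")  # too few templates
})

test_that("UID dedup pulls the allele rate toward the spiked fraction", {
  panel <- fix_panel(n = 1, len = 120, seed = 81)
  pos <- 30
  mut_base <- setdiff(c("A", "C", "G", "T"),
                      substr(panel$sequence[1], pos, pos))[1]
  ref_base <- substr(panel$sequence[1], pos, pos)
  wins <- 0
  for (s in 1:10) {
    mols <- spike_mutants(panel, panel$target_id[1], pos, mut_base,
                          fraction = 0.01, n_molecules = 3000, seed = s)
    reads <- attach_uids(mols, uid_length = 10, seq_error = 0.02,
                         q_low = 12, p_lowq_base = 0.3, seed = s + 100)
    al <- observe_allele(reads$insert_seq, panel$sequence[1], pos,
                         ref_base, mut_base)
    pre <- allele_rate(sum(al == "mut"), sum(al == "ref"))
    g <- collapse_uids(reads$uid, al)
    post <- allele_rate(g$templates[["mut"]], g$templates[["ref"]])
    if (abs(post - 0.01) < abs(pre - 0.01)) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("error-free libraries report the spiked fraction exactly", {
  panel <- fix_panel(n = 1, len = 120, seed = 83)
  pos <- 10
  mut_base <- setdiff(c("A", "C", "G", "T"),
                      substr(panel$sequence[1], pos, pos))[1]
  ref_base <- substr(panel$sequence[1], pos, pos)
  mols <- spike_mutants(panel, panel$target_id[1], pos, mut_base,
                        fraction = 0.5, n_molecules = 2000, seed = 7)
  # 16 bp UIDs: collision probability ~5e-7 at 2000 molecules, so template
  # counts must match molecule counts exactly
  reads <- attach_uids(mols, uid_length = 16, seq_error = 0, seed = 8)
  al <- observe_allele(reads$insert_seq, panel$sequence[1], pos,
                       ref_base, mut_base)
  g <- collapse_uids(reads$uid, al)
  expect_equal(g$templates[["dropped"]], 0)
  expect_equal(g$templates[["mut"]], sum(mols$allele == "mut"))
  # negative control: zero mutant molecules -> rate exactly 0
  neg <- spike_mutants(panel, panel$target_id[1], pos, mut_base,
                       fraction = 0, n_molecules = 500, seed = 9)
  nreads <- attach_uids(neg, uid_length = 10, seq_error = 0, seed = 10)
  nal <- observe_allele(nreads$insert_seq, panel$sequence[1], pos,
                        ref_base, mut_base)
  ng <- collapse_uids(nreads$uid, nal)
  expect_equal(ng$templates[["mut"]], 0)
  expect_identical(call_variant(0, ng$templates[["mut"]]), "negative")
})
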