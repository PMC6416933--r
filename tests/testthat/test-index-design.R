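test_that("hamming_distance matches a position-by-position oracle", {
  expect_identical(hamming_distance("ACGTACGTAC", "ACGTACGTAC"), 0L)
  expect_identical(hamming_distance("ACGT", "ACGA"), 1L)
  expect_error(hamming_distance("ACG", "ACGT"), "equal length")
  # exhaustive over all pairs of 3-mers on {A, C}
  g <- do.call(expand.grid, rep(list(c("A", "C")), 3))
  mers <- apply(g, 1, paste, collapse = "")
  for (a in mers) for (b in mers)
    expect_identical(hamming_distance(a, b), as.integer(oracle_hamming(a, b)))
})

test_that("hamming_distance is a metric on fixed-length strings", {
  set.seed(3)
  for (rep in 1:50) {
    trip <- replicate(3, paste(sample(c("A", "C", "G", "T"), 8, TRUE),
                               collapse = ""))
    d12 <- hamming_distance(trip[1], trip[2])
    d21 <- hamming_distance(trip[2], trip[1])
    d13 <- hamming_distance(trip[1], trip[3])
    d23 <- hamming_distance(trip[2], trip[3])
    expect_identical(d12, d21)
    expect_identical(hamming_distance(trip[1], trip[1]), 0L)
    expect_true((d12 == 0) == (trip[1] == trip[2]))
    expect_lte(d13, d12 + d23)
  }
})

test_that("repeat rule flags homopolymer runs and matches a scan oracle", {
  expect_true(violates_repeat_rule("AAAT", 3))
  expect_false(violates_repeat_rule("ATATAT", 3))
  expect_error(violates_repeat_rule("", 3), "empty")
  scan_oracle <- function(s, run) {
    v <- strsplit(s, "")[[1]]
    any(vapply(seq_len(length(v) - run + 1),
               function(i) length(unique(v[i:(i + run - 1)])) == 1,
               logical(1)))
  }
  set.seed(11)
  for (rep in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
    expect_identical(violates_repeat_rule(s, 3), scan_oracle(s, 3))
  }
  # the alternative tandem-motif reading is a separate, optional rule
  expect_true(violates_motif_rule("ACGACGTTAC"))
  expect_false(violates_motif_rule("ACGTTGCATC"))
})

test_that("validate_index_set reports every violation without raising", {
  expect_error(index_set(c("ACGT", "ACGT")), "unique")
  v <- validate_index_set(index_set("GAGA"),
                          design_rules(min_pairwise_hamming = 1,
                                       gc_min = 0, gc_max = 1,
                                       require_rc_distinct = FALSE))
  expect_true(v$pass)
  v2 <- validate_index_set(index_set("GGGA"),
                           design_rules(min_pairwise_hamming = 1,
                                        gc_min = 0, gc_max = 1,
                                        require_rc_distinct = FALSE))
  expect_false(v2$per_index$repeat_ok[1])
  expect_false(v2$pass)
  # palindromic index collides with its own reverse complement
  v3 <- validate_index_set(index_set("ACGT"),
                           design_rules(min_pairwise_hamming = 1,
                                        gc_min = 0, gc_max = 1))
  expect_false(v3$per_index$rc_ok[1])
})

test_that("reported min distance equals the exhaustive pairwise minimum", {
  set.seed(7)
  for (rep in 1:5) {
    seqs <- unique(replicate(8, paste(sample(c("A", "C", "G", "T"), 6,
                                             TRUE), collapse = "")))
    set <- index_set(seqs)
    v <- validate_index_set(set, design_rules(min_pairwise_hamming = 1,
                                              gc_min = 0, gc_max = 1,
                                              require_rc_distinct = FALSE))
    brute <- min(outer(seq_along(seqs), seq_along(seqs),
                       Vectorize(function(i, j)
                         if (i == j) Inf else
                           oracle_hamming(seqs[i], seqs[j]))))
    expect_identical(v$min_distance, as.integer(brute))
  }
})

test_that("generate_index_set yields validated, seed-reproducible sets", {
  rules <- design_rules(min_pairwise_hamming = 4)
  s1 <- generate_index_set(8, 10, rules, seed = 123)
  s2 <- generate_index_set(8, 10, rules, seed = 123)
  expect_identical(s1$sequence, s2$sequence)
  v <- validate_index_set(s1, rules)
  expect_true(v$pass)
  expect_gte(v$min_distance, 4L)
  expect_error(generate_index_set(300, 2,
                                  design_rules(min_pairwise_hamming = 1,
                                               gc_min = 0, gc_max = 1,
                                               require_rc_distinct = FALSE),
                                  seed = 1, max_attempts = 2000),
               "no set found")
})

test_that("decode_capacity matches exhaustive two-index radius overlap", {
  s <- fix_set()
  v <- validate_index_set(s)
  expect_identical(decode_capacity(s, 1L), v$min_distance >= 3L)
  expect_false(decode_capacity(index_set(c("AACC", "AACT", "GGTT")), 1L))
  # exhaustive at length 4: capacity true iff no string is within radius
  # of two distinct indexes
  set4 <- index_set(c("AAAA", "CCCC", "GGGG", "TTTT"))
  for (mm in 0:1) {
    overlap <- any(vapply(all_kmers(4), function(o) {
      d <- vapply(set4$sequence, function(s) oracle_hamming(o, s),
                  numeric(1))
      sum(d <= mm) >= 2
    }, logical(1)))
    expect_identical(decode_capacity(set4, mm), !overlap)
  }
})

test_that("index sets round-trip through TSV and FASTA", {
  s <- fix_set()
  tsv <- tempfile(fileext = ".tsv")
  write_index_set(s, tsv)
  r <- read_index_set(tsv)
  expect_identical(r$sequence, s$sequence)
  expect_identical(r$index_id, s$index_id)
  fa <- tempfile(fileext = ".fa")
  writeLines(paste0(">", s$index_id, "\n", s$sequence), fa)
  r2 <- read_index_set(fa)
  expect_identical(r2$sequence, s$sequence)
})
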