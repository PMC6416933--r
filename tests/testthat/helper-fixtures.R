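# Shared fixtures, all built in code at test time.

# fixed 8-index, 10 bp set with min pairwise distance >= 4
fix_set <- function() generate_index_set(8, 10, design_rules(), seed = 42)

# small 6 bp set for exhaustive demux checks (relaxed GC to ease search)
fix_set6 <- function(n = 4, min_dist = 3, seed = 5)
  generate_index_set(n, 6, design_rules(min_pairwise_hamming = min_dist,
                                        gc_min = 0.2, gc_max = 0.8),
                     seed = seed)

fix_panel <- function(n = 8, len = 200, seed = 9) make_panel(n, len, seed)

# standard run: 8 experimental samples, one per panel target
fix_config <- function(n_reads = 10000, seed = 1, ...) {
  set <- fix_set()
  panel <- fix_panel()
  sheet <- default_sample_sheet(set, panel)
  list(set = set, panel = panel, sheet = sheet,
       config = run_config(n_reads, panel, sheet, seed = seed, ...))
}

# all mechanisms and errors off
fix_null_config <- function(n_reads = 5000, seed = 1, ...)
  fix_config(n_reads = n_reads, seed = seed, p_hop = 0,
             p_template_switch = 0, p_bleed = 0, seq_error = 0, ...)

# independent per-position hamming oracle
oracle_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  sum(mapply(function(x, y) x != y, av, bv))
}

# independent nearest-neighbor-with-ties demux oracle
oracle_match <- function(obs, set, max_mismatch) {
  d <- vapply(set$sequence, function(s) oracle_hamming(obs, s), numeric(1))
  within <- which(d <= max_mismatch)
  if (!length(within)) return("unassigned")
  best <- min(d[within])
  hits <- which(d == best)
  if (length(hits) > 1) "ambiguous" else set$index_id[hits]
}

# all DNA strings of a given length (for exhaustive checks, length <= 6)
all_kmers <- function(L) {
  g <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), L))
  apply(g, 1, paste, collapse = "")
}

binom_3sigma <- function(n, p) 3 * sqrt(p * (1 - p) / n)
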