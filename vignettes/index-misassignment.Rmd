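---
title: "Models and conventions behind indexleak"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind indexleak}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indexleak)
```

`indexleak` measures how often reads in a multiplexed sequencing run are
attributed to the wrong sample, and simulates the mechanisms that cause
it. This vignette is the package's own account of the underlying models,
the defaults and why they were chosen, and the conventions that decide
what a printed rate means.

## The mis-assignment model

A multiplexed pool contains indexed libraries described by a sample
sheet: experimental samples (one amplicon target each), empty or water
controls (indexed adapters in the pool, no template, weight 0),
and balancing libraries (real template, but off-panel inserts, pooled
late). The simulator draws each read's sample by weight and then applies
the contamination mechanisms in a fixed causal order:

1. **Oligo synthesis cross-contamination.** The index physically attached
   to a molecule of sample *i* is drawn from row *i* of the
   `oligo_contam` matrix (rows sum to 1). This happens at synthesis, so
   it precedes everything and is unaffected by pooling stage. Off by
   default (`NULL` = identity): synthesis contamination is a property of
   a specific oligo order, not of a platform.
2. **Template switching** (`p_template_switch`, default 0.02 per read)
   replaces the index with a uniformly drawn *other* pooled index. It is
   active only when pooling happens at the ligation stage, where excess
   free adapters from all samples coexist with templates in the same PCR;
   a single bead purification leaves roughly twice the free-adapter
   carry-over of two rounds, modeled as a 2× factor for
   `ligation_1bead` over `ligation_2bead`. The 2× is a free parameter:
   it fixes the *ordering* of the pooling scenarios, not any published
   magnitude, which mechanism-level data do not pin down.
3. **Free-oligo index hopping** (`p_hop`, default 0.002). Active while
   free indexed oligos can reach foreign templates — pooling at
   ligation or after PCR. After single-strand circularisation the pools
   are exonuclease-digested, which removes free oligos; pools formed at
   `post_sscir`/`post_dnb` are therefore not exposed, and the simulator
   disables `p_hop` for them. In `linear_rcr` amplification the hop is a
   direct, non-accumulating per-read event: every copy of a spot is made
   independently from the original circular template, so one bad copy
   stays one bad copy. In `exponential` mode every existing copy is
   duplicated each cycle, each duplication hops with probability
   `p_hop`, and a wrong copy's descendants stay wrong.
4. **Spot-array signal bleeding** (`p_bleed`, default 0.003). Reads are
   shuffled onto the first `n` cells of a rectangular grid (so neighbors
   are random with respect to sample); with probability `p_bleed` a
   spot's index read is overwritten by a uniformly chosen occupied
   von-Neumann neighbor's index, with index-read qualities drawn from a
   degraded model (below). This reproduces the two diagnostic
   signatures of bleeding: mis-assigned reads share an index with a
   neighbor far more often than index frequency alone explains, and
   their index-region Q30 fraction collapses.
5. **Sequencing error** is applied last, to insert and index reads
   alike.

Each read's truth-table tag is the *last* identity-setting event
(`bleed` over `hop` over `template_switch` over `oligo_contam`), with
`seq_error_only` for reads whose only index-read corruption is a base
error and `clean` otherwise. Tags partition the reads, so tag counts can
be tested against the configured probabilities.

### Exponential amplification

The exponential mode is a branching process: with per-duplication hop
probability $h$ over $c$ cycles, the expected wrong-copy fraction is

$$E[f_c] = 1 - (1 - h/2)^c \approx ch/2 \quad (h \text{ small}),$$

versus a constant $h$ for linear amplification — the rationale for
rolling-circle arrays being robust to index hopping. The implementation
is the exact count recursion `wrong' = 2·wrong + Binom(right, h)`
vectorised over spots; it has the same distribution as simulating the
full binary tree at any cycle count (capped at 20 cycles, i.e. 2²⁰
copies). The spot's reported index is the majority species; **ties break
toward wrong** (conservative: a 50/50 spot is not trusted). This
matters: a first-cycle hop yields exactly half wrong forever, so the
tie rule is what lets single early hops surface as miscalls.

The package's amplification-contrast demonstration runs $h = 0.1$,
$c = 10$, where the exponential majority-miscall rate (~20%) towers over
the linear rate (~10%) at 10⁵ spots. At realistic small $h$ the
*majority-call* contrast shrinks toward $h^2$ and is not resolvable at
desk scale — the accumulation claim is about wrong-copy *fractions*, and
the demonstration uses an exaggerated $h$ to make the spot-level effect
visible. This is a directional property, not a calibrated rate.

### Quality model and quality-linked errors

Qualities are two-component per base: `q_low` (default 12) with
probability `p_lowq_base` (default 0.05), else `q_high` (default 37).
Bled spots use a low-quality mix (`p_lowq_bleed = 0.8`, mean ≈ Q17) for
the index read — their true signal was never detected, which is exactly
why a Q30 filter removes them. The per-base substitution probability is
`seq_error · 10^(−Q/10)` normalised by the quality model's mean error,
so errors concentrate at low-quality bases while the marginal per-base
error rate equals `seq_error` (default 0.001) — and `seq_error = 0`
yields *exactly* zero errors, which the null-configuration invariant
(all mechanisms off ⇒ every rate identically 0) requires.

## Demultiplexing and filtering conventions

- Matching is nearest-index by hamming distance within `max_mismatch`
  (0 or 1 in normal use); two indexes tied at the minimal distance give
  "ambiguous", which is excluded from every downstream denominator. `N`
  bases mismatch all four bases. `decode_capacity()` certifies
  `min_d ≥ 2·mismatch + 1`, under which ambiguity is impossible (and
  verified exhaustively at index length ≤ 6 in the tests).
- The Q30 filter applies **before** matching, on the **index region** by
  default (insert or both are available and reports record the region):
  the filter exists to catch undetected index signals, and the index
  region is where the bleeding signature lives.
- "Q30 > 60%" is a strict inequality; a read at exactly 0.60 is
  filtered out. A threshold of 0 means "without any filtering" (it does
  not drop reads whose Q30 fraction is exactly zero), matching how
  unfiltered totals are reported.
- Split rates are fractions of *all* input reads, so they sum to ≤ 1.

## Rate conventions

Two report modes fix the denominators, which differ across assay styles
and must never be inferred:

- **wgs**: everything over the total reads of all indexes in the matrix.
  Empty/balancing control rates divide additionally by the number of
  control indexes (the per-index convention).
- **hpv**: the internal-control amplicon (HBB) column is excluded from
  matrix percentages and the total rate; its column total is the
  denominator for per-control **leakage**. The **sample-to-sample
  average** is the mean over improper cells of cell/denominator, with
  empty-control *rows* excluded from the averaged cells (they are not
  samples) though their reads stay in the denominator. Including them is
  a flag (`include_empty_rows`), but note the bundled HPV example then
  averages to 0.0003% rather than 0.0004% — inclusion is not a no-op.

Display never feeds back into computation: `fmt_pct()` renders four
decimals ("0.0002%"), `fmt_sci()` three significant figures
("2.16E-07"), and `one_in_n()` produces the "1 in 36 million" phrasing
(reciprocal in millions, two significant figures half-up at ≥ 10⁷, one
decimal of a million below, plain integers under 10⁵). On the bundled
PCR-free example the total contamination computed from the printed cells
is 0.0117% where the source table displays 0.0118%, and three proper
cells land one display-ulp above their source values (e.g. 14.7310% vs
14.7309%): the printed cells sum to 9,156,404 while the percentages are
consistent only with a slightly larger denominator (an excluded
empty-control row's unprinted reads would account for it). The package
reports what the printed counts imply and leaves the convention
configurable rather than tuning to the display.

`exclude_index()` removes an index's row *and* its proper target
columns, so post-exclusion rates equal recomputation from a reduced
assignment list (tested as an oracle equivalence) — the procedure for
discarding an index whose oligo pool is contaminated, where true and
false reads cannot be separated.

## Barcode design rules

`generate_index_set()` rejection-samples candidates (bounded at 10⁵
attempts, explicit "no set found" failure) against: minimum pairwise
hamming distance (default 4, supporting 1-mismatch demultiplexing with
margin), GC in [0.4, 0.6] (a balanced default; no published window
exists), no homopolymer run ≥ 3, and reverse-complement distinctness
against the whole set including self (palindromes fail). The "no 3-base
tandem repeat" rule is ambiguous between *homopolymer run* (AAA) and
*repeated motif* (ACGACG); the homopolymer reading is the default —
homopolymers are the dominant synthesis/sequencing failure mode — and
the motif reading is available as `forbid_tandem_motif`, off by
default. Neither is asserted as the original intent.

## UID deduplication and calling

Reads group by (UID, target); the template consensus is the strict
majority of ref/mut observations, with ties and "other"-majorities
dropped. The rule is deliberately conservative — no published consensus
rule exists, and tie-dropping is what makes isolated PCR/sequencing
errors vanish after deduplication. Calls are positive iff allele rate
≥ 0.5% *and* mutant templates ≥ 3; the thresholds sit between observed
contamination-level rates (≤ 0.05%) and the 1% sensitivity a spike-in
series must retain, and both are configurable package choices. Indels
are represented as a substitution marker at the panel position; true
indel calling is out of scope. The 0–10 genotype score in
`call_panel_genotypes()` is a saturating read-count convention of this
package; no published formula exists for it.

## What the simulator does and does not emulate

It emulates: single-indexed amplicon pools with empty/water/balancing
roles, pooling-stage-dependent mechanism exposure, linear vs exponential
amplification, rectangular-array neighbor bleeding, Phred+33 quality
strings with quality-linked errors, and UID-tagged duplicate reads with
spiked mutant fractions. It does not emulate: sequence-dependent error
spectra, PCR chimera breakpoints, optical duplicates, flow-cell tile
structure, off-target genomic copies of panel genes (a known source of
residual false positives for multi-copy loci), or indel chemistry.
Passing tests therefore demonstrate internal consistency of the
mechanisms and statistics — not that any particular real platform has a
particular rate. Published per-scenario magnitudes that depend on
unavailable read-level data are reproduced *directionally* (orderings,
contrasts), while all printed count arithmetic is reproduced exactly
from the bundled tables.

## Problem sizes and determinism

The test-suite and acceptance runs use 10⁶ reads for hop-rate recovery
(3σ binomial checks at injected rates 10⁻⁴–10⁻²), 1.5×10⁵ reads per
pooling scenario, 10⁵ spots for the amplification and bleeding
demonstrations, and 5×10³ molecules per spike-in fraction — sizes at
which every directional property is many standard errors wide while a
full run stays around a minute. All randomness flows from a single seed;
identical configurations produce byte-identical FASTQ and reports
(checksummed in the pipeline manifest).
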