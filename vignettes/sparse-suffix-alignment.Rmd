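---
title: "Sparse suffix array alignment: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse suffix array alignment: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psira)
```

## The model

`psira` indexes a DNA reference with a sparse suffix array and aligns short
reads against it, exactly or with up to *k* substitutions.

Let *G* = *g*₀…*g*ₙ₋₁`$` be the reference with an end sentinel that sorts
before every base. The suffix array lists the start positions of all suffixes
in lexicographic order; the **sparse** suffix array (SSA) keeps only suffixes
starting at positions divisible by the sparsification factor *D*, stored as
position/*D*. The index is therefore `ceiling(n/D)` 32-bit entries plus the
2-bit packed sequence, a *D*-fold space saving over the full array.

A query of length *m* ≥ *D* occurring at start *s* has *s* + *i* divisible by
*D* for exactly one offset *i* in 0..*D*−1. So exact search runs *D*
sub-searches: for each *i*, the tail *P*[*i*:] is binary-searched over the
SSA and the head *P*[:*i*] is compared directly against the genome just
before each tail hit. Soundness and completeness therefore do not depend on
*D*; only the work does (verified by oracle equivalence across
*D* ∈ {1, 2, 4, 8} in the test suite).

For approximate alignment, write the *m*-bit number *B* with 0-bits exactly
at mismatching read positions. Among all placements within the mismatch
budget, those with higher *B* — mismatches further towards the 3' end, where
sequencing errors concentrate — rank first. The search returns **all**
placements with at most *k* substitutions, each with its exact mismatch set,
sorted by decreasing *B* and tie-broken by ascending genomic start.

## Tunable parameters

* **`D` (sparsification factor, default 4).** Unitless sampling period.
  Index size scales as 1/*D*; query work scales as *D*. Any integer ≥ 1 is
  accepted (`D = 1` degenerates to a plain suffix array). Choose
  *D* ≤ minimum read length; `exact_align()` rejects shorter patterns
  outright rather than implementing the meta-character machinery that
  sub-*D* patterns would need.
* **`K` (partition prefix length, default 8).** The table has 4^K rows, each
  a half-open SSA row interval for one K-mer; a query with
  `nchar(q) >= K` narrows to its K-mer interval before binary search,
  replacing log(n/D) with log(n/(D·4^K)) comparisons at 8·4^K bytes of
  table. K = 8 (65536 rows, 512 KiB) suits genome-scale references; tests
  use K ∈ {1, 2, 4} so brute-force enumeration stays easy. A guard rejects
  K > 12.
* **`k` (mismatch budget, default 0).** "k-mismatch" means *at most* k; the
  exact count travels with every hit, so callers can filter to exactly-k.
* **`max_hits`** truncates *after* rightmost sorting, so a cap always keeps
  the highest-B alignments.

## Candidate generation: why alterations move rightward

Level-wise generation produces (j)-mismatch candidates from (j−1)-mismatch
ones. When a candidate's exact search fails, the binary-search insertion
point's two neighbouring rows yield *L*, the longest prefix of the candidate
occurring among indexed suffixes: altering any position > *L* is pointless
because the prefix that would have to precede it does not occur. That prune
is the engine of the whole search — for the worked 16-base pattern with
*L* = 10, the last five read positions are never touched.

A subtle point is the *direction* in which successive alterations may move.
Requiring each new alteration to sit strictly **left** of the previous one
looks natural (it emits candidates in rightmost-priority order) but is
incomplete: consider a true alignment whose mismatches sit at read positions
{3, 10} while the unaltered pattern's failure prefix is L = 3. Altering
position 10 first is forbidden (10 > L, and correctly so — the altered
pattern cannot occur anywhere), and after altering position 3 a leftward rule
can never reach 10. `psira` instead generates each new alteration strictly
**right** of the previous one. This is provably complete: the leftmost
mismatch p of a true alignment always satisfies p ≤ L (the pattern matches
the genome window up to p, and with offset i = (−s) mod D the sampled suffix
at s+i realises at least that much prefix), and correcting it extends the
matching prefix past the next mismatch, so induction carries to level k. It
also generates every mismatch set exactly once — no deduplication structure
is needed — and output order is restored by a final sort on (B, start),
which the ordering tests verify bit-for-bit via recomputed B values.

In the sparse setting the failure prefix is assembled per offset as
*i* + (tail neighbour LCP), maximised over offsets, and set to *m* outright
whenever any offset's tail range is non-empty (head verification failures
are not subtracted). These are deliberate overestimates: an overestimated
*L'* only admits extra candidates, each of which is searched exactly and
filtered by the genome itself, so correctness is untouched; the oracle
equivalence suite covers the prune wherever it binds.

Each candidate records the altered pattern, the altered positions and a
head-length offset. Because the offset loop lives inside the exact search,
every candidate is searched at all *D* head lengths and the recorded
`head_offset` is informational (0 by convention).

## Numerical and representational choices

* **Coordinates** are 0-based, intervals half-open, everywhere inside the
  package; SAM output converts to 1-based. Suffix ranges are half-open
  `[sp, ep)` with emptiness as `sp == ep` (the inclusive convention would
  need an `ep = sp − 1` sentinel).
* **Sentinel.** One logical sentinel terminates the whole concatenation of
  FASTA records; it is never stored. Comparisons treat "past the end" as
  smaller than any base, which is exactly the behaviour of rank −1 in the
  prefix-doubling sorter and of the bounds check in the binary search.
  Alignments whose window would cross a record boundary are discarded at
  verification time.
* **Non-ACGT reference characters** become code 0 ('A') with their global
  positions recorded; any hit overlapping such a position carries
  `n_flag = TRUE`. This keeps the 2-bit packing exact while preserving
  auditability. Reads containing non-ACGT bases are reported unaligned by
  default (`n_policy = "reject"`); `"substitute"` maps them to 'A'.
* **Short sampled suffixes** (fewer than K bases before the sentinel) have
  no K-mer and belong to no partition-table interval. They always fall at
  interval boundaries — a short suffix precedes every suffix extending its
  prefix — so intervals stay contiguous, and such rows remain reachable via
  the table-free binary search path. Empty K-mer rows store the zero-width
  interval at the next occupied block's start.
* **Suffix sorting** is prefix doubling (O(n log² n)), adequate far beyond
  the tested scales; the contract deliberately permits any correct sorter,
  and every constructed index at n ≤ 2000 is checked against a brute-force
  string sort.
* **Determinism.** Index bytes are a pure function of the input; alignment
  output is byte-identical for any thread count because reads are
  partitioned into contiguous chunks and reassembled in input order.
  32-bit fields cap genomes at 2^31 − 1 bases.
* **B values.** Ordering uses an exact positional comparator; the numeric
  `mask_b()` helper is exact only for m ≤ 53 and exists for tests and
  diagnostics.

## What the synthetic data does and does not establish

`generate_genome()` draws i.i.d. uniform ACGT bases; `sample_reads()` draws
uniform start positions and substitutes each position with probability given
by an error profile that rises linearly along the read (default 0 → 0.3, the
monotone "errors accumulate towards the 3' end" shape), always to a
*different* base, so the injected mask is exactly the read's Hamming
mismatch set — ground truth is exact by construction. The recovery criterion
caps injection at 2 errors per read (rejection-resampling of the mask) to
state its world precisely.

A green suite establishes: exact equivalence with brute-force scans over
thousands of random instances for all tested D, complete and correctly
ordered ≤k-mismatch enumeration, byte-stable serialization and parallel
output, and 100% truth recovery on capped-error reads. It does **not**
establish performance on repeat-rich real genomes (uniform random sequence
has far milder repeat structure), behaviour with indels or clipped reads
(out of scope by design), or anything about quality values (carried through,
never used).

## Known limitations

* Substitutions only; an indel shifts every downstream base and will exhaust
  the mismatch budget rather than align.
* Reverse-strand search is an opt-in flag that simply queries the reverse
  complement; there is no reverse-complement-aware index.
* All-hits reporting: a read occurring in a high-copy repeat yields all its
  placements (cap with `max_hits`); there is no mapping-quality model.
* The k-mismatch candidate tree grows roughly as (3L)^k in the worst case;
  k ≤ 3 on short reads is the intended regime.
* Patterns shorter than D are rejected, reads shorter than D are reported
  unaligned with a reason.
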