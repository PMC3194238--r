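# psira

Sparse suffix array indexing and rightmost k-mismatch alignment of short DNA
sequencing reads, as an R library and a two-command CLI.

## The problem

Short-read alignment maps millions of 25–100 bp reads onto a reference genome.
Full-text indexes make this fast, but a plain suffix array of an *n*-base
genome stores *n* 32-bit positions — prohibitive for mammalian genomes. A
**sparse suffix array (SSA)** keeps only the suffixes starting at positions
divisible by a sparsification factor *D*, stored as position/*D*: the index
shrinks by a factor of *D* and the lost positions are recovered at query time.
Because reads have a guaranteed minimum length, choosing *D* below that length
avoids the awkward short-pattern machinery entirely. The memory/time trade-off
is tunable: larger *D* means a smaller index and *D*-fold more search work,
which parallelises naturally (the per-offset searches are independent).

Sequencing errors are not uniform along a read — they concentrate towards the
3' end. `psira` therefore reports approximate alignments under the
**rightmost-mismatch criteria**, preferring placements whose mismatches sit as
far right as possible.

## The method

For a genome *G* of length *n* (2-bit packed; multi-record FASTA is
concatenated with an implicit end sentinel `$` that sorts before every base):

* **Index.** Sort the suffixes starting at positions *p* with *p* mod *D* = 0
  and store *p*/*D* in SSA order (`ceiling(n/D)` 32-bit entries). A partition
  table with 4^K rows (default *K* = 8, 65536 rows) maps each K-mer to its
  half-open SSA row interval, shrinking binary search from log(n/D) to
  log(n/(D·4^K)).
* **Exact search.** For each offset *i* in 0..*D*−1, split the pattern
  *P* = head(*i* bases) + tail; binary-search the tail over the SSA, then
  verify the head directly against the genome immediately before each hit.
  Each occurrence at start *s* is found by exactly one offset,
  *i* = (−*s*) mod *D*; the union over offsets is every occurrence.
* **k-mismatch search.** Align *P* at a window and write the *m*-bit number
  *B* = *b*₀*b*₁…*b*ₘ₋₁ with *b*ⱼ = 1 iff the bases agree; the rightmost
  k-mismatch alignments are those with the highest *B*. When an exact search
  fails, the insertion point's neighbours give *L*, the longest matching
  prefix of *P* among indexed suffixes: no prefix of length > *L* occurs, so
  only positions ≤ *L* are worth altering. Candidates are generated level by
  level (1-mismatch patterns from the original, 2-mismatch from the
  1-mismatch ones, …), each new alteration strictly right of the previous one
  and bounded by the parent's failure prefix; every altered pattern is
  searched exactly. Output is every alignment within *k* substitutions,
  sorted by decreasing *B*, each with its exact mismatch set.

## Worked example

The 16-base reference `AGGTCGATTCGGGACC`. Its smallest suffix starts at
position 13, and sparsifying the suffix array with *D* = 4 keeps the sampled
suffixes at 0, 4, 8, 12 in order A… < C… < G… < T…, giving SSA = {0, 1, 3, 2}:

```r
library(psira)
g   <- encode_reference(c(chr_demo = "AGGTCGATTCGGGACC"))
idx <- build_index(g, D = 4, K = 1)
idx
#> SparseIndex: n=16, D=4, |ssa|=4, K=1 (table occupancy 100.0%)
idx$ssa
#> [1] 0 1 3 2
build_suffix_array(g)$entries[1]
#> [1] 13

k_mismatch_align(idx, "GGTCGATTCGGGACG", k = 1)
#>     record start gstart length n_mismatch mismatches n_flag
#> 1 chr_demo     1      1     15          1         14  FALSE
```

The read differing from the genome only at its last base aligns at 0-based
start 1 with the single mismatch at read position 14 — a rightmost (3'-most)
error, exactly where the criteria rank it best. The same run through the CLI:

```sh
$ psira index --ref ref.fa --sparse 4 --kmer 1 --out demo.psira
indexed 16 bases: |ssa|=4 (D=4), table K=1 occupancy 100.0%
$ psira align --index demo.psira --reads reads.fq --mismatches 1 --format sam --out out.sam
$ cat out.sam
@HD	VN:1.6	SO:unknown
@SQ	SN:chr_demo	LN:16
@PG	ID:psira	PN:psira
r1	0	chr_demo	2	255	15M	*	0	0	GGTCGATTCGGGACC	IIIIIIIIIIIIIII	NM:i:0
r2	0	chr_demo	2	255	15M	*	0	0	GGTCGATTCGGGACG	IIIIIIIIIIIIIII	NM:i:1	XB:Z:14
```

(`exec/psira` is an Rscript shim; `Rscript exec/psira …` works uninstalled.)
SAM positions are 1-based, `NM:i` is the mismatch count and the custom `XB:Z`
tag lists the 0-based mismatch read coordinates. Unaligned reads are always
emitted with FLAG 4. Output is byte-identical for any `--threads` value.

## Scope

Forward-strand, substitution-only alignment is the core (an opt-in
`--both-strands` flag also queries the reverse complement). No indels, no
quality-aware scoring, no paired-end logic, no BAM output; genomes must stay
below 2^31 bases. See `vignettes/sparse-suffix-alignment.Rmd` for the design
rationale, parameter guidance and known limitations.
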