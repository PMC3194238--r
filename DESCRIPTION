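Package: psira
Title: Sparse Suffix Array Indexing and Rightmost k-Mismatch Read Alignment
Version: 1.0.0
Authors@R: person("psira", "developers", email = "psira-dev@example.org",
    role = c("aut", "cre"))
Description: Index a DNA reference genome with a sparse suffix array (SSA):
    only suffixes starting at positions divisible by a sparsification factor D
    are sorted, stored as position/D, together with a 4^K-row partition table
    over the first K bases that narrows every lookup to one K-mer interval.
    Exact read alignment decomposes each query, for every offset i < D, into a
    head of length i verified directly against the 2-bit packed reference and
    a tail searched on the SSA. Approximate alignment reports all alignments
    within k substitutions, generated level by level from the failure prefix
    of each exact search and ordered by the rightmost-mismatch criteria, which
    prioritise alignments whose errors lie towards the 3' end of the read
    where sequencing errors concentrate. Includes a FASTA/FASTQ front end,
    SAM and TSV writers, a two-command command-line interface, a serialized
    binary index format, and deterministic synthetic-data generators with
    brute-force oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    withr
Config/testthat/edition: 3
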