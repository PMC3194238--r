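# Deterministic synthetic data and brute-force oracles. The oracles implement
# the definitions directly (string sorts and O(nm) scans) and are kept free of
# any code shared with the production search paths.

#' Linear position-dependent substitution profile
#'
#' Sequencing errors concentrate towards the 3' end of a read; the default
#' profile rises linearly from `p_start` at the first base to `p_end` at the
#' last.
#'
#' @param p_start,p_end substitution probabilities at read positions 0 and
#'   m - 1; must satisfy `0 <= p_start <= p_end <= 1` (non-decreasing).
#' @return a function of a read length returning the per-position probability
#'   vector.
#' @export
error_profile_linear <- function(p_start = 0, p_end = 0.3) {
  stopifnot(p_start >= 0, p_end <= 1, p_start <= p_end)
  function(len) {
    if (len == 1L) return(p_end)
    p_start + (p_end - p_start) * (seq_len(len) - 1L) / (len - 1L)
  }
}

#' Generate a uniform random genome
#'
#' @param n base count.
#' @param seed RNG seed; the output is a pure function of `(n, seed)`.
#' @param name record name.
#' @return a single-record `PackedGenome`.
#' @export
generate_genome <- function(n, seed = NULL, name = "synthetic_1") {
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  s <- paste(sample(.BASES, n, replace = TRUE), collapse = "")
  encode_reference(stats::setNames(s, name))
}

#' Sample reads from a genome with injected substitutions
#'
#' Read starts are uniform; each position is substituted to a uniformly chosen
#' *different* base with the profile's probability, so the injected mask is
#' exactly the Hamming mismatch set of the read against its origin. With
#' `max_mismatches` finite, a read's error mask is re-drawn until it has at
#' most that many positions (the profile shape conditional on the cap is
#' preserved).
#'
#' @param g a `PackedGenome`.
#' @param count number of reads.
#' @param length read length (<= genome length).
#' @param profile a profile function as from [error_profile_linear()].
#' @param seed RNG seed.
#' @param max_mismatches cap on injected errors per read (default unlimited).
#' @return a data.frame with `id`, `seq`, `qual` (constant 'I'), truth `start`
#'   (0-based global) and `mask` (list column of injected positions).
#' @export
sample_reads <- function(g, count, length, profile = error_profile_linear(),
                         seed = NULL, max_mismatches = Inf) {
  stopifnot(inherits(g, "PackedGenome"))
  if (length > g$n) stop("read length exceeds genome length", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  text <- decode_genome(g)
  pvec <- profile(length)
  stopifnot(all(pvec >= 0), all(pvec <= 1), !is.unsorted(pvec))
  starts <- sample.int(g$n - length + 1L, count, replace = TRUE) - 1L
  seqs <- character(count)
  masks <- vector("list", count)
  qual <- strrep("I", length)
  for (i in seq_len(count)) {
    repeat {
      pos <- which(runif(length) < pvec) - 1L
      if (length(pos) <= max_mismatches) break
    }
    s <- substr(text, starts[i] + 1L, starts[i] + length)
    for (p in pos) {
      orig <- substr(s, p + 1L, p + 1L)
      substr(s, p + 1L, p + 1L) <- sample(.BASES[.BASES != orig], 1L)
    }
    seqs[i] <- s
    masks[[i]] <- pos
  }
  data.frame(id = sprintf("read_%06d", seq_len(count)), seq = seqs,
             qual = rep.int(qual, count), start = starts, mask = I(masks),
             stringsAsFactors = FALSE)
}

#' Write reads and their ground truth to disk
#'
#' Emits `<prefix>.fastq` (or `.fasta`), `<prefix>_truth.tsv` with columns
#' read_id, start, mask, and optionally `<prefix>_ref.fasta`.
#'
#' @param reads a data.frame from [sample_reads()].
#' @param dir output directory.
#' @param prefix file name prefix.
#' @param format `"fastq"` or `"fasta"`.
#' @param genome optional `PackedGenome` to write alongside.
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture_files <- function(reads, dir, prefix = "synthetic",
                                format = c("fastq", "fasta"), genome = NULL) {
  format <- match.arg(format)
  reads_path <- file.path(dir, paste0(prefix, ".", format))
  x <- Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$id))
  if (format == "fastq") {
    Biostrings::writeXStringSet(x, reads_path, format = "fastq",
                                qualities = Biostrings::BStringSet(reads$qual))
  } else {
    Biostrings::writeXStringSet(x, reads_path)
  }
  truth_path <- file.path(dir, paste0(prefix, "_truth.tsv"))
  truth <- data.frame(read_id = reads$id, start = reads$start,
                      mask = vapply(reads$mask, paste, "", collapse = ","),
                      stringsAsFactors = FALSE)
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out <- c(reads = reads_path, truth = truth_path)
  if (!is.null(genome)) {
    ref_path <- file.path(dir, paste0(prefix, "_ref.fasta"))
    gx <- Biostrings::DNAStringSet(
      stats::setNames(decode_genome(genome), genome$records$name[1L]))
    Biostrings::writeXStringSet(gx, ref_path)
    out <- c(out, ref = ref_path)
  }
  invisible(out)
}

.oracle_text <- function(x) {
  if (inherits(x, "PackedGenome")) decode_genome(x) else x
}

#' Brute-force suffix sort oracle
#'
#' Materialises every suffix string and sorts them bytewise; the shorter
#' string sorting before its extensions realises the sentinel rule. Intended
#' for small instances only.
#'
#' @param x a nucleotide string or `PackedGenome`.
#' @return 0-based suffix start positions in lexicographic order.
#' @export
oracle_suffix_sort <- function(x) {
  s <- .oracle_text(x)
  n <- nchar(s)
  suf <- substring(s, seq_len(n), n)
  order(suf, method = "radix") - 1L
}

#' Brute-force sparse suffix sort oracle
#'
#' Sorts only the suffixes starting at multiples of `D` and divides the
#' starts by `D`.
#'
#' @param x a nucleotide string or `PackedGenome`.
#' @param D sparsification factor.
#' @return integer sparse entries.
#' @export
oracle_sparse_sort <- function(x, D) {
  s <- .oracle_text(x)
  n <- nchar(s)
  D <- as.integer(D)
  pos <- seq.int(0L, n - 1L, by = D)
  suf <- substring(s, pos + 1L, n)
  pos[order(suf, method = "radix")] %/% D
}

#' Naive exact-occurrence scan oracle
#'
#' @param x a nucleotide string or `PackedGenome`.
#' @param pattern pattern string.
#' @return sorted 0-based start positions of every exact occurrence.
#' @export
oracle_naive_scan <- function(x, pattern) {
  s <- .oracle_text(x)
  n <- nchar(s)
  m <- nchar(pattern)
  if (m > n) return(integer(0L))
  gi <- utf8ToInt(s)
  pi <- utf8ToInt(pattern)
  ns <- n - m + 1L
  mism <- integer(ns)
  for (j in seq_len(m)) mism <- mism + (gi[j:(j + ns - 1L)] != pi[j])
  which(mism == 0L) - 1L
}

#' Brute-force Hamming scan oracle
#'
#' Scores the pattern at every start and returns all placements with at most
#' `k` mismatches together with their exact mismatch sets.
#'
#' @param x a nucleotide string or `PackedGenome`.
#' @param pattern pattern string.
#' @param k mismatch budget.
#' @return list with `starts` (integer) and `masks` (list of ascending
#'   0-based read coordinates), ordered by ascending start.
#' @export
oracle_hamming_scan <- function(x, pattern, k) {
  s <- .oracle_text(x)
  n <- nchar(s)
  m <- nchar(pattern)
  if (m > n) return(list(starts = integer(0L), masks = list()))
  gi <- utf8ToInt(s)
  pi <- utf8ToInt(pattern)
  ns <- n - m + 1L
  mism <- integer(ns)
  for (j in seq_len(m)) mism <- mism + (gi[j:(j + ns - 1L)] != pi[j])
  starts <- which(mism <= k) - 1L
  masks <- lapply(starts, function(st) {
    which(gi[(st + 1L):(st + m)] != pi) - 1L
  })
  list(starts = starts, masks = masks)
}
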