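# Library-level alignment driver with data-level parallelism.

.unaligned <- function(id, seq, qual, reason) {
  list(id = id, seq = seq, qual = qual, status = "unaligned", reason = reason,
       hits = NULL)
}

.align_one <- function(idx, id, seq, qual, k, both_strands, n_policy,
                       max_hits) {
  m <- nchar(seq)
  seq <- toupper(seq)
  if (m < idx$D) {
    return(.unaligned(id, seq, qual, "read shorter than sparsification factor"))
  }
  if (grepl("[^ACGT]", seq)) {
    if (n_policy == "reject") {
      return(.unaligned(id, seq, qual, "non-ACGT base in read"))
    }
    seq <- codes_to_dna(dna_to_codes(seq, substitute_non_acgt = TRUE))
  }
  hits <- k_mismatch_align(idx, seq, k)
  hits$strand <- rep("+", nrow(hits))
  if (both_strands) {
    h2 <- k_mismatch_align(idx, revcomp_dna(seq), k)
    h2$strand <- rep("-", nrow(h2))
    if (nrow(h2)) {
      h2$mismatches <- I(lapply(h2$mismatches, function(p) sort(m - 1L - p)))
    }
    hits <- .sort_hits(rbind(hits, h2), m)
  }
  if (is.finite(max_hits) && nrow(hits) > max_hits) {
    hits <- hits[seq_len(max_hits), , drop = FALSE]
  }
  if (nrow(hits) == 0L) {
    return(.unaligned(id, seq, qual, "no alignment found"))
  }
  list(id = id, seq = seq, qual = qual, status = "aligned", reason = NA,
       hits = hits)
}

#' Align a set of reads against a sparse index
#'
#' Each read is aligned independently with [k_mismatch_align()]; per-read
#' output keeps all hits (or the `max_hits` best after rightmost sorting).
#' With `threads > 1` the reads are partitioned into contiguous chunks
#' processed by forked workers (data-level parallelism); results are
#' reassembled in input order, so the output is byte-identical to a serial
#' run. Per-query offset-level parallelism is a correctness contract only
#' (the D offset searches are independent) and is not exercised here.
#'
#' @param idx a `SparseIndex`.
#' @param reads a data.frame with `id`, `seq` and optional `qual`, as from
#'   [read_reads()] or [sample_reads()].
#' @param k mismatch budget (`k = 0`: exact).
#' @param threads number of worker processes.
#' @param max_hits keep at most this many hits per read, truncating *after*
#'   rightmost sorting so the highest-B alignments survive.
#' @param both_strands also query the reverse complement; reverse hits carry
#'   strand `"-"` and mismatch positions mapped back to original read
#'   coordinates.
#' @param n_policy `"reject"` (default): reads with non-ACGT bases are
#'   reported unaligned; `"substitute"`: such bases become 'A' before
#'   alignment.
#' @return a list with one element per read: `id`, `seq`, `qual`, `status`,
#'   `reason`, and for aligned reads a `hits` data.frame (columns of
#'   [k_mismatch_align()] plus `strand`).
#' @export
align_reads <- function(idx, reads, k = 0L, threads = 1L, max_hits = Inf,
                        both_strands = FALSE,
                        n_policy = c("reject", "substitute")) {
  stopifnot(inherits(idx, "SparseIndex"), is.data.frame(reads))
  n_policy <- match.arg(n_policy)
  if (is.null(reads$qual)) reads$qual <- NA_character_
  nr <- nrow(reads)
  worker <- function(rows) {
    lapply(rows, function(i) {
      .align_one(idx, reads$id[i], reads$seq[i], reads$qual[i], k,
                 both_strands, n_policy, max_hits)
    })
  }
  threads <- max(1L, as.integer(threads))
  if (threads == 1L || nr < 2L || .Platform$OS.type != "unix") {
    return(worker(seq_len(nr)))
  }
  chunk <- ceiling(nr / threads)
  parts <- split(seq_len(nr), ceiling(seq_len(nr) / chunk))
  res <- parallel::mclapply(parts, worker, mc.cores = threads,
                            mc.preschedule = FALSE)
  err <- vapply(res, inherits, TRUE, "try-error")
  if (any(err)) stop("parallel worker failed: ", res[[which(err)[1L]]])
  unlist(res, recursive = FALSE, use.names = FALSE)
}
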