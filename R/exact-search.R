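# Exact alignment over the SSA: range search, head verification, offset loop.

#' Search a query on the sparse suffix array
#'
#' Returns the maximal half-open range `[sp, ep)` of SSA rows whose suffixes
#' have `q` as a prefix (0-based rows; empty iff `sp == ep`). When
#' `nchar(q) >= K` the search first narrows to the partition-table interval of
#' the first K bases and binary-searches the remainder; shorter queries
#' binary-search the full array. Both paths return identical ranges whenever
#' both apply.
#'
#' @param idx a `SparseIndex`.
#' @param q nucleotide query string (ACGT only).
#' @param use_table set `FALSE` to force the table-free path (used by the
#'   equivalence tests).
#' @return an object of class `SuffixRange` with fields `sp` and `ep`.
#' @export
ssa_range_search <- function(idx, q, use_table = TRUE) {
  stopifnot(inherits(idx, "SparseIndex"), nchar(q) >= 1L)
  qc <- dna_to_codes(q)
  r <- cpp_range_search(idx$genome$codes, idx$ssa, idx$D, idx$K,
                        idx$table$lo, idx$table$hi, qc, isTRUE(use_table))
  structure(list(sp = r[1L], ep = r[2L]), class = "SuffixRange")
}

#' @export
print.SuffixRange <- function(x, ...) {
  cat(sprintf("SuffixRange [%d, %d) (%s)\n", x$sp, x$ep,
              if (x$ep > x$sp) sprintf("%d row(s)", x$ep - x$sp) else "empty"))
  invisible(x)
}

#' Verify a pattern head against the genome before a sampled tail position
#'
#' Given a sampled global position `q` where a tail was found, checks whether
#' the genome carries `head` immediately before it, i.e. at
#' `[q - nchar(head), q)`. When `pattern_length` is supplied, the full window
#' starting at `q - nchar(head)` must also lie inside one reference record.
#'
#' @param idx a `SparseIndex`.
#' @param q global position (D times an SSA entry).
#' @param head head string of length `i`, `0 <= i < D`.
#' @param pattern_length optional full pattern length for the within-record
#'   check.
#' @return the 0-based global alignment start, or `NULL` when verification
#'   fails.
#' @export
verify_head <- function(idx, q, head, pattern_length = NULL) {
  stopifnot(inherits(idx, "SparseIndex"))
  i <- nchar(head)
  s <- q - i
  if (s < 0L) return(NULL)
  if (i > 0L) {
    hc <- dna_to_codes(head)
    if (!identical(idx$genome$codes[(s + 1L):q], hc)) return(NULL)
  }
  if (!is.null(pattern_length)) {
    rec <- findInterval(s, idx$genome$records$start)
    rend <- idx$genome$records$start[rec] + idx$genome$records$length[rec]
    if (s + pattern_length > rend) return(NULL)
  }
  s
}

# shared post-processing: record mapping, boundary discard, N flagging.
# starts are global; masks a list of ascending 0-based read coordinates.
.alignments_df <- function(idx, starts, masks, m) {
  g <- idx$genome
  if (length(starts) == 0L) {
    return(data.frame(record = character(0L), start = integer(0L),
                      gstart = integer(0L), length = integer(0L),
                      n_mismatch = integer(0L),
                      mismatches = I(list()), n_flag = logical(0L),
                      stringsAsFactors = FALSE))
  }
  rec <- findInterval(starts, g$records$start)
  keep <- (starts + m) <= (g$records$start[rec] + g$records$length[rec])
  starts <- starts[keep]
  masks <- masks[keep]
  rec <- rec[keep]
  np <- g$n_positions
  n_flag <- if (length(np) == 0L || length(starts) == 0L) {
    rep(FALSE, length(starts))
  } else {
    findInterval(starts + m - 1L, np) > findInterval(starts - 1L, np)
  }
  data.frame(record = g$records$name[rec],
             start = starts - g$records$start[rec],
             gstart = starts,
             length = rep.int(m, length(starts)),
             n_mismatch = lengths(masks),
             mismatches = I(masks),
             n_flag = n_flag,
             stringsAsFactors = FALSE)
}

.check_pattern <- function(idx, pattern, n_policy) {
  if (nchar(pattern) < idx$D) {
    stop("pattern shorter than sparsification factor", call. = FALSE)
  }
  dna_to_codes(pattern, substitute_non_acgt = identical(n_policy, "substitute"))
}

#' Exact alignment of a pattern
#'
#' For each offset `i` in `0..D-1` the pattern is split into a head (first `i`
#' bases, verified directly against the genome) and a tail (searched on the
#' SSA); the union over offsets is every exact occurrence of the pattern.
#' Each occurrence at start `s` is produced by exactly one offset,
#' `i = (-s) mod D`. Hits whose window would span a record boundary are
#' discarded; hits overlapping a converted non-ACGT reference position carry
#' `n_flag = TRUE`.
#'
#' @param idx a `SparseIndex`.
#' @param pattern read sequence, `nchar(pattern) >= D`.
#' @param n_policy what to do with non-ACGT bases in the pattern: `"reject"`
#'   (default, an error) or `"substitute"` (replace with 'A').
#' @return a data.frame of alignments sorted by ascending start position, with
#'   columns `record`, `start` (0-based within the record), `gstart`,
#'   `length`, `n_mismatch` (always 0 here), `mismatches` (list column) and
#'   `n_flag`.
#' @examples
#' idx <- build_index(encode_reference(c(x = "AGGTCGATTCGGGACC")), D = 4, K = 1)
#' exact_align(idx, "GGTCGATTCGGGACC")$gstart  # 1
#' @export
exact_align <- function(idx, pattern, n_policy = c("reject", "substitute")) {
  stopifnot(inherits(idx, "SparseIndex"))
  n_policy <- match.arg(n_policy)
  pc <- .check_pattern(idx, pattern, n_policy)
  res <- cpp_exact_align(idx$genome$codes, idx$ssa, idx$D, idx$K,
                         idx$table$lo, idx$table$hi, pc)
  .alignments_df(idx, res$starts, rep(list(integer(0L)), length(res$starts)),
                 length(pc))
}
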