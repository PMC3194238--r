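# Rightmost k-mismatch alignment: failure prefix, B-mask ordering, level-wise
# candidate generation, and the full search.

#' Longest matching prefix of a query over the sampled suffixes
#'
#' When a range search fails, the insertion point's two neighbouring rows
#' bound the query lexicographically, so the larger of their matched-prefix
#' lengths equals the maximum longest-common-prefix of the query with any
#' sampled suffix. Positions at or beyond `L` cannot start a match and are
#' pruned from candidate alteration. When the query occurs, `L = nchar(q)`.
#'
#' @param idx a `SparseIndex`.
#' @param q nucleotide query string.
#' @return the prefix length `L` in bases.
#' @export
longest_matching_prefix <- function(idx, q) {
  stopifnot(inherits(idx, "SparseIndex"), nchar(q) >= 1L)
  cpp_longest_prefix(idx$genome$codes, idx$ssa, idx$D, dna_to_codes(q))
}

#' Construct a mismatch mask
#'
#' A mask over a length-`m` alignment is the set of read coordinates where the
#' read differs from the reference; it encodes the binary number
#' `B = b_0 b_1 ... b_{m-1}` with 0-bits exactly at the mismatch positions.
#' Higher `B` means the mismatches sit further right (towards the 3' end).
#'
#' @param m pattern length.
#' @param positions 0-based mismatch read coordinates (any order; stored
#'   sorted ascending).
#' @export
mismatch_mask <- function(m, positions = integer(0L)) {
  m <- as.integer(m)
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) && (positions[1L] < 0L || positions[length(positions)] >= m)) {
    stop("mismatch positions must lie in [0, m)", call. = FALSE)
  }
  structure(list(m = m, positions = positions), class = "MismatchMask")
}

#' Numeric value of a mask's B number
#'
#' Exact for `m <= 53` (double precision); the comparator
#' [rightmost_compare()] is exact for any `m` and is what the aligner uses.
#'
#' @param mask a `MismatchMask`.
#' @export
mask_b <- function(mask) {
  stopifnot(inherits(mask, "MismatchMask"))
  bits <- rep(1, mask$m)
  bits[mask$positions + 1L] <- 0
  sum(bits * 2^(mask$m - seq_len(mask$m)))
}

#' Compare two masks under the rightmost-mismatch criteria
#'
#' `a` precedes `b` iff `B(a) > B(b)`: walking the ascending mismatch lists,
#' the first differing slot decides, with the larger position (or list
#' exhaustion) winning. The empty mask (exact match) precedes everything.
#'
#' @param a,b `MismatchMask` objects of equal length `m`.
#' @return -1 if `a` precedes `b`, 0 if equal, 1 if `a` follows `b`.
#' @export
rightmost_compare <- function(a, b) {
  stopifnot(inherits(a, "MismatchMask"), inherits(b, "MismatchMask"))
  if (a$m != b$m) stop("masks have different pattern lengths", call. = FALSE)
  pa <- a$positions
  pb <- b$positions
  t <- 1L
  repeat {
    ea <- t > length(pa)
    eb <- t > length(pb)
    if (ea && eb) return(0L)
    if (ea) return(-1L)
    if (eb) return(1L)
    if (pa[t] != pb[t]) return(if (pa[t] > pb[t]) -1L else 1L)
    t <- t + 1L
  }
}

#' Create an altered-pattern candidate
#'
#' The three-attribute list entry of the level-wise search: the altered
#' pattern, the positions altered so far, and a head-length offset. In this
#' implementation every candidate is searched at all `D` head lengths (the
#' offset loop lives inside the exact search), so `head_offset` records the
#' offset of a specific sparse search invocation and defaults to 0.
#'
#' @param pattern the altered pattern string.
#' @param positions 0-based read coordinates altered so far, in alteration
#'   order (strictly ascending).
#' @param head_offset head length for a specific sparse search.
#' @param L failure prefix of this candidate's own exact search, if known.
#' @export
new_candidate <- function(pattern, positions = integer(0L), head_offset = 0L,
                          L = NULL) {
  structure(list(pattern = pattern, positions = as.integer(positions),
                 head_offset = as.integer(head_offset), L = L),
            class = "Candidate")
}

.candidate_prefix <- function(idx, cand) {
  if (!is.null(cand$L)) return(cand$L)
  res <- cpp_exact_align(idx$genome$codes, idx$ssa, idx$D, idx$K,
                         idx$table$lo, idx$table$hi,
                         dna_to_codes(cand$pattern))
  res$L
}

#' Generate the next level of altered-pattern candidates
#'
#' For each parent, one candidate is emitted per (position `p`, base `c`) with
#' `c` different from the original read base at `p` (three per position) and
#' `p` constrained by two prunes: `p <= L'`, the failure prefix of the
#' parent's exact search (positions right of `L'` cannot start a match: the
#' pattern prefix preceding them does not occur), and `p` strictly greater
#' than the parent's previous alteration. The ascending-alteration rule makes
#' every mismatch set reachable in exactly one way: the leftmost mismatch of a
#' true alignment always satisfies the `L'` prune, and correcting it extends
#' the matching prefix past the next one. Candidates are emitted in descending
#' position order.
#'
#' @param idx a `SparseIndex`.
#' @param parents list of `Candidate` objects at level `j - 1`; for level 1
#'   pass a single unaltered-pattern candidate. Parents lacking a stored `L`
#'   have their exact search run here.
#' @param original the unaltered pattern string.
#' @return list of `Candidate` objects at level `j`.
#' @export
generate_level_candidates <- function(idx, parents, original) {
  stopifnot(inherits(idx, "SparseIndex"))
  m <- nchar(original)
  out <- list()
  for (par in parents) {
    stopifnot(inherits(par, "Candidate"))
    L <- .candidate_prefix(idx, par)
    floorp <- if (length(par$positions)) max(par$positions) else -1L
    pmax <- min(L, m - 1L)
    if (pmax <= floorp) next
    for (p in seq.int(pmax, floorp + 1L, by = -1L)) {
      ob <- substr(original, p + 1L, p + 1L)
      for (b in .BASES[.BASES != ob]) {
        pat <- par$pattern
        substr(pat, p + 1L, p + 1L) <- b
        out[[length(out) + 1L]] <-
          new_candidate(pat, c(par$positions, p), head_offset = 0L)
      }
    }
  }
  out
}

#' Rightmost k-mismatch alignment
#'
#' Finds every alignment of the pattern with Hamming distance at most `k`,
#' with the exact mismatch set of each, ordered by the rightmost-mismatch
#' criteria (decreasing `B`; ties by ascending genomic start). Altered
#' patterns are generated level by level from the failure prefix of each
#' exact search and searched with the same head/tail offset mechanics as
#' [exact_align()]. With `k = 0` the result equals [exact_align()].
#'
#' @param idx a `SparseIndex`.
#' @param pattern read sequence, `nchar(pattern) >= D`.
#' @param k maximum number of substitutions, `k >= 0`.
#' @param n_policy as in [exact_align()].
#' @return a data.frame in rightmost order with the columns of
#'   [exact_align()]; `mismatches` holds each hit's 0-based mismatch read
#'   coordinates, ascending.
#' @export
k_mismatch_align <- function(idx, pattern, k,
                             n_policy = c("reject", "substitute")) {
  stopifnot(inherits(idx, "SparseIndex"))
  k <- as.integer(k)
  if (is.na(k) || k < 0L) stop("k must be >= 0", call. = FALSE)
  n_policy <- match.arg(n_policy)
  pc <- .check_pattern(idx, pattern, n_policy)
  res <- cpp_k_mismatch(idx$genome$codes, idx$ssa, idx$D, idx$K,
                        idx$table$lo, idx$table$hi, pc, k)
  .alignments_df(idx, res$starts, res$masks, length(pc))
}
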