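# Sparse suffix array index: construction, sparsification, partition table.

# hard ceiling on partition table size (4^12 = ~16.8M rows)
.MAX_TABLE_ROWS <- 4^12

#' Build the full suffix array of a packed genome
#'
#' Suffixes of the sentinel-terminated genome are sorted lexicographically;
#' the implicit sentinel makes a shorter suffix sort before any suffix it
#' prefixes. Construction is prefix doubling in compiled code; any correct
#' suffix sorting routine satisfies the contract, and results are validated
#' against a brute-force sort oracle in the test suite.
#'
#' @param g a `PackedGenome`.
#' @return an object of class `SuffixArray` whose `entries` field is the
#'   0-based start position of each suffix in lexicographic order.
#' @examples
#' g <- encode_reference(c(x = "AGGTCGATTCGGGACC"))
#' build_suffix_array(g)$entries[1]  # 13
#' @export
build_suffix_array <- function(g) {
  stopifnot(inherits(g, "PackedGenome"))
  structure(list(entries = cpp_suffix_array(g$codes)), class = "SuffixArray")
}

#' @export
print.SuffixArray <- function(x, ...) {
  cat(sprintf("SuffixArray over %d suffixes\n", length(x$entries)))
  invisible(x)
}

#' Sparsify a suffix array by factor d
#'
#' Keeps entries whose value is divisible by `d`, in order of appearance, and
#' divides each by `d`. With `d = 1` this is the identity.
#'
#' @param sa a `SuffixArray`.
#' @param d sparsification factor, a positive integer.
#' @return integer vector of sampled entries (start positions divided by `d`).
#' @export
sparsify <- function(sa, d) {
  stopifnot(inherits(sa, "SuffixArray"))
  d <- as.integer(d)
  if (is.na(d) || d < 1L) stop("sparsification factor must be >= 1", call. = FALSE)
  e <- sa$entries
  e[e %% d == 0L] %/% d
}

# K-mer code (0-based row order) of each sampled suffix; NA when the suffix is
# shorter than K bases.
.row_kmer_codes <- function(genome, ssa, D, K) {
  codes <- as.integer(genome$codes)
  pos <- ssa * D
  acc <- integer(length(ssa))
  for (j in 0:(K - 1L)) {
    pj <- pos + j
    b <- integer(length(ssa))
    inb <- pj < genome$n
    b[inb] <- codes[pj[inb] + 1L]
    acc <- acc * 4L + b
  }
  acc[pos + K > genome$n] <- NA_integer_
  acc
}

#' Build the K-mer partition table over an SSA
#'
#' For every one of the 4^K K-mer codes the table holds the half-open interval
#' of SSA rows whose suffixes start with that K-mer; absent K-mers map to an
#' empty interval placed at the insertion point. Sampled suffixes shorter than
#' K bases belong to no interval (they can never match a query of length >= K)
#' and sit at interval boundaries; they remain reachable through the table-free
#' binary-search path.
#'
#' @param genome a `PackedGenome`.
#' @param ssa integer vector of sampled entries (positions divided by `D`),
#'   in lexicographic suffix order.
#' @param D sparsification factor the entries were built with.
#' @param K partition prefix length (base count), `K >= 1`.
#' @return list with integer vectors `lo` and `hi` of length 4^K (0-based
#'   half-open row bounds).
#' @export
build_partition_table <- function(genome, ssa, D, K) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be >= 1", call. = FALSE)
  if (4^K > .MAX_TABLE_ROWS) {
    stop(sprintf("partition table would need %.0f rows; use a smaller K", 4^K),
         call. = FALSE)
  }
  S <- length(ssa)
  nK <- as.integer(4^K)
  kc <- .row_kmer_codes(genome, ssa, D, K)
  lo <- hi <- integer(nK)
  nz <- which(!is.na(kc))
  if (length(nz)) {
    runs <- rle(kc[nz])
    ends <- cumsum(runs$lengths)
    firsts <- ends - runs$lengths + 1L
    lo[runs$values + 1L] <- nz[firsts] - 1L
    hi[runs$values + 1L] <- nz[ends]
    present <- logical(nK)
    present[runs$values + 1L] <- TRUE
    nxt <- S
    for (c in nK:1L) {       # place empty buckets at the next block start
      if (present[c]) nxt <- lo[c] else { lo[c] <- nxt; hi[c] <- nxt }
    }
  }
  list(lo = lo, hi = hi)
}

#' Build a sparse suffix array index
#'
#' Composes suffix sorting, sparsification by `D`, and the K-mer partition
#' table into a searchable index. `D = 1` degenerates to a plain suffix array
#' index; position 0 is always sampled.
#'
#' @param g a `PackedGenome`.
#' @param D sparsification factor (any integer >= 1). Larger `D` shrinks the
#'   index (`ceiling(n/D)` entries) at the price of `D` offset searches per
#'   query; choose `D` below the minimum read length.
#' @param K partition prefix length; the table has 4^K rows (default 8, i.e.
#'   65536 rows).
#' @return an object of class `SparseIndex` with fields `genome`, `D`, `K`,
#'   `ssa` (integer, 0-based sampled entries = positions / D) and `table`.
#' @examples
#' g <- encode_reference(c(x = "AGGTCGATTCGGGACC"))
#' idx <- build_index(g, D = 4, K = 1)
#' idx$ssa  # 0 1 3 2
#' @export
build_index <- function(g, D = 4L, K = 8L) {
  stopifnot(inherits(g, "PackedGenome"))
  D <- as.integer(D)
  if (is.na(D) || D < 1L) stop("sparsification factor must be >= 1", call. = FALSE)
  sa <- build_suffix_array(g)
  ssa <- sparsify(sa, D)
  tab <- build_partition_table(g, ssa, D, as.integer(K))
  structure(list(genome = g, D = D, K = as.integer(K), ssa = ssa, table = tab),
            class = "SparseIndex")
}

#' @export
print.SparseIndex <- function(x, ...) {
  occ <- mean(x$table$hi > x$table$lo)
  cat(sprintf(
    "SparseIndex: n=%d, D=%d, |ssa|=%d, K=%d (table occupancy %.1f%%)\n",
    x$genome$n, x$D, length(x$ssa), x$K, 100 * occ))
  invisible(x)
}
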