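# Binary index serialization: magic "PSIRA1", little-endian, 32-bit fields.
# Layout: magic, version, n, D, K, record count, n_position count, ssa length,
# record table (name length, name bytes, start, length), 2-bit packed codes
# (4 bases/byte), n_positions, ssa, partition table as 4^K (lo, hi) pairs.

.pack_codes <- function(codes) {
  v <- as.integer(codes)
  pad <- (-length(v)) %% 4L
  if (pad) v <- c(v, integer(pad))
  m <- matrix(v, nrow = 4L)
  as.raw(m[1L, ] + 4L * m[2L, ] + 16L * m[3L, ] + 64L * m[4L, ])
}

.unpack_codes <- function(bytes, n) {
  b <- as.integer(bytes)
  out <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, (b %/% 64L) %% 4L)
  as.raw(out[seq_len(n)])
}

#' Serialize a sparse index
#'
#' Writes the "PSIRA1" binary format (little-endian, 32-bit unsigned fields,
#' 2-bit packed sequence). The format is fully deterministic: identical inputs
#' produce byte-identical files.
#'
#' @param idx a `SparseIndex`.
#' @param path output file; when `NULL`, the serialized bytes are returned as
#'   a raw vector instead.
#' @return `path` invisibly, or a raw vector when `path` is `NULL`.
#' @export
save_index <- function(idx, path = NULL) {
  stopifnot(inherits(idx, "SparseIndex"))
  g <- idx$genome
  if (g$n >= 2^31) stop("genomes of 2^31 bases or more are not supported", call. = FALSE)
  con <- if (is.null(path)) rawConnection(raw(0L), "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  wu32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  writeBin(charToRaw("PSIRA1"), con)
  wu32(1L)  # format version
  wu32(c(g$n, idx$D, idx$K, nrow(g$records), length(g$n_positions),
         length(idx$ssa)))
  for (r in seq_len(nrow(g$records))) {
    nm <- charToRaw(g$records$name[r])
    wu32(length(nm))
    writeBin(nm, con)
    wu32(c(g$records$start[r], g$records$length[r]))
  }
  writeBin(.pack_codes(g$codes), con)
  if (length(g$n_positions)) wu32(g$n_positions)
  if (length(idx$ssa)) wu32(idx$ssa)
  wu32(as.integer(rbind(idx$table$lo, idx$table$hi)))
  if (is.null(path)) return(rawConnectionValue(con))
  invisible(path)
}

#' Deserialize a sparse index
#'
#' @param x path to an index file, or a raw vector as returned by
#'   [save_index()] with `path = NULL`.
#' @return a `SparseIndex` giving search results identical to the saved one.
#' @export
load_index <- function(x) {
  blob <- if (is.raw(x)) x else readBin(x, raw(), file.size(x))
  pos <- 1L
  need <- function(k) {
    if (pos + k - 1L > length(blob)) stop("truncated index file", call. = FALSE)
  }
  take <- function(k) {
    need(k)
    out <- blob[pos:(pos + k - 1L)]
    pos <<- pos + as.integer(k)
    out
  }
  ru32 <- function(cnt = 1L) {
    readBin(take(4L * cnt), "integer", n = cnt, size = 4L, endian = "little")
  }
  magic <- rawToChar(take(6L))
  if (magic != "PSIRA1") stop("bad magic: not a psira index file", call. = FALSE)
  version <- ru32()
  if (version != 1L) {
    stop(sprintf("unsupported index version %d", version), call. = FALSE)
  }
  hdr <- ru32(6L)
  n <- hdr[1L]; D <- hdr[2L]; K <- hdr[3L]
  nrec <- hdr[4L]; nnp <- hdr[5L]; nssa <- hdr[6L]
  if (n < 1L || D < 1L || K < 1L || nrec < 1L) {
    stop("corrupt index header", call. = FALSE)
  }
  recs <- data.frame(name = character(nrec), start = integer(nrec),
                     length = integer(nrec), stringsAsFactors = FALSE)
  for (r in seq_len(nrec)) {
    nl <- ru32()
    recs$name[r] <- rawToChar(take(nl))
    v <- ru32(2L)
    recs$start[r] <- v[1L]
    recs$length[r] <- v[2L]
  }
  codes <- .unpack_codes(take(ceiling(n / 4)), n)
  npos <- if (nnp > 0L) ru32(nnp) else integer(0L)
  ssa <- if (nssa > 0L) ru32(nssa) else integer(0L)
  tab <- ru32(2L * 4^K)
  even <- seq(1L, length(tab), by = 2L)
  g <- structure(list(codes = codes, n = n, records = recs,
                      n_positions = npos), class = "PackedGenome")
  structure(list(genome = g, D = D, K = K, ssa = ssa,
                 table = list(lo = tab[even], hi = tab[even + 1L])),
            class = "SparseIndex")
}
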