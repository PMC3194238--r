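# Reference model: 2-bit packed genome over concatenated FASTA records.

#' Encode FASTA records as a 2-bit packed genome
#'
#' Concatenates the records in input order into a single coordinate space.
#' Lowercase (soft-masked) bases are folded to upper case. Any IUPAC letter
#' outside A/C/G/T is stored as code 0 (an 'A') and its global position is
#' recorded in `n_positions`, so downstream alignments overlapping such a
#' position can be flagged. The end-of-text sentinel is implicit: it is never
#' stored, and suffix comparisons treat "past the end" as smaller than any
#' base.
#'
#' @param seqs a named character vector (or coercible list) of nucleotide
#'   strings; names are record (chromosome) names.
#' @return an object of class `PackedGenome` with fields `codes` (raw vector
#'   of 2-bit codes, one byte per base), `n`, `records` (data.frame with
#'   `name`, `start`, `length`; 0-based starts), and `n_positions` (sorted
#'   0-based global positions whose original character was not A/C/G/T).
#' @examples
#' g <- encode_reference(c(x = "ACGT"))
#' as.integer(g$codes)  # 0 1 2 3
#' @export
encode_reference <- function(seqs) {
  if (is.list(seqs)) seqs <- unlist(seqs)
  if (length(seqs) == 0L) stop("no sequence", call. = FALSE)
  if (!is.character(seqs)) stop("sequences must be character strings", call. = FALSE)
  nms <- names(seqs)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop("every record must be named", call. = FALSE)
  }
  if (anyDuplicated(nms)) stop("duplicate record names", call. = FALSE)
  if (any(!nzchar(seqs))) stop("no sequence", call. = FALSE)

  codes <- vector("list", length(seqs))
  npos <- vector("list", length(seqs))
  starts <- integer(length(seqs))
  lens <- integer(length(seqs))
  gpos <- 0L
  for (r in seq_along(seqs)) {
    ints <- utf8ToInt(seqs[[r]])
    # fold lower case
    low <- ints >= 97L & ints <= 122L
    ints[low] <- ints[low] - 32L
    bad <- ints < 65L | ints > 90L
    if (any(bad)) {
      stop(sprintf("non-letter character at position %d of record '%s'",
                   which(bad)[1L], nms[r]), call. = FALSE)
    }
    v <- .acgt_lookup[ints + 1L]
    na <- which(is.na(v))
    npos[[r]] <- gpos + na - 1L
    v[na] <- 0L
    codes[[r]] <- as.raw(v)
    starts[r] <- gpos
    lens[r] <- length(v)
    gpos <- gpos + length(v)
  }
  structure(list(
    codes = unlist(codes),
    n = gpos,
    records = data.frame(name = unname(nms), start = starts, length = lens,
                         stringsAsFactors = FALSE),
    n_positions = unlist(npos)
  ), class = "PackedGenome")
}

#' Decode (part of) a packed genome back to a nucleotide string
#'
#' Non-ACGT characters of the original input come back as 'A' (their 2-bit
#' substitute); consult `g$n_positions` for where that happened.
#'
#' @param g a `PackedGenome`.
#' @param from,to half-open 0-based global range; defaults to the whole genome.
#' @export
decode_genome <- function(g, from = 0L, to = g$n) {
  stopifnot(inherits(g, "PackedGenome"), from >= 0L, to <= g$n, from <= to)
  if (from == to) return("")
  codes_to_dna(g$codes[(from + 1L):to])
}

#' Base at a global position, sentinel included
#'
#' @param g a `PackedGenome`.
#' @param p 0-based global position; `p == g$n` addresses the implicit
#'   sentinel and returns `"$"`, which sorts before every base.
#' @export
base_at <- function(g, p) {
  stopifnot(inherits(g, "PackedGenome"), length(p) == 1L)
  p <- as.integer(p)
  if (is.na(p) || p < 0L || p > g$n) stop("position out of range", call. = FALSE)
  if (p == g$n) return("$")
  .BASES[as.integer(g$codes[p + 1L]) + 1L]
}

#' Map a global position to (record, offset)
#'
#' @param g a `PackedGenome`.
#' @param gpos 0-based global position, `0 <= gpos < n`.
#' @return list with `record` (name) and `offset` (0-based within the record).
#' @export
to_record <- function(g, gpos) {
  stopifnot(inherits(g, "PackedGenome"), length(gpos) == 1L)
  gpos <- as.integer(gpos)
  if (is.na(gpos) || gpos < 0L || gpos >= g$n) {
    stop("global position out of range", call. = FALSE)
  }
  i <- findInterval(gpos, g$records$start)
  list(record = g$records$name[i], offset = gpos - g$records$start[i])
}

#' Map (record, offset) to a global position
#'
#' @param g a `PackedGenome`.
#' @param record record name.
#' @param offset 0-based offset within the record.
#' @export
to_global <- function(g, record, offset) {
  stopifnot(inherits(g, "PackedGenome"))
  i <- match(record, g$records$name)
  if (is.na(i)) stop(sprintf("unknown record '%s'", record), call. = FALSE)
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 0L || offset >= g$records$length[i]) {
    stop("offset beyond record length", call. = FALSE)
  }
  g$records$start[i] + offset
}

#' @export
print.PackedGenome <- function(x, ...) {
  cat(sprintf("PackedGenome: %d bases in %d record(s), %d non-ACGT position(s)\n",
              x$n, nrow(x$records), length(x$n_positions)))
  invisible(x)
}

#' Read a multi-record FASTA reference into a packed genome
#'
#' Record names are the first whitespace-delimited token of each header.
#'
#' @param path path to a FASTA file (arbitrary line wrapping).
#' @return a `PackedGenome`.
#' @export
read_fasta_reference <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) == 0L) stop("no sequence", call. = FALSE)
  nms <- sub("\\s.*$", "", names(dss))
  encode_reference(stats::setNames(as.character(dss), nms))
}
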