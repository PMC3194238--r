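# Read input (FASTA/FASTQ, auto-detected) and alignment output (SAM/TSV).

#' Read sequencing reads from FASTA or FASTQ
#'
#' The format is auto-detected from the first character ('>' FASTA, '@'
#' FASTQ). Qualities are carried through untouched and never used in scoring.
#' Read ids are the first whitespace-delimited token.
#'
#' @param path input file.
#' @return a data.frame with columns `id`, `seq` and `qual` (`NA` for FASTA).
#' @export
read_reads <- function(path) {
  first <- substr(readLines(path, n = 1L), 1L, 1L)
  if (identical(first, ">")) {
    x <- Biostrings::readDNAStringSet(path)
    qual <- rep(NA_character_, length(x))
  } else if (identical(first, "@")) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(x)$qualities)
  } else {
    stop("unrecognised reads format (expected FASTA or FASTQ)", call. = FALSE)
  }
  data.frame(id = sub("\\s.*$", "", names(x)), seq = as.character(x),
             qual = qual, stringsAsFactors = FALSE)
}

# B-order sort of a hits data.frame (used when forward and reverse hits are
# merged; single-strand results already arrive sorted from the search).
.sort_hits <- function(hits, m) {
  if (nrow(hits) < 2L) return(hits)
  key <- vapply(hits$mismatches, function(p) {
    bits <- rep("1", m)
    bits[p + 1L] <- "0"
    paste(bits, collapse = "")
  }, "")
  o <- order(key, -hits$gstart, -match(hits$strand, c("+", "-")),
             method = "radix", decreasing = TRUE)
  hits[o, , drop = FALSE]
}

#' Write alignment results as SAM
#'
#' Emits @HD/@SQ headers from the reference record table and one line per
#' alignment: FLAG 0 for the primary hit (16 with the reverse-strand bit when
#' applicable), 256 added for secondary hits, 4 for unmapped reads; MAPQ 255;
#' CIGAR `<m>M`; `NM:i:` mismatch count; custom `XB:Z:` comma-joined mismatch
#' read positions (present when mismatches exist); `XN:i:1` when the hit
#' overlaps a converted non-ACGT reference position; `XR:Z:` the reason on
#' unmapped records. Unaligned reads are always emitted so the output is a
#' total function of the input.
#'
#' @param results list of per-read results from [align_reads()].
#' @param genome the `PackedGenome` the alignments refer to.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(results, genome, path) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", genome$records$name,
                      genome$records$length),
              "@PG\tID:psira\tPN:psira")
  body <- unlist(lapply(results, .sam_lines_one), use.names = FALSE)
  writeLines(c(header, body), path)
  invisible(path)
}

.sam_lines_one <- function(r) {
  qual <- if (is.na(r$qual)) "*" else r$qual
  if (r$status != "aligned") {
    return(paste(r$id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L, r$seq, qual,
                 paste0("XR:Z:", gsub("[\t ]", "_", r$reason)), sep = "\t"))
  }
  h <- r$hits
  m <- nchar(r$seq)
  rc_seq <- NULL
  vapply(seq_len(nrow(h)), function(j) {
    rev_strand <- h$strand[j] == "-"
    flag <- (j > 1L) * 256L + rev_strand * 16L
    if (rev_strand) {
      if (is.null(rc_seq)) rc_seq <<- revcomp_dna(r$seq)
      sq <- rc_seq
      ql <- if (is.na(r$qual)) "*" else intToUtf8(rev(utf8ToInt(r$qual)))
    } else {
      sq <- r$seq
      ql <- qual
    }
    tags <- sprintf("NM:i:%d", h$n_mismatch[j])
    if (h$n_mismatch[j] > 0L) {
      tags <- c(tags, paste0("XB:Z:", paste(h$mismatches[[j]], collapse = ",")))
    }
    if (h$n_flag[j]) tags <- c(tags, "XN:i:1")
    paste(c(r$id, flag, h$record[j], h$start[j] + 1L, 255L,
            sprintf("%dM", m), "*", 0L, 0L, sq, ql, tags), collapse = "\t")
  }, "")
}

#' Write alignment results as TSV
#'
#' Columns: read_id, record, start0 (0-based), strand, n_mismatch,
#' mismatch_positions (comma-joined, empty when exact). Unaligned reads get
#' record `*`, start0 -1 and n_mismatch -1.
#'
#' @inheritParams write_sam
#' @export
write_tsv <- function(results, path) {
  lines <- unlist(lapply(results, function(r) {
    if (r$status != "aligned") {
      return(paste(r$id, "*", -1L, "*", -1L, "", sep = "\t"))
    }
    h <- r$hits
    vapply(seq_len(nrow(h)), function(j) {
      paste(r$id, h$record[j], h$start[j], h$strand[j], h$n_mismatch[j],
            paste(h$mismatches[[j]], collapse = ","), sep = "\t")
    }, "")
  }), use.names = FALSE)
  writeLines(c("read_id\trecord\tstart0\tstrand\tn_mismatch\tmismatch_positions",
               lines), path)
  invisible(path)
}
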