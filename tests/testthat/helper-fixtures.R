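# Shared fixtures. The 16-base worked-example sequence and its D=4 sparse
# suffix array are used throughout.

FIG_SEQ <- "AGGTCGATTCGGGACC"

fig_genome <- function() encode_reference(c(x = FIG_SEQ))

fig_index <- function(D = 4L, K = 1L) build_index(fig_genome(), D = D, K = K)

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# a pattern guaranteed to share structure with the genome: either sampled
# from it (with optional substitutions) or fully random
random_pattern <- function(text, m, n_subs = 0L) {
  n <- nchar(text)
  s <- sample.int(n - m + 1L, 1L) - 1L
  p <- substr(text, s + 1L, s + m)
  if (n_subs > 0L) {
    for (pos in sample.int(m, n_subs)) {
      orig <- substr(p, pos, pos)
      substr(p, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), orig), 1L)
    }
  }
  p
}

# hits of a single-record index as a "start:mask" character set (order-free)
hit_keys <- function(df) {
  sprintf("%d:%s", df$gstart,
          vapply(df$mismatches, paste, "", collapse = ","))
}

oracle_keys <- function(orc) {
  sprintf("%d:%s", orc$starts,
          vapply(orc$masks, paste, "", collapse = ","))
}
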