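test_that("range search finds the worked-example tail and misses absent strings", {
  idx <- fig_index(D = 4, K = 1)
  r <- ssa_range_search(idx, "GACC")
  expect_identical(c(r$sp, r$ep), c(2L, 3L))
  miss <- ssa_range_search(idx, "TTTT")
  expect_identical(miss$sp, miss$ep)
})

test_that("table-assisted and table-free range searches agree", {
  g <- generate_genome(3000, seed = 13)
  idx <- build_index(g, D = 2, K = 4)
  text <- decode_genome(g)
  set.seed(14)
  for (q in 1:200) {
    m <- sample(2:20, 1)  # below and above K
    p <- random_pattern(text, m, n_subs = sample(0:1, 1))
    a <- ssa_range_search(idx, p, use_table = TRUE)
    b <- ssa_range_search(idx, p, use_table = FALSE)
    expect_identical(c(a$sp, a$ep), c(b$sp, b$ep))
  }
})

test_that("verify_head checks the genome bases preceding a sampled tail", {
  idx <- fig_index(D = 4, K = 1)
  expect_identical(verify_head(idx, 4L, "GGT"), 1L)
  expect_null(verify_head(idx, 0L, "A"))          # would underflow
  expect_null(verify_head(idx, 4L, "CCC"))        # mismatching head
  expect_identical(verify_head(idx, 4L, ""), 4L)  # empty head, offset 0
  # within-record guard: window would overrun the record
  expect_null(verify_head(idx, 4L, "GGT", pattern_length = 20L))
  expect_identical(verify_head(idx, 4L, "GGT", pattern_length = 15L), 1L)
})

test_that("exact_align finds the worked-example read at start 1", {
  idx <- fig_index(D = 4, K = 1)
  hits <- exact_align(idx, "GGTCGATTCGGGACC")
  expect_identical(hits$gstart, 1L)
  expect_identical(hits$n_mismatch, 0L)
  # self-match of the entire genome
  all_hits <- exact_align(idx, FIG_SEQ)
  expect_identical(all_hits$gstart, 0L)
})

test_that("exact_align input contract", {
  idx <- fig_index(D = 4, K = 1)
  expect_error(exact_align(idx, "GGT"), "shorter than sparsification")
  expect_error(exact_align(idx, "GGTNGATTCGGGACC"), "non-ACGT")
  # substitute policy: N -> A
  h <- exact_align(fig_index(D = 1, K = 1), "NGGT", n_policy = "substitute")
  expect_identical(h$gstart, 0L)
})

test_that("exact_align equals the naive scan for all D (oracle equivalence)", {
  set.seed(1234)
  for (rep in 1:60) {
    n <- sample(40:1500, 1)
    text <- random_dna(n)
    g <- encode_reference(c(x = text))
    m <- sample(10:32, 1)
    p <- random_pattern(text, m, n_subs = sample(0:2, 1))
    expected <- oracle_naive_scan(text, p)
    for (D in c(1L, 2L, 4L, 8L)) {
      idx <- build_index(g, D = D, K = 2L)
      got <- exact_align(idx, p)$gstart
      expect_identical(got, expected)
      expect_false(anyDuplicated(got) > 0)  # one offset per occurrence
    }
  }
})

test_that("D=1 search reduces to the plain suffix array and repeats are found", {
  text <- strrep("AC", 30)
  g <- encode_reference(c(x = text))
  idx <- build_index(g, D = 1, K = 2)
  hits <- exact_align(idx, "ACACAC")
  expect_identical(hits$gstart, as.integer(seq(0, 54, by = 2)))
})

test_that("alignments never span a record boundary", {
  g <- encode_reference(c(a = "AAAATTTT", b = "TTTTAAAA"))
  idx <- build_index(g, D = 1, K = 1)
  hits <- exact_align(idx, "TTTTTTTT")  # only exists across the boundary
  expect_identical(nrow(hits), 0L)
  hits2 <- exact_align(idx, "TTTT")
  expect_identical(hits2$record, c("a", "b"))
  expect_identical(hits2$start, c(4L, 0L))
})

test_that("hits overlapping converted non-ACGT positions carry n_flag", {
  g <- encode_reference(c(x = "ACGTNCGTACGT"))
  idx <- build_index(g, D = 1, K = 1)
  hits <- exact_align(idx, "TACG")  # genome reads ...GTACGT
  expect_true(nrow(hits) >= 1)
  expect_true(all(!hits$n_flag[hits$gstart > 4]))
  overlapping <- exact_align(idx, "GTAC")  # window [2,6) overlaps position 4
  expect_true(any(overlapping$n_flag[overlapping$gstart == 2]))
})
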