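test_that("longest_matching_prefix reproduces the worked failure analysis", {
  # reference contains AGGTCGATTC but not AGGTCGATTCG
  g <- encode_reference(c(r = "TTAGGTCGATTCATTT"))
  idx <- build_index(g, D = 1, K = 1)
  expect_identical(longest_matching_prefix(idx, "AGGTCGATTCGGGACC"), 10L)
  # a query that occurs returns its full length
  expect_identical(longest_matching_prefix(idx, "AGGTCGATTC"), 10L)
  expect_identical(longest_matching_prefix(idx, "TTAG"), 4L)
})

test_that("longest_matching_prefix equals brute-force max LCP over samples", {
  lcp <- function(a, b) {
    k <- 0L
    while (k < min(nchar(a), nchar(b)) &&
           substr(a, k + 1, k + 1) == substr(b, k + 1, k + 1)) k <- k + 1L
    k
  }
  set.seed(33)
  for (rep in 1:40) {
    n <- sample(30:400, 1)
    text <- random_dna(n)
    D <- sample(c(1L, 2L, 4L), 1)
    idx <- build_index(encode_reference(c(x = text)), D = D, K = 2L)
    q <- random_pattern(text, sample(8:20, 1), n_subs = sample(0:3, 1))
    sampled <- substring(text, seq(1, n, by = D), n)
    expect_identical(longest_matching_prefix(idx, q),
                     max(vapply(sampled, lcp, 1L, b = q)))
  }
})

test_that("rightmost_compare orders masks by decreasing B", {
  m8 <- function(p) mismatch_mask(8, p)
  expect_identical(rightmost_compare(m8(7), m8(6)), -1L)
  expect_identical(rightmost_compare(m8(5), m8(c(5, 7))), -1L)
  expect_identical(rightmost_compare(m8(c(5, 7)), m8(5)), 1L)
  expect_identical(rightmost_compare(m8(integer(0)), m8(7)), -1L)
  expect_identical(rightmost_compare(m8(c(1, 3)), m8(c(1, 3))), 0L)
  expect_error(rightmost_compare(m8(1), mismatch_mask(9, 1)), "different")
  # {5} has B 251, {5,7} has B 250 on m = 8
  expect_identical(mask_b(m8(5)), 251)
  expect_identical(mask_b(m8(c(5, 7))), 250)
})

test_that("rightmost_compare is consistent with the numeric B value", {
  set.seed(44)
  m <- 20L
  for (rep in 1:200) {
    a <- mismatch_mask(m, sample(0:(m - 1), sample(0:4, 1)))
    b <- mismatch_mask(m, sample(0:(m - 1), sample(0:4, 1)))
    expect_identical(rightmost_compare(a, b),
                     as.integer(sign(mask_b(b) - mask_b(a))))
  }
})

test_that("level-1 candidates stop at the failure prefix", {
  # L = 10 on a 16-base pattern: positions 10..0 altered, 11..15 never
  g <- encode_reference(c(r = "TTAGGTCGATTCATTT"))
  idx <- build_index(g, D = 1, K = 1)
  pat <- "AGGTCGATTCGGGACC"
  root <- new_candidate(pat)
  cands <- generate_level_candidates(idx, list(root), pat)
  pos <- vapply(cands, function(cc) cc$positions, 1L)
  expect_identical(sort(unique(pos)), 0:10)
  expect_true(all(pos <= 10L))
  # three altered bases per position, none equal to the original
  expect_identical(as.integer(table(pos)[as.character(0:10)]),
                   rep(3L, 11L))
  for (cc in cands) {
    p <- cc$positions
    expect_false(substr(cc$pattern, p + 1, p + 1) == substr(pat, p + 1, p + 1))
  }
  # emitted rightmost-first
  expect_identical(pos[1:3], rep(10L, 3L))
})

test_that("next-level alterations lie strictly right of the previous one", {
  set.seed(55)
  text <- random_dna(600)
  idx <- build_index(encode_reference(c(x = text)), D = 2, K = 2)
  pat <- random_pattern(text, 20, n_subs = 2)
  lvl1 <- generate_level_candidates(idx, list(new_candidate(pat)), pat)
  lvl2 <- generate_level_candidates(idx, lvl1, pat)
  for (cc in lvl2) {
    expect_length(cc$positions, 2L)
    expect_lt(cc$positions[1], cc$positions[2])
  }
  # no duplicate (mask, altered pattern) pairs across the level
  keys <- vapply(lvl2, function(cc) paste(cc$pattern,
                                          paste(cc$positions, collapse = ",")),
                 "")
  expect_false(anyDuplicated(keys) > 0)
})

test_that("k = 0 alignment is identical to exact_align", {
  g <- generate_genome(800, seed = 66)
  idx <- build_index(g, D = 4, K = 2)
  text <- decode_genome(g)
  set.seed(67)
  for (rep in 1:10) {
    p <- random_pattern(text, 24, n_subs = sample(0:1, 1))
    expect_identical(k_mismatch_align(idx, p, 0L), exact_align(idx, p))
  }
})

test_that("k-mismatch search equals the Hamming scan oracle", {
  set.seed(88)
  for (rep in 1:40) {
    n <- sample(100:1200, 1)
    text <- random_dna(n)
    g <- encode_reference(c(x = text))
    m <- sample(12:30, 1)
    k <- sample(1:3, 1)
    p <- random_pattern(text, m, n_subs = sample(0:k, 1))
    D <- sample(c(1L, 2L, 4L), 1)
    idx <- build_index(g, D = D, K = 2L)
    got <- k_mismatch_align(idx, p, k)
    orc <- oracle_hamming_scan(text, p, k)
    expect_setequal(hit_keys(got), oracle_keys(orc))
  }
})

test_that("output order is non-increasing in B with ties by start", {
  set.seed(99)
  for (rep in 1:10) {
    # plant the pattern plus 1- and 2-mismatch variants so several hits exist
    p <- random_dna(16)
    v1 <- p; substr(v1, 4, 4) <- setdiff(c("A", "C", "G", "T"),
                                         substr(p, 4, 4))[1]
    v2 <- p
    for (j in c(2L, 12L)) {
      substr(v2, j, j) <- setdiff(c("A", "C", "G", "T"), substr(p, j, j))[1]
    }
    text <- paste0(random_dna(40), p, random_dna(40), v1, random_dna(40), v2,
                   random_dna(40), p)
    g <- encode_reference(c(x = text))
    idx <- build_index(g, D = 2, K = 2)
    got <- k_mismatch_align(idx, p, 2L)
    expect_gte(nrow(got), 4L)
    masks <- lapply(got$mismatches, mismatch_mask, m = 16L)
    for (i in seq_len(nrow(got) - 1L)) {
      cmp <- rightmost_compare(masks[[i]], masks[[i + 1L]])
      expect_lte(cmp, 0L)
      if (cmp == 0L) expect_lt(got$gstart[i], got$gstart[i + 1L])
    }
  }
})

test_that("each reported alignment has exactly the mismatches of its mask", {
  set.seed(111)
  text <- random_dna(700)
  g <- encode_reference(c(x = text))
  idx <- build_index(g, D = 4, K = 2)
  p <- random_pattern(text, 20, n_subs = 2)
  got <- k_mismatch_align(idx, p, 3L)
  pi <- utf8ToInt(p)
  gi <- utf8ToInt(text)
  for (i in seq_len(nrow(got))) {
    s <- got$gstart[i]
    observed <- which(gi[(s + 1):(s + 20)] != pi) - 1L
    expect_identical(got$mismatches[[i]], observed)
    expect_identical(got$n_mismatch[i], length(observed))
  }
})

test_that("reads with injected errors are recovered with their exact mask", {
  g <- generate_genome(5000, seed = 321)
  reads <- sample_reads(g, count = 40, length = 30,
                        profile = error_profile_linear(0.02, 0.25),
                        seed = 322, max_mismatches = 2)
  idx <- build_index(g, D = 4, K = 4)
  for (i in seq_len(nrow(reads))) {
    got <- k_mismatch_align(idx, reads$seq[i], 2L)
    key <- sprintf("%d:%s", reads$start[i],
                   paste(reads$mask[[i]], collapse = ","))
    expect_true(key %in% hit_keys(got))
  }
})
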