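test_that("published germline junction pairs all carry an 8-bp duplication", {
  pairs <- germline_junction_pairs()
  expect_equal(nrow(pairs), 8)
  calls <- lapply(seq_len(nrow(pairs)), function(i) {
    detect_tsd(pairs$left_flank[i], pairs$right_flank[i], max_len = 12)
  })
  lens <- vapply(calls, function(x) x$tsd_len, integer(1))
  expect_true(all(lens == 8))
  expect_true(all(vapply(calls, function(x) x$canonical, logical(1))))
  expect_identical(calls[[1]]$tsd_seq, "CAAGCAAC")
  expect_identical(calls[[8]]$tsd_seq, "CTAGGTCA")
  rate <- tsd_rate(calls)
  expect_equal(rate$fraction_canonical, 1.0)
  expect_equal(unname(rate$counts_by_length[["8"]]), 8L)
})

test_that("detect_tsd finds the longest overlap, including none", {
  expect_equal(detect_tsd("AAAAAAAAAAAA", "CCCCCCCCCCCC")$tsd_len, 0)
  expect_false(detect_tsd("AAAAAAAAAAAA", "CCCCCCCCCCCC")$canonical)
  # 9-bp duplication is observed, not clipped to 8
  l <- "TGTACGGTCATGA"; r <- "GGTCATGATTTCA"
  expect_equal(detect_tsd(l, r, max_len = 12)$tsd_len, 8)
  l9 <- "TGTACGGTCATGAC"; r9 <- "GGTCATGACTTTCA"
  call9 <- detect_tsd(l9, r9, max_len = 12)
  expect_equal(call9$tsd_len, 9)
  expect_false(call9$canonical)
  expect_error(detect_tsd("ACGT", "ACGT", max_len = 12),
               class = "invalid_argument")
})

test_that("detect_tsd agrees with a brute-force all-k scan", {
  set.seed(42)
  for (i in 1:400) {
    l <- paste(sample(c("A", "T"), 12, replace = TRUE), collapse = "")
    r <- paste(sample(c("A", "T"), 12, replace = TRUE), collapse = "")
    expect_equal(detect_tsd(l, r, max_len = 12)$tsd_len,
                 brute_tsd_len(l, r, 12))
  }
})

test_that("detect_tsd is symmetric under revcomp-and-swap", {
  set.seed(7)
  for (i in 1:100) {
    l <- paste(sample(c("A", "C", "G", "T"), 14, replace = TRUE),
               collapse = "")
    r <- paste(sample(c("A", "C", "G", "T"), 14, replace = TRUE),
               collapse = "")
    expect_equal(detect_tsd(l, r, max_len = 12)$tsd_len,
                 detect_tsd(revcomp_test(r), revcomp_test(l),
                            max_len = 12)$tsd_len)
  }
})

test_that("max_len caps the scan; shorter scans still match brute force", {
  # a self-overlapping duplication word: every k <= 8 matches, so a
  # truncated scan returns exactly max_len
  l <- "ACGCATGGTTTTTTTT"; r <- "TTTTTTTTGCAGGACT"
  for (m in c(12, 8, 5, 3)) {
    expect_equal(detect_tsd(l, r, max_len = m)$tsd_len, min(m, 8L))
  }
  # on arbitrary pairs a truncated scan equals the brute-force scan
  pairs <- germline_junction_pairs()
  for (i in seq_len(nrow(pairs))) {
    for (m in c(5, 7)) {
      expect_equal(
        detect_tsd(pairs$left_flank[i], pairs$right_flank[i],
                   max_len = m)$tsd_len,
        brute_tsd_len(toupper(pairs$left_flank[i]),
                      toupper(pairs$right_flank[i]), m))
    }
  }
})

test_that("tsd_rate arithmetic and empty input behave", {
  calls <- c(replicate(86, new_call <- detect_tsd("AAATATTTACCAAGCAAC",
                                                  "CAAGCAACACGTTCAGTG"),
                       simplify = FALSE),
             replicate(14, detect_tsd("AAAAAAAAAAAA", "CCCCCCCCCCCC"),
                       simplify = FALSE))
  expect_equal(tsd_rate(calls)$fraction_canonical, 0.86)
  expect_error(tsd_rate(list()), class = "empty_input")
})
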