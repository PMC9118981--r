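test_that("pattern parsing handles the diagnostic motif, wildcards and errors", {
  p <- parse_pattern("S-G-G-X-E-X-Q-G-P-X-G-G-G-P")
  expect_length(p$positions, 14L)
  expect_equal(which(p$wildcard), c(4L, 6L, 10L))
  expect_true(all(lengths(p$positions[!p$wildcard]) == 1L))

  w <- parse_pattern("X")
  expect_length(w$positions, 1L)
  expect_setequal(w$positions[[1]], cyaclear:::AA20)

  expect_error(parse_pattern("S-G-B"), "B")
  expect_error(parse_pattern("S-g-G"), "g")
})

test_that("format/parse round-trips randomly generated valid patterns", {
  set.seed(11)
  for (i in 1:25) {
    L <- sample(1:20, 1)
    toks <- vapply(seq_len(L), function(j) {
      r <- runif(1)
      if (r < 0.25) "X"
      else if (r < 0.4)
        paste0("[", paste(sort(sample(cyaclear:::AA20, sample(2:4, 1))),
                          collapse = ""), "]")
      else sample(cyaclear:::AA20, 1)
    }, character(1))
    txt <- paste(toks, collapse = "-")
    expect_identical(format(parse_pattern(txt)), txt)
  }
})

test_that("scanner finds the pattern instance itself and nothing in short or unmatched input", {
  hits <- scan_motif("SGGAEAQGPAGGGP", cah_motif(), seq_id = "x")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 1L)
  expect_equal(hits$matched, "SGGAEAQGPAGGGP")
  expect_equal(hits$relative_position, 1 / 14)

  expect_equal(nrow(scan_motif("AAAA", cah_motif())), 0L)
  expect_error(scan_motif("", cah_motif()), "empty")
  expect_error(scan_motif("SG-GA", cah_motif()), "gap_or_stop")
})

test_that("scanner agrees with the regex oracle on random sequences up to 10 kres", {
  set.seed(42)
  pat_txt <- "S-G-G-X-E-X-Q-G-P-X-G-G-G-P"
  for (n in c(14, 100, 1000, 10000)) {
    s <- random_protein(n)
    # plant a couple of instances so agreement is not vacuous
    if (n >= 200) {
      inst <- "SGGAEAQGPAGGGP"
      for (pos in c(50, n - 60))
        substr(s, pos, pos + 13) <- inst
    }
    got <- scan_motif(s, pat_txt)$start
    expect_identical(as.integer(got), oracle_scan_regex(s, pat_txt))
  }
  # short permissive pattern: many overlapping hits
  for (i in 1:10) {
    s <- random_protein(500)
    expect_identical(as.integer(scan_motif(s, "S-X-G")$start),
                     oracle_scan_regex(s, "S-X-G"))
  }
})

test_that("motif false-positive rate on uniform sequences matches the analytic window probability", {
  set.seed(7)
  # 2 fixed positions -> per-window match probability (1/20)^2
  n_seq <- 200; len <- 600
  pat <- "S-X-G"
  windows <- n_seq * (len - 2)
  hits <- sum(vapply(seq_len(n_seq), function(i)
    nrow(scan_motif(random_protein(len), pat)), numeric(1)))
  p <- (1 / 20)^2
  expect_lt(abs(hits - windows * p), 4 * sqrt(windows * p * (1 - p)))
})

test_that("PFM columns are proper distributions with the right information content", {
  # identical sequences: frequency 1, full information
  p1 <- pfm_from_alignment(rep("SGGAEA", 10))
  expect_true(all(abs(colSums(p1$freq) - 1) < 1e-9))
  expect_equal(p1$info_bits, rep(log2(20), 6), tolerance = 1e-12)

  # uniform column: zero bits
  p2 <- pfm_from_alignment(cyaclear:::AA20)
  expect_equal(p2$info_bits, 0, tolerance = 1e-12)

  # hand-counted 5 x 6 alignment
  aln <- c("SGGAEA", "SGGAEA", "SGGCEA", "TGGAEA", "SGAAEA")
  p3 <- pfm_from_alignment(aln)
  expect_equal(unname(p3$freq["S", 1]), 4 / 5)
  expect_equal(unname(p3$freq["T", 1]), 1 / 5)
  expect_equal(unname(p3$freq["G", 3]), 4 / 5)
  expect_equal(unname(p3$freq["A", 3]), 1 / 5)
  h <- -(0.8 * log2(0.8) + 0.2 * log2(0.2))
  expect_equal(p3$info_bits[1], log2(20) - h, tolerance = 1e-12)

  expect_error(pfm_from_alignment(c("SGG", "SG")), "length")
  expect_error(pfm_from_alignment("SGG"), "at least 2")
})

test_that("gaps are excluded from PFM column counts and duplication never lowers a column maximum", {
  p <- pfm_from_alignment(c("S-G", "SAG", "SAG"))
  expect_equal(unname(p$freq["A", 2]), 1)  # gap dropped from column 2
  base <- pfm_from_alignment(c("SAG", "SCG", "ACG"))
  dup <- pfm_from_alignment(c("SAG", "SCG", "ACG", "SCG"))
  expect_true(all(apply(dup$freq, 2, max) >= apply(base$freq, 2, max) - 1e-12))
})
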