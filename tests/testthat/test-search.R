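test_that("failure expectations match hand arithmetic on the GATA-3 matrix", {
  ex <- gata3_example()
  E <- failure_expectations(ex$matrix, ex$background)
  expect_equal(E[1], 1.339, tolerance = 1e-6)
  expect_equal(E[2], 8.1532, tolerance = 1e-4)
  expect_gt(E[2], E[1])  # position 2 is matched before position 1

  # constant column c >= 0: E = |c| + c - c = c
  Mc <- scoring_matrix(matrix(0.7, 3, 4))
  expect_equal(failure_expectations(Mc, uniform_background()),
               rep(0.7, 3))
})

test_that("matching order sorts by decreasing expectation, stable ties", {
  expect_equal(matching_order(c(1.3, 8.1, 2.0)), c(2L, 3L, 1L))
  expect_equal(matching_order(rep(1, 5)), 1:5)
  expect_equal(matching_order(1:4), 4:1)
})

test_that("intermediate thresholds use best suffix scores past depth t", {
  ex <- gata3_example()
  k <- 3000L
  tab <- build_tables(ex$matrix, k)
  # column maxima: 0.17 1.64 1.03 1.18 0.58 1.12 (grid x1000)
  expect_equal(tab$suffix_max[1], 5720)  # P[0]: whole matrix
  expect_equal(tab$suffix_max[6], 1120)  # P[5]: last column only
  expect_equal(tab$suffix_max[7], 0)     # P[6]
  expect_equal(tab$thresholds[6], k)     # T[n] = k

  M1 <- scoring_matrix(matrix(c(2, -1, 0, 1), 1, 4), scale_digits = 0)
  t1 <- build_tables(M1, 5L)
  expect_equal(t1$thresholds, 5L)
  expect_equal(t1$suffix_max, c(2, 0))

  expect_error(build_tables(ex$matrix, k, order = c(1, 1, 2, 3, 4, 5)),
               "permutation")
})

test_that("exact string matching is the 0/1 special case", {
  M <- exact_match_matrix("ACG")
  res <- naive_search("TACGACGT", M, k = 3)
  expect_equal(res$hits$position, c(2L, 5L))
  expect_equal(res$hits$score, c(3, 3))
  expect_equal(lookahead_search("TACGACGT", M, 3)$hits$position, c(2L, 5L))
  expect_equal(fls_search("TACGACGT", M, uniform_background(),
                          3)$hits$position, c(2L, 5L))

  # threshold at the grid minimum: every window is a hit
  all_res <- naive_search("TACGACGT", M, k = 0)
  expect_equal(all_res$hits$position, 1:6)
  # one step past the maximum: none
  expect_equal(nrow(naive_search("TACGACGT", M, k = 4)$hits), 0L)
})

test_that("all three engines agree with the plain-R oracle", {
  set.seed(41)
  bg <- background(c(A = 0.3, C = 0.25, G = 0.25, T = 0.2))
  for (rep in 1:8) {
    n <- sample(4:14, 1)
    M <- log_odds(random_prob_matrix(n), bg)
    seq <- random_sequence(2000, bg)
    pmf <- compute_pmf(M, bg)
    thr <- p_to_threshold(pmf, sample(c(0.05, 0.005), 1))
    oracle <- r_scan_oracle(seq, M, thr$k)

    na <- naive_search(seq, M, thr$k)
    ls <- lookahead_search(seq, M, thr$k)
    fls <- fls_search(seq, M, bg, thr$k)
    expect_equal(na$hits$position, oracle$position)
    expect_equal(na$hits$score, oracle$score)
    expect_equal(hit_key(ls$hits), hit_key(na$hits))
    expect_equal(hit_key(fls$hits), hit_key(na$hits))

    w <- na$stats$windows_scanned
    expect_equal(na$stats$column_lookups, w * n)
    expect_lte(ls$stats$column_lookups, w * n)
    expect_lte(fls$stats$column_lookups, w * n)
  }
})

test_that("pruning stays sound when column maxima are negative", {
  set.seed(43)
  bg <- uniform_background()
  for (rep in 1:5) {
    n <- 8
    s <- matrix(rnorm(n * 4), n, 4)
    s[2, ] <- s[2, ] - 5   # entire column negative
    s[6, ] <- s[6, ] - 3
    M <- scoring_matrix(s)
    seq <- random_sequence(3000, bg)
    pmf <- compute_pmf(M, bg)
    k <- p_to_threshold(pmf, 0.01)$k
    na <- naive_search(seq, M, k)
    expect_equal(hit_key(lookahead_search(seq, M, k)$hits),
                 hit_key(na$hits))
    expect_equal(hit_key(fls_search(seq, M, bg, k)$hits),
                 hit_key(na$hits))
  }
})

test_that("FLS with a forced identity order degenerates to LS exactly", {
  set.seed(47)
  bg <- uniform_background()
  M <- log_odds(random_prob_matrix(10), bg)
  seq <- random_sequence(5000, bg)
  k <- p_to_threshold(compute_pmf(M, bg), 0.01)$k
  ls <- lookahead_search(seq, M, k)
  fls_id <- fls_search(seq, M, bg, k, order = 1:10)
  expect_identical(fls_id$hits, ls$hits)
  expect_identical(fls_id$stats, ls$stats)
})

test_that("windows containing ambiguous symbols are skipped and counted", {
  M <- exact_match_matrix("AAA")
  seq <- "AAANAAAA"
  res <- naive_search(seq, M, 3)
  # windows 2,3,4 contain the N; window 1 and 5,6 are clean
  expect_equal(res$hits$position, c(1L, 5L, 6L))
  expect_equal(res$stats$skipped_windows, 3)
  expect_equal(res$stats$windows_scanned, 3)
  expect_equal(res$stats$column_lookups, 9)
})

test_that("records shorter than the matrix yield a warning and no windows", {
  M <- exact_match_matrix("ACGTA")
  expect_warning(res <- naive_search("ACG", M, 5), "shorter")
  expect_equal(nrow(res$hits), 0L)
  expect_equal(res$stats$windows_scanned, 0)
})

test_that("scan_sequences orchestrates the full workflow consistently", {
  set.seed(53)
  bg <- background(c(A = 0.28, C = 0.22, G = 0.27, T = 0.23))
  seqs <- c(r1 = random_sequence(4000, bg), r2 = random_sequence(3000, bg))
  counts <- count_matrix(matrix(rpois(32, 8), 8, 4) + 1)

  res_na <- scan_sequences(seqs, counts, bg = bg, p = 0.01, engine = "na")
  res_ls <- scan_sequences(seqs, counts, bg = bg, p = 0.01, engine = "ls")
  res_fls <- scan_sequences(seqs, counts, bg = bg, p = 0.01, engine = "fls")
  expect_identical(res_na$hits, res_ls$hits)
  expect_identical(res_na$hits, res_fls$hits)
  expect_true(all(res_na$hits$score >= res_na$threshold$k_real - 1e-12))
  expect_true(all(res_na$hits$record_id %in% names(seqs)))

  # p = 1: every clean window is reported
  res_all <- scan_sequences(seqs, counts, bg = bg, p = 1, engine = "na")
  expect_equal(nrow(res_all$hits), res_all$stats$windows_scanned)

  # estimated background path and explicit threshold path both work
  res_est <- scan_sequences(seqs, counts, p = 0.01, engine = "fls")
  expect_s3_class(res_est$background, "background")
  res_k <- scan_sequences(seqs, counts, bg = bg,
                          threshold = res_na$threshold$k, engine = "na")
  expect_identical(res_k$hits, res_na$hits)
})

test_that("reverse-strand hits are reverse-complement forward hits", {
  set.seed(59)
  bg <- uniform_background()
  seqs <- c(s = random_sequence(5000, bg))
  I <- random_prob_matrix(7)
  res <- scan_sequences(seqs, I, bg = bg, p = 0.01, engine = "fls",
                        both_strands = TRUE)
  fwd <- res$hits[res$hits$strand == "+", ]
  rev <- res$hits[res$hits$strand == "-", ]

  # forward hits equal the single-strand scan
  res_f <- scan_sequences(seqs, I, bg = bg, p = 0.01, engine = "fls")
  expect_equal(fwd$position, res_f$hits$position)

  # reverse hits equal a naive scan with the reverse-complement matrix
  M <- log_odds(I, bg)
  rcM <- reverse_complement_matrix(M)
  k_rc <- p_to_threshold(compute_pmf(rcM, bg), 0.01)$k
  res_rc <- naive_search(seqs[["s"]], rcM, k_rc)
  expect_equal(rev$position, res_rc$hits$position)
  expect_equal(rev$score, res_rc$hits$score)
})
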