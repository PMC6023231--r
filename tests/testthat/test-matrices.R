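test_that("pseudocounting mixes counts with background proportionally", {
  bg <- uniform_background()
  cm <- count_matrix(matrix(c(1, 1, 1, 1), 1, 4))
  expect_equal(as.numeric(unclass(add_pseudocounts(cm, bg, 1))),
               rep(0.25, 4))

  cm2 <- count_matrix(matrix(c(0, 0, 0, 4), 1, 4))
  expect_equal(as.numeric(unclass(add_pseudocounts(cm2, bg, 1))),
               c(0.05, 0.05, 0.05, 0.85))

  # zero pseudocount weight must not leave zero probabilities behind
  cm3 <- count_matrix(matrix(c(2, 0, 0, 0), 1, 4))
  expect_error(add_pseudocounts(cm3, bg, 0), "zero")
  cm4 <- count_matrix(matrix(c(2, 1, 1, 1), 1, 4))
  expect_silent(add_pseudocounts(cm4, bg, 0))
})

test_that("log-odds scores are log(I/q) in the requested base", {
  bg <- background(c(A = 0.5, C = 0.25, G = 0.125, T = 0.125))
  I <- probability_matrix(matrix(as.numeric(bg), 1, 4))
  expect_equal(as.numeric(log_odds(I, bg)$scores), rep(0, 4))

  I2 <- probability_matrix(matrix(c(0.5, 0.25, 0.125, 0.125), 1, 4))
  expect_equal(as.numeric(log_odds(I2, uniform_background(),
                                   base = "log2")$scores),
               c(1, 0, -1, -1))

  I3 <- probability_matrix(matrix(0.25, 1, 4))
  expect_equal(as.numeric(log_odds(I3, bg, base = "log2")$scores),
               c(-1, 0, 1, 1))

  # a zero probability is rejected with position and symbol in the message
  I4 <- matrix(c(0.5, 0.5, 0, 0), 1, 4)
  pm <- structure(I4, class = "probability_matrix",
                  dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_error(log_odds(pm, bg), "position 1.*G")
})

test_that("k-mer scoring sums the selected matrix cells", {
  ex <- gata3_example()
  expect_equal(score_kmer(ex$matrix, "AGATAG"), 5.69)
  expect_equal(score_kmer(ex$matrix, "AGATAG", use_int = TRUE), 5.69)

  zero <- scoring_matrix(matrix(0, 4, 4))
  expect_equal(score_kmer(zero, "ACGT"), 0)

  M <- exact_match_matrix("GATTACA")
  expect_equal(score_kmer(M, "GATTACA"), 7)

  expect_error(score_kmer(ex$matrix, "ACG"), "length")
  expect_error(score_kmer(ex$matrix, "AGATAN"), "non-ACGT")
})

test_that("background estimation counts ACGT and excludes the rest", {
  expect_equal(as.numeric(estimate_background("ACGT")), rep(0.25, 4))
  expect_warning(bg <- estimate_background("AACG"),
                 "zero frequency")
  expect_equal(as.numeric(bg), c(0.5, 0.25, 0.25, 0))
  expect_warning(bg2 <- estimate_background("AAAANNN"), "zero frequency")
  expect_equal(as.numeric(bg2), c(1, 0, 0, 0))
  expect_error(suppressWarnings(estimate_background("NNNN")), "no unambiguous")
})

test_that("information content is relative entropy in bits", {
  bg <- background(c(A = 0.4, C = 0.3, G = 0.2, T = 0.1))
  I <- probability_matrix(matrix(as.numeric(bg), 1, 4))
  expect_equal(information_content(I, bg)$total, 0)

  eps <- 1e-9
  I2 <- probability_matrix(matrix(c(1 - 3 * eps, eps, eps, eps), 1, 4))
  expect_equal(information_content(I2)$total, 2, tolerance = 1e-6)

  I3 <- probability_matrix(matrix(0.25, 22, 4))
  expect_equal(information_content(I3)$total, 0)

  # relative-entropy nonnegativity for arbitrary matrices and backgrounds
  set.seed(7)
  for (rep in 1:20) {
    I <- random_prob_matrix(sample(3:12, 1))
    q <- rgamma(4, 1) + 0.05
    bg <- background(setNames(q / sum(q), c("A", "C", "G", "T")))
    expect_true(all(information_content(I, bg)$per_position >= -1e-12))
  }
})

test_that("pseudocount + log-odds round-trips back to the probabilities", {
  set.seed(11)
  bg <- background(c(A = 0.3, C = 0.2, G = 0.3, T = 0.2))
  counts <- count_matrix(matrix(rpois(40, 5), 10, 4))
  I <- add_pseudocounts(counts, bg, 1)
  M <- log_odds(I, bg)
  back <- exp(M$scores) * rep(as.numeric(bg), each = 10)
  back <- back / rowSums(back)
  expect_equal(unname(back), unname(unclass(I)), tolerance = 1e-9)
})

test_that("integer discretization error is bounded by half a grid step per position", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(4:15, 1)
    I <- random_prob_matrix(n)
    M <- log_odds(I, uniform_background(), scale_digits = 3)
    expect_equal(M$int_scores,
                 matrix(as.integer(sign(M$scores) *
                                     floor(abs(M$scores) * 1000 + 0.5)),
                        n, 4, dimnames = dimnames(M$int_scores)))
    kmer <- random_word(n)
    d <- abs(score_kmer(M, kmer) - score_kmer(M, kmer, use_int = TRUE))
    expect_lte(d, n * 0.5 * 1e-3)
  }
})

test_that("reverse-complement matrix scores the reverse strand", {
  set.seed(17)
  I <- random_prob_matrix(8)
  M <- log_odds(I, uniform_background())
  rc <- reverse_complement_matrix(M)
  revcomp <- function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  }
  for (rep in 1:5) {
    w <- random_word(8)
    expect_equal(score_kmer(rc, w), score_kmer(M, revcomp(w)))
  }
  # involution
  rc2 <- reverse_complement_matrix(rc)
  expect_equal(rc2$scores, M$scores)
})

test_that("invalid constructor inputs are rejected", {
  expect_error(background(c(0.5, 0.5, 0.2, -0.2)), "nonnegative")
  expect_error(background(c(0.3, 0.3, 0.3, 0.3)), "sum to 1")
  expect_error(background(c(A = 0.5, C = 0.5, G = 0, X = 0)), "A, C, G, T")
  expect_error(count_matrix(matrix(-1, 2, 4)), "nonnegative")
  expect_error(count_matrix(matrix(0, 2, 4)), "positive count")
  expect_error(probability_matrix(matrix(c(0.5, 0.5, 0.5, 0.5), 1, 4)),
               "sum to")
})
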