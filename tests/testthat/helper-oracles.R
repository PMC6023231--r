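# Independent oracles used against the package implementation. These are
# deliberately written without calling the code paths they check: the
# score-distribution oracle enumerates all 4^n k-mers, and the scan oracle
# scores every window in plain R.

BASES <- c("A", "C", "G", "T")

# Exact distribution of the integer-grid score of a random k-mer:
# enumerate all 4^n words, weight by the product of background
# probabilities. Returns a named vector (names are grid scores).
enum_score_dist <- function(M, bg) {
  n <- nrow(M$int_scores)
  stopifnot(n <= 10)
  grid <- expand.grid(rep(list(1:4), n))
  sc <- rep(0L, nrow(grid))
  pr <- rep(1, nrow(grid))
  q <- as.numeric(bg)
  for (i in seq_len(n)) {
    sc <- sc + M$int_scores[i, grid[[i]]]
    pr <- pr * q[grid[[i]]]
  }
  tapply(pr, sc, sum)
}

# Upper-tail probability P(score >= gamma) from the enumerated distribution.
enum_tail <- function(dist, gamma) {
  sum(dist[as.numeric(names(dist)) >= gamma])
}

# Plain-R full-scoring scan over one sequence; the reference for all three
# engines. k is on the integer grid.
r_scan_oracle <- function(seq, M, k) {
  codes <- match(strsplit(seq, "")[[1L]], BASES)
  n <- nrow(M$int_scores)
  m <- length(codes)
  pos <- integer(0)
  sc <- integer(0)
  if (m >= n) {
    for (i in seq_len(m - n + 1L)) {
      cs <- codes[i:(i + n - 1L)]
      if (anyNA(cs)) next
      s <- sum(M$int_scores[cbind(seq_len(n), cs)])
      if (s >= k) {
        pos <- c(pos, i)
        sc <- c(sc, s)
      }
    }
  }
  data.frame(position = pos, score = sc / 10^M$scale_digits)
}

# 0/1 matrix encoding exact matching of a word: M(i, s_i) = 1, else 0.
exact_match_matrix <- function(word) {
  ch <- strsplit(word, "")[[1L]]
  m <- matrix(0, length(ch), 4L)
  m[cbind(seq_along(ch), match(ch, BASES))] <- 1
  scoring_matrix(m, scale_digits = 0L)
}

# Random strictly positive probability matrix (independent of the
# package's IC-targeted generator).
random_prob_matrix <- function(width, floor = 1e-3, shape = 0.5) {
  p <- matrix(rgamma(width * 4L, shape = shape), width, 4L)
  p <- p / rowSums(p)
  p <- (p + floor) / (1 + 4 * floor)
  probability_matrix(p)
}

random_word <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

hit_key <- function(hits) paste(hits$position, hits$score, sep = ":")
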