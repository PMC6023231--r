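#' Score distribution of a random k-mer
#'
#' Computes the exact probability mass function of the match score of a
#' random k-mer drawn i.i.d. from the background, on the integer score
#' grid of the matrix (`scores * 10^scale_digits`). The PMF is built by
#' the classic pseudopolynomial recursion, one matrix position at a time:
#' starting from a point mass at 0, position i replaces mass `f(x)` by
#' `sum_a q_a f(x - s_ia)`. Column order does not affect the result (the
#' recursion is a convolution).
#'
#' @param M A [log_odds()] scoring matrix (its integer twin is used).
#' @param bg A [background()].
#' @param cap Maximum number of grid cells permitted (default 1e7); a
#'   wider grid aborts with advice to lower `scale_digits`.
#' @return An object of class `"score_pmf"`: list with `min_score`,
#'   `max_score` (integer grid bounds, the sums of per-position minima and
#'   maxima), `mass` (probabilities for every grid value from `min_score`
#'   to `max_score`), and `scale_digits`.
#' @export
compute_pmf <- function(M, bg, cap = 1e7) {
  stopifnot(inherits(M, "scoring_matrix"), inherits(bg, "background"))
  s <- M$int_scores
  q <- as.numeric(bg)
  n <- nrow(s)
  row_min <- apply(s, 1L, min)
  row_max <- apply(s, 1L, max)
  cmin <- cumsum(as.numeric(row_min))
  cmax <- cumsum(as.numeric(row_max))
  if (max(cmax - cmin) + 1 > cap) {
    stop("score grid needs ", max(cmax - cmin) + 1, " cells (cap ", cap,
         "); reduce scale_digits or raise cap")
  }
  f <- 1    # PMF over [off, off + length(f) - 1]
  off <- 0
  for (i in seq_len(n)) {
    len <- cmax[i] - cmin[i] + 1
    g <- numeric(len)
    for (a in 1:4) {
      if (q[a] == 0) next
      st <- off + s[i, a] - cmin[i] + 1
      idx <- st:(st + length(f) - 1L)
      g[idx] <- g[idx] + q[a] * f
    }
    f <- g
    off <- cmin[i]
  }
  structure(
    list(min_score = as.integer(cmin[n]), max_score = as.integer(cmax[n]),
         mass = f, scale_digits = M$scale_digits),
    class = "score_pmf"
  )
}

#' Upper-tail probabilities of the score distribution
#'
#' The complementary CDF `G(gamma) = P(X >= gamma) = sum_{x >= gamma} f(x)`
#' for every grid score, i.e. the p-value of each attainable score. The
#' suffix sums are accumulated from the top of the grid downward so the
#' smallest masses are added first.
#'
#' @param pmf A [compute_pmf()] result.
#' @return A numeric vector of the same length as `pmf$mass`:
#'   `G(min_score), ..., G(max_score)`. `G(min_score)` is 1 and the vector
#'   is nonincreasing.
#' @export
complementary_cdf <- function(pmf) {
  stopifnot(inherits(pmf, "score_pmf"))
  rev(cumsum(rev(pmf$mass)))
}

#' Convert a p-value to a score threshold
#'
#' Finds the smallest grid score `k` whose upper-tail probability
#' `G(k)` does not exceed the requested p-value: the discrete quantile
#' of the complementary CDF. A window scoring at least `k` is then
#' significant at level `p`; `p_achieved = G(k)` reports the attained
#' (conservative) significance. When even the maximum score has tail
#' probability above `p`, `k` is one grid step past the maximum, so no
#' window can pass.
#'
#' @param pmf A [compute_pmf()] result.
#' @param p Requested p-value in (0, 1].
#' @return An object of class `"threshold_result"`: list with
#'   `p_requested`, `k` (integer grid score), `k_real` (`k / 10^d`),
#'   `p_achieved`, and `scale_digits`.
#' @examples
#' M <- scoring_matrix(matrix(c(1, 0, 0, 0, 0, 1, 0, 0), 2, 4,
#'                            byrow = TRUE), scale_digits = 0)
#' p_to_threshold(compute_pmf(M, uniform_background()), 0.5)$k  # 1
#' @export
p_to_threshold <- function(pmf, p) {
  stopifnot(inherits(pmf, "score_pmf"))
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1) {
    stop("p must be a single value in (0, 1]")
  }
  # clamp the top of the tail at 1: the suffix sum over the whole mass can
  # exceed 1 by accumulated rounding, which would break the p = 1 case
  G <- pmin(complementary_cdf(pmf), 1)
  idx <- which(G <= p)
  if (length(idx)) {
    k <- pmf$min_score + idx[1L] - 1L
    p_achieved <- G[idx[1L]]
  } else {
    k <- pmf$max_score + 1L
    p_achieved <- 0
  }
  structure(
    list(p_requested = p, k = as.integer(k),
         k_real = k / 10^pmf$scale_digits,
         p_achieved = p_achieved, scale_digits = pmf$scale_digits),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "Significance threshold: k = %d (grid) = %.4f (score units)\n",
    x$k, x$k_real))
  cat(sprintf("  p requested = %g, p achieved = %g\n",
              x$p_requested, x$p_achieved))
  invisible(x)
}
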