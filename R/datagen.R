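#' Random background sequence
#'
#' Draws an i.i.d. DNA sequence from a background distribution — the
#' synthetic "SEQ1"-style benchmark sequence whose composition
#' approximates the requested (by default uniform) background.
#'
#' @param length Number of bases.
#' @param bg A [background()] (default uniform).
#' @param seed Optional integer seed; the caller's RNG stream is left
#'   untouched.
#' @return A single character string.
#' @export
random_sequence <- function(length, bg = uniform_background(), seed = NULL) {
  stopifnot(length >= 1, inherits(bg, "background"))
  with_seed(seed, {
    paste(sample(DNA_BASES, length, replace = TRUE, prob = as.numeric(bg)),
          collapse = "")
  })
}

# Sharpen base columns with exponent beta (p proportional to p0^beta,
# per-column renormalised) and floor with an eps-uniform mixture. Done in
# log space so large beta does not underflow to 0/0.
sharpen_columns <- function(p0, beta, eps) {
  lp <- beta * log(p0)
  lp <- lp - rep(apply(lp, 2L, max), each = 4L)
  p <- exp(lp)
  p <- p / rep(colSums(p), each = 4L)
  (p + eps) / (1 + 4 * eps)
}

# Total IC (bits, vs bg) of the sharpened matrix. Monotone nondecreasing
# in beta.
ic_at_beta <- function(p0, beta, q, eps) {
  p <- sharpen_columns(p0, beta, eps)
  sum(p * log2(p / q))
}

#' Random probability matrix with a target information content
#'
#' Generates a motif probability matrix of the given width whose total
#' information content (relative entropy against `bg`, in bits) matches
#' `target_ic` within `tol`. Each position is first drawn from a
#' symmetric Dirichlet; a single per-matrix sharpening exponent `beta`
#' (position probabilities proportional to `p^beta`, renormalised) is
#' then chosen by bisection until the total IC hits the target. Columns
#' are floored by mixing with a small uniform component so all
#' probabilities stay well away from zero and log-odds magnitudes remain
#' bounded.
#'
#' @param width Motif width (positions).
#' @param target_ic Target total IC in bits; feasible range is
#'   approximately `[0, 2 * width]` under a uniform background.
#' @param bg A [background()] (default uniform); IC is measured against
#'   it.
#' @param tol Convergence tolerance in bits (default 0.1).
#' @param seed Optional integer seed.
#' @param alpha Dirichlet concentration for the base columns (default 1,
#'   i.e. uniform over the simplex).
#' @param floor_eps Uniform mixing weight that bounds probabilities away
#'   from zero (default 5e-5).
#' @param max_iter Bisection iteration cap (default 100).
#' @return A [probability_matrix()] with attribute `achieved_ic`.
#' @export
random_matrix_with_ic <- function(width, target_ic,
                                  bg = uniform_background(), tol = 0.1,
                                  seed = NULL, alpha = 1,
                                  floor_eps = 5e-5, max_iter = 100L) {
  stopifnot(width >= 1, inherits(bg, "background"))
  q <- matrix(as.numeric(bg), 4L, width)
  if (target_ic < 0) stop("target_ic must be nonnegative")
  with_seed(seed, {
    p0 <- matrix(rgamma(4L * width, shape = alpha), 4L, width)
    p0 <- p0 / rep(colSums(p0), each = 4L)

    f <- function(beta) ic_at_beta(p0, beta, q, floor_eps)
    # bracket the target
    lo <- 0
    hi <- 1
    while (f(hi) < target_ic && hi < 2^16) hi <- hi * 2
    if (f(hi) + tol < target_ic) {
      stop("target_ic ", target_ic, " infeasible for width ", width,
           " (max achievable about ", round(f(hi), 2), " bits)")
    }
    beta <- hi
    for (it in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      v <- f(mid)
      if (abs(v - target_ic) <= tol * 0.5) { beta <- mid; break }
      if (v < target_ic) lo <- mid else hi <- mid
      beta <- mid
    }
    achieved <- f(beta)
    if (abs(achieved - target_ic) > tol) {
      stop("IC bisection failed to converge: achieved ", round(achieved, 3),
           " bits for target ", target_ic)
    }
    p <- sharpen_columns(p0, beta, floor_eps)
    out <- probability_matrix(t(p))
    attr(out, "achieved_ic") <- achieved
    out
  })
}

#' Benchmark matrix collections
#'
#' Reproducible sweeps of IC-targeted matrices mirroring the two
#' synthetic benchmark designs:
#'
#' * `"MOD1"`: fixed width 22, one group per integer target IC from 5 to
#'   30 bits — varies motif conservation at constant width.
#' * `"MOD2"`: widths 5 to 30, each with target IC equal to 70% of the
#'   maximal IC (`0.7 * 2 * width` bits under a uniform background) —
#'   varies width at constant relative conservation.
#'
#' @param kind `"MOD1"` or `"MOD2"`.
#' @param replicates Matrices per sweep cell.
#' @param seed Integer seed; the full collection is deterministic in it.
#' @param bg A [background()] (default uniform).
#' @param tol IC tolerance per matrix (default 0.1 bits).
#' @return A list with one element per sweep cell; each element is a list
#'   with `width`, `target_ic`, and `matrices` (list of probability
#'   matrices with `achieved_ic` attributes).
#' @export
mod_sweeps <- function(kind = c("MOD1", "MOD2"), replicates = 100L,
                       seed = 1L, bg = uniform_background(), tol = 0.1) {
  kind <- match.arg(kind)
  stopifnot(replicates >= 1)
  cells <- if (kind == "MOD1") {
    lapply(5:30, function(ic) list(width = 22L, target_ic = ic))
  } else {
    lapply(5:30, function(w) list(width = w, target_ic = 0.7 * 2 * w))
  }
  with_seed(seed, {
    lapply(cells, function(cell) {
      mats <- lapply(seq_len(replicates), function(i) {
        random_matrix_with_ic(cell$width, cell$target_ic, bg = bg,
                              tol = tol)
      })
      list(width = cell$width, target_ic = cell$target_ic,
           matrices = mats)
    })
  })
}
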