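#' Nucleotide background distribution
#'
#' A background distribution assigns a probability to each of the four DNA
#' bases A, C, G, T. It is the one-row representation of the constant
#' background matrix used when turning a probability matrix into log-odds
#' scores, and it parameterises the random-sequence model behind the
#' p-value computation.
#'
#' @param probs Numeric vector of length 4. If named, names must be a
#'   permutation of A, C, G, T; if unnamed, values are taken in A, C, G, T
#'   order. Must be nonnegative and sum to 1 (tolerance 1e-12).
#' @return An object of class `"background"`: a named numeric vector over
#'   A, C, G, T.
#' @examples
#' background(c(A = 0.278, C = 0.312, G = 0.212, T = 0.198))
#' uniform_background()
#' @export
background <- function(probs) {
  if (!is.numeric(probs) || length(probs) != 4L) {
    stop("background requires 4 numeric probabilities")
  }
  if (is.null(names(probs))) names(probs) <- DNA_BASES
  if (!setequal(names(probs), DNA_BASES)) {
    stop("background must be named with exactly A, C, G, T")
  }
  probs <- probs[DNA_BASES]
  if (any(probs < 0)) stop("background probabilities must be nonnegative")
  if (abs(sum(probs) - 1) > 1e-12) {
    stop("background probabilities must sum to 1 (got ", sum(probs), ")")
  }
  structure(as.numeric(setNames(probs, DNA_BASES)), class = "background")
}

#' @rdname background
#' @export
uniform_background <- function() background(rep(0.25, 4))

#' @export
print.background <- function(x, ...) {
  cat("Background distribution:\n")
  print(unclass(x))
  invisible(x)
}

#' Motif count matrix
#'
#' Wraps a matrix of per-position observation counts for a DNA motif, the
#' usual JASPAR position frequency matrix. Internally positions are rows
#' and the four bases are columns; readers and writers transpose to the
#' JASPAR on-disk layout (rows A, C, G, T).
#'
#' @param counts Numeric matrix, either `width x 4` or `4 x width` (the
#'   latter is transposed). All entries must be nonnegative and every
#'   position must have at least one positive count.
#' @param name Optional motif identifier carried as an attribute.
#' @return An object of class `"count_matrix"`.
#' @export
count_matrix <- function(counts, name = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L && nrow(counts) == 4L) counts <- t(counts)
  if (ncol(counts) != 4L) stop("count matrix must have 4 base columns")
  if (nrow(counts) < 1L) stop("count matrix must have width >= 1")
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and nonnegative")
  }
  if (any(rowSums(counts) == 0)) {
    stop("every motif position must have at least one positive count")
  }
  dimnames(counts) <- list(NULL, DNA_BASES)
  structure(counts, class = "count_matrix", name = name)
}

#' Motif probability matrix
#'
#' Per-position nucleotide probabilities I(i, a) of the signal model: each
#' position's probabilities sum to 1. Produced by [add_pseudocounts()] or
#' the synthetic generator [random_matrix_with_ic()].
#'
#' @param probs Numeric matrix `width x 4` (or `4 x width`, transposed) of
#'   probabilities; each position must sum to 1 within 1e-12.
#' @param name Optional motif identifier.
#' @return An object of class `"probability_matrix"`.
#' @export
probability_matrix <- function(probs, name = NULL) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L && nrow(probs) == 4L) probs <- t(probs)
  if (ncol(probs) != 4L) stop("probability matrix must have 4 base columns")
  if (nrow(probs) < 1L) stop("probability matrix must have width >= 1")
  if (any(probs < 0)) stop("probabilities must be nonnegative")
  bad <- which(abs(rowSums(probs) - 1) > 1e-12)
  if (length(bad)) {
    stop("probabilities at position ", bad[1L], " sum to ",
         rowSums(probs)[bad[1L]], ", not 1")
  }
  dimnames(probs) <- list(NULL, DNA_BASES)
  structure(probs, class = "probability_matrix", name = name)
}

#' Motif width
#'
#' Number of positions of a motif object (count, probability or scoring
#' matrix).
#' @param x A count, probability, or scoring matrix.
#' @return Integer width.
#' @export
motif_width <- function(x) {
  if (inherits(x, "scoring_matrix")) return(nrow(x$scores))
  nrow(x)
}

#' Convert counts to probabilities with background-proportional pseudocounts
#'
#' Adds `total_weight * bg[a]` pseudo-observations of base `a` to every
#' position before normalising, so that all probabilities are strictly
#' positive and the subsequent log-odds transform is defined:
#' `I(i,a) = (counts(i,a) + w * q_a) / (colsum_i + w)`.
#'
#' @param counts A [count_matrix()].
#' @param bg A [background()]; pseudocounts are proportional to it.
#' @param total_weight Total pseudo-observation weight `w` added per
#'   position (default 1). `total_weight = 0` is allowed only when no zero
#'   count would survive.
#' @return A [probability_matrix()].
#' @examples
#' cm <- count_matrix(matrix(c(0, 0, 0, 4), 1, 4))
#' add_pseudocounts(cm, uniform_background())  # (0.05, 0.05, 0.05, 0.85)
#' @export
add_pseudocounts <- function(counts, bg, total_weight = 1) {
  stopifnot(inherits(counts, "count_matrix"), inherits(bg, "background"))
  if (!is.numeric(total_weight) || length(total_weight) != 1L ||
      total_weight < 0) {
    stop("total_weight must be a single nonnegative number")
  }
  cm <- unclass(counts)
  if (total_weight == 0 && any(cm == 0)) {
    stop("total_weight = 0 would leave zero probabilities; ",
         "use a positive pseudocount weight")
  }
  probs <- sweep(cm + total_weight * rep(unclass(bg), each = nrow(cm)),
                 1L, rowSums(cm) + total_weight, "/")
  probability_matrix(probs, name = attr(counts, "name"))
}

#' Log-odds scoring matrix
#'
#' Transforms a probability matrix into the position weight matrix of
#' log-odds scores against a background, `M(i,a) = log(I(i,a) / q_a)`,
#' together with an integer-discretized twin (`scores * 10^scale_digits`,
#' rounded half away from zero). The integer twin is the matrix actually
#' used by both the threshold dynamic program and the scanning engines, so
#' that score/threshold comparisons are exact.
#'
#' @param I A [probability_matrix()] with strictly positive entries.
#' @param bg A [background()] with strictly positive entries.
#' @param base `"natural"` (default) or `"log2"`.
#' @param scale_digits Decimal digits `d` retained by the integer
#'   discretization (default 3, i.e. scores times 1000).
#' @return An object of class `"scoring_matrix"`: a list with elements
#'   `scores` (width x 4 real matrix), `int_scores` (integer twin),
#'   `scale_digits`, `base`, and `name`.
#' @examples
#' pm <- probability_matrix(matrix(c(0.5, 0.25, 0.125, 0.125), 1, 4))
#' log_odds(pm, uniform_background(), base = "log2")$scores  # 1 0 -1 -1
#' @export
log_odds <- function(I, bg, base = c("natural", "log2"), scale_digits = 3L) {
  stopifnot(inherits(I, "probability_matrix"), inherits(bg, "background"))
  base <- match.arg(base)
  probs <- unclass(I)
  q <- unclass(bg)
  bad <- which(probs <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("zero probability at position ", bad[1L, 1L], ", symbol ",
         DNA_BASES[bad[1L, 2L]], "; add pseudocounts first")
  }
  if (any(q <= 0)) {
    stop("background probability for ", DNA_BASES[which(q <= 0)[1L]],
         " is zero; log-odds undefined")
  }
  scores <- log(sweep(probs, 2L, q, "/"))
  if (base == "log2") scores <- scores / log(2)
  new_scoring_matrix(scores, scale_digits, base, attr(I, "name"))
}

# Low-level constructor; also used for hand-built matrices such as the
# packaged GATA-3 fixture whose printed values are already log-odds.
new_scoring_matrix <- function(scores, scale_digits = 3L, base = "natural",
                               name = NULL) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 4L && nrow(scores) == 4L) scores <- t(scores)
  if (ncol(scores) != 4L) stop("scoring matrix must have 4 base columns")
  if (nrow(scores) < 1L) stop("scoring matrix must have width >= 1")
  scale_digits <- as.integer(scale_digits)
  dimnames(scores) <- list(NULL, DNA_BASES)
  int_scores <- matrix(as.integer(round_half_out(scores * 10^scale_digits)),
                       nrow(scores), 4L, dimnames = dimnames(scores))
  structure(
    list(scores = scores, int_scores = int_scores,
         scale_digits = scale_digits, base = base, name = name),
    class = "scoring_matrix"
  )
}

#' @rdname log_odds
#' @param scores A `width x 4` (or `4 x width`) real matrix of ready-made
#'   log-odds scores.
#' @param name Optional motif identifier.
#' @export
scoring_matrix <- function(scores, scale_digits = 3L,
                           base = "natural", name = NULL) {
  new_scoring_matrix(scores, scale_digits, base, name)
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat(sprintf("Scoring matrix%s: width %d, %s log, scale 10^-%d\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              nrow(x$scores), x$base, x$scale_digits))
  print(t(x$scores))
  invisible(x)
}

#' Score one k-mer against a scoring matrix
#'
#' Sums the matrix entry selected by each symbol:
#' `G_M(s) = sum_i M(i, s_i)`.
#'
#' @param M A [log_odds()] scoring matrix.
#' @param kmer A string over A, C, G, T whose length equals the motif
#'   width.
#' @param use_int If `TRUE`, sum the integer-discretized scores and return
#'   the result divided by `10^scale_digits`.
#' @return The match score (a single number).
#' @export
score_kmer <- function(M, kmer, use_int = FALSE) {
  stopifnot(inherits(M, "scoring_matrix"))
  n <- nrow(M$scores)
  codes <- encode_dna_cpp(kmer)
  if (length(codes) != n) {
    stop("k-mer length ", length(codes), " != matrix width ", n)
  }
  if (any(codes == 0L)) {
    stop("k-mer contains a non-ACGT symbol at position ",
         which(codes == 0L)[1L])
  }
  idx <- cbind(seq_len(n), codes)
  if (use_int) {
    sum(M$int_scores[idx]) / 10^M$scale_digits
  } else {
    sum(M$scores[idx])
  }
}

#' Estimate the background distribution from sequence
#'
#' Counts A, C, G, T in a single streaming pass; other symbols (N,
#' lower-case handled case-insensitively) are excluded from both numerator
#' and denominator.
#'
#' @param seq A character vector of sequences (all records pooled) or a
#'   `DNAStringSet`.
#' @return A [background()]. A warning is raised if any base has zero
#'   frequency, since such a background cannot feed [log_odds()].
#' @examples
#' estimate_background("AACG")  # A 0.5, C 0.25, G 0.25, T 0
#' @export
estimate_background <- function(seq) {
  seq <- as_records(seq)
  counts <- numeric(4)
  for (s in seq) {
    codes <- encode_dna_cpp(s)
    counts <- counts + tabulate(codes, nbins = 4L)
  }
  if (sum(counts) == 0) {
    stop("sequence contains no unambiguous A/C/G/T symbols")
  }
  probs <- counts / sum(counts)
  if (any(probs == 0)) {
    warning("estimated background has zero frequency for ",
            paste(DNA_BASES[probs == 0], collapse = ", "),
            "; log-odds scoring against it will fail")
  }
  background(setNames(probs, DNA_BASES))
}

#' Motif information content
#'
#' Per-position relative entropy (in bits) of the motif probabilities
#' against the background, `IC_i = sum_a I(i,a) log2(I(i,a)/q_a)`, and its
#' total over positions. Under a uniform background this is the familiar
#' `2 - H(column)` bits; it measures how distinguishable the motif is from
#' background, with a maximum of 2 bits per position.
#'
#' @param I A [probability_matrix()] with strictly positive entries.
#' @param bg A [background()] with strictly positive entries (default
#'   uniform).
#' @return A list with `per_position` (numeric vector, bits) and `total`
#'   (bits). Each per-position value is nonnegative.
#' @export
information_content <- function(I, bg = uniform_background()) {
  stopifnot(inherits(I, "probability_matrix"), inherits(bg, "background"))
  probs <- unclass(I)
  q <- unclass(bg)
  if (any(probs <= 0)) stop("probability matrix has zero entries")
  if (any(q <= 0)) stop("background has zero entries")
  per <- rowSums(probs * log2(sweep(probs, 2L, q, "/")))
  list(per_position = per, total = sum(per))
}

#' Reverse complement of a scoring matrix
#'
#' Reverses the position order and swaps complementary bases (A with T, C
#' with G), giving the matrix that scores the reverse strand of a window
#' read on the forward strand.
#'
#' @param M A scoring matrix.
#' @return A scoring matrix of the same width and scale.
#' @export
reverse_complement_matrix <- function(M) {
  stopifnot(inherits(M, "scoring_matrix"))
  n <- nrow(M$scores)
  rc <- M$scores[rev(seq_len(n)), c("T", "G", "C", "A"), drop = FALSE]
  colnames(rc) <- DNA_BASES
  new_scoring_matrix(rc, M$scale_digits, M$base,
                     if (is.null(M$name)) NULL else paste0(M$name, "_rc"))
}
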