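#' Matching-failure expectations of matrix positions
#'
#' The per-position heuristic weight used by the faster lookahead engine:
#' `E_i = |min_a M(i,a)| + max_a M(i,a) - sum_a q_a M(i,a)`, combining the
#' score range of the position with its background-expected score. A
#' position with large `E_i` is likely to reveal early that a random
#' window cannot reach the threshold, so such positions are matched first.
#'
#' @param M A scoring matrix (real scores are used).
#' @param bg A [background()].
#' @return Numeric vector `E` of length `motif_width(M)`.
#' @export
failure_expectations <- function(M, bg) {
  stopifnot(inherits(M, "scoring_matrix"), inherits(bg, "background"))
  s <- M$scores
  q <- as.numeric(bg)
  abs(apply(s, 1L, min)) + apply(s, 1L, max) - as.numeric(s %*% q)
}

#' Column visiting order from failure expectations
#'
#' Positions sorted by decreasing expectation; ties are broken by
#' ascending original position, so the order is deterministic and the
#' all-equal case yields the identity permutation.
#'
#' @param E Numeric vector of per-position expectations.
#' @return An integer permutation of `seq_along(E)`.
#' @export
matching_order <- function(E) {
  order(-E, seq_along(E))
}

#' Intermediate lookahead thresholds
#'
#' Precomputes, for the given column visiting order, the best achievable
#' suffix scores `P[t] = sum_{j > t} max_a M(pi(j), a)` (on the integer
#' grid) and the per-depth thresholds `T[t] = k - P[t]`. A window whose
#' running score after depth `t` falls below `T[t]` cannot reach `k` even
#' with a best-case suffix, so it is abandoned. `P[n] = 0` and
#' `T[n] = k`.
#'
#' @param M A scoring matrix.
#' @param k Significance threshold on the integer score grid.
#' @param order Integer permutation of matrix positions (default
#'   identity, i.e. plain lookahead scoring).
#' @param bg Optional [background()]; when supplied, failure expectations
#'   are stored alongside the tables.
#' @return An object of class `"lookahead_tables"`: list with `order`,
#'   `suffix_max` (`P[0..n]`, length n+1), `thresholds` (`T[1..n]`), `k`,
#'   and `expectations` (or NULL).
#' @export
build_tables <- function(M, k, order = seq_len(motif_width(M)), bg = NULL) {
  stopifnot(inherits(M, "scoring_matrix"))
  n <- nrow(M$int_scores)
  if (length(order) != n || !setequal(order, seq_len(n))) {
    stop("order must be a permutation of 1..", n)
  }
  k <- as.integer(round(k))
  col_max <- apply(M$int_scores, 1L, max)[order]
  # P[t] (t = 0..n): best suffix score over permuted positions t+1..n
  P <- rev(cumsum(c(0, rev(as.numeric(col_max)))))
  thresholds <- k - P[-1L]
  E <- if (!is.null(bg)) failure_expectations(M, bg) else NULL
  structure(
    list(order = as.integer(order), suffix_max = P,
         thresholds = as.integer(thresholds), k = k, expectations = E),
    class = "lookahead_tables"
  )
}

# Shared driver for the three engines over one record.
scan_one <- function(seq, M, k, order, prune, record_id = "seq1") {
  stopifnot(inherits(M, "scoring_matrix"))
  n <- nrow(M$int_scores)
  codes <- if (is.integer(seq)) seq else encode_dna_cpp(seq)
  if (length(codes) < n) {
    warning("record '", record_id, "' is shorter than the matrix width (",
            length(codes), " < ", n, "); no windows to scan")
  }
  tab <- build_tables(M, k, order)
  res <- scan_codes_cpp(codes, M$int_scores, tab$order, tab$thresholds,
                        prune)
  hits <- data.frame(
    record_id = rep(record_id, length(res$positions)),
    position = res$positions,
    strand = rep("+", length(res$positions)),
    score = res$scores / 10^M$scale_digits,
    stringsAsFactors = FALSE
  )
  stats <- list(
    windows_scanned = res$windows_scanned,
    column_lookups = res$column_lookups,
    windows_pruned_at = setNames(res$prune_hist, seq_len(n)),
    hits = nrow(hits),
    skipped_windows = res$skipped_windows
  )
  list(hits = hits, stats = stats)
}

#' Scanning engines
#'
#' All three engines report exactly the windows whose full match score
#' (on the integer grid) reaches the threshold `k`, together with their
#' scores; they differ only in how much scoring work they do per window.
#'
#' * `naive_search()` (NA) scores every window over all positions.
#' * `lookahead_search()` (LS) visits positions left to right and
#'   abandons a window as soon as its running score plus the best
#'   achievable suffix score cannot reach `k`.
#' * `fls_search()` (FLS) additionally permutes the visiting order by
#'   decreasing matching-failure expectation, so windows tend to be
#'   abandoned earlier; the intermediate thresholds are rebuilt for the
#'   permuted order.
#'
#' Windows containing non-ACGT symbols are skipped and counted in the
#' statistics. Scores are returned in real units (grid score divided by
#' `10^scale_digits`).
#'
#' @param seq A single sequence (character string) or its integer
#'   encoding.
#' @param M A scoring matrix.
#' @param k Significance threshold on the integer score grid (as returned
#'   in `p_to_threshold(...)$k`).
#' @param bg A [background()] (FLS only; drives the column order).
#' @param record_id Record name used in the hit table.
#' @param order Optional explicit column order for `fls_search`
#'   (overrides the expectation-derived order; mainly for testing).
#' @return A list with `hits` (data.frame: record_id, position, strand,
#'   score) and `stats` (windows_scanned, column_lookups,
#'   windows_pruned_at, hits, skipped_windows).
#' @examples
#' M <- scoring_matrix(matrix(c(1, 0, 0, 0,
#'                              0, 1, 0, 0,
#'                              0, 0, 1, 0), 3, 4, byrow = TRUE),
#'                     scale_digits = 0)
#' naive_search("TACGACGT", M, k = 3)$hits$position  # 2 and 5
#' @export
naive_search <- function(seq, M, k, record_id = "seq1") {
  scan_one(seq, M, k, seq_len(motif_width(M)), prune = FALSE,
           record_id = record_id)
}

#' @rdname naive_search
#' @export
lookahead_search <- function(seq, M, k, record_id = "seq1") {
  scan_one(seq, M, k, seq_len(motif_width(M)), prune = TRUE,
           record_id = record_id)
}

#' @rdname naive_search
#' @export
fls_search <- function(seq, M, bg, k, record_id = "seq1", order = NULL) {
  if (is.null(order)) {
    order <- matching_order(failure_expectations(M, bg))
  }
  scan_one(seq, M, k, order, prune = TRUE, record_id = record_id)
}

# Merge per-record stats.
combine_stats <- function(stats_list) {
  n <- length(stats_list[[1L]]$windows_pruned_at)
  out <- list(
    windows_scanned = sum(vapply(stats_list, `[[`, 0, "windows_scanned")),
    column_lookups = sum(vapply(stats_list, `[[`, 0, "column_lookups")),
    windows_pruned_at = setNames(
      Reduce(`+`, lapply(stats_list, `[[`, "windows_pruned_at")),
      seq_len(n)),
    hits = sum(vapply(stats_list, `[[`, 0, "hits")),
    skipped_windows = sum(vapply(stats_list, `[[`, 0, "skipped_windows"))
  )
  out
}

#' Scan sequence records for motif matches
#'
#' The full workflow: estimate the background from the records (unless one
#' is supplied), convert counts or probabilities to a log-odds scoring
#' matrix (counts are pseudocounted first), discretize, derive the score
#' threshold from the requested p-value by the exact score-distribution
#' dynamic program, build the column order and intermediate thresholds,
#' and scan every record with the chosen engine. Optionally the reverse
#' strand is scanned with the reverse-complement matrix (its own
#' threshold is computed at the same p-value); reverse-strand hits are
#' reported on forward coordinates with strand `"-"`.
#'
#' @param records Sequences: named character vector, single string, or
#'   `DNAStringSet`.
#' @param motif A [count_matrix()], [probability_matrix()], or ready
#'   scoring matrix.
#' @param bg A [background()], or NULL to estimate from the records.
#' @param p P-value in (0, 1] from which the threshold is derived.
#' @param threshold Explicit grid-score threshold; overrides `p` (exactly
#'   one of the two is used).
#' @param engine `"fls"` (default), `"ls"`, or `"na"`.
#' @param both_strands Also scan the reverse strand (default FALSE).
#' @param scale_digits,pseudocount_weight,log_base Preprocessing knobs
#'   passed to [log_odds()] and [add_pseudocounts()].
#' @return An object of class `"pwm_scan"`: list with `hits` (data.frame
#'   over all records, sorted by record and position), `stats`,
#'   `threshold` (a `threshold_result`, or the explicit grid threshold),
#'   `order`, `background`, and `matrix`.
#' @export
scan_sequences <- function(records, motif, bg = NULL, p = 1e-4,
                           threshold = NULL,
                           engine = c("fls", "ls", "na"),
                           both_strands = FALSE, scale_digits = 3L,
                           pseudocount_weight = 1,
                           log_base = "natural") {
  engine <- match.arg(engine)
  if (!is.null(threshold) && !missing(p)) {
    stop("supply exactly one of p and threshold")
  }
  records <- as_records(records)
  if (is.null(bg)) bg <- estimate_background(records)

  M <- motif
  if (inherits(M, "count_matrix")) {
    M <- add_pseudocounts(M, bg, pseudocount_weight)
  }
  if (inherits(M, "probability_matrix")) {
    M <- log_odds(M, bg, base = log_base, scale_digits = scale_digits)
  }
  stopifnot(inherits(M, "scoring_matrix"))

  strands <- list(list(M = M, strand = "+"))
  if (both_strands) {
    strands <- c(strands,
                 list(list(M = reverse_complement_matrix(M), strand = "-")))
  }

  ord <- switch(engine,
                fls = matching_order(failure_expectations(M, bg)),
                seq_len(motif_width(M)))

  all_hits <- list()
  all_stats <- list()
  thr_out <- NULL
  for (str in strands) {
    Ms <- str$M
    if (is.null(threshold)) {
      thr <- p_to_threshold(compute_pmf(Ms, bg), p)
      k <- thr$k
    } else {
      thr <- NULL
      k <- as.integer(threshold)
    }
    if (str$strand == "+") thr_out <- if (is.null(thr)) threshold else thr
    ord_s <- if (engine == "fls" && str$strand == "-") {
      matching_order(failure_expectations(Ms, bg))
    } else {
      ord
    }
    for (rid in names(records)) {
      res <- switch(engine,
        na = naive_search(records[[rid]], Ms, k, record_id = rid),
        ls = lookahead_search(records[[rid]], Ms, k, record_id = rid),
        fls = fls_search(records[[rid]], Ms, bg, k, record_id = rid,
                         order = ord_s))
      if (str$strand == "-") {
        res$hits$strand <- rep("-", nrow(res$hits))
      }
      all_hits[[length(all_hits) + 1L]] <- res$hits
      all_stats[[length(all_stats) + 1L]] <- res$stats
    }
  }
  hits <- do.call(rbind, all_hits)
  hits <- hits[order(match(hits$record_id, names(records)),
                     hits$position, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  stats <- combine_stats(all_stats)
  structure(
    list(hits = hits, stats = stats, threshold = thr_out, order = ord,
         engine = engine, background = bg, matrix = M),
    class = "pwm_scan"
  )
}

#' @export
print.pwm_scan <- function(x, ...) {
  cat(sprintf("PWM scan (%s engine): %d hit(s) in %.0f window(s)\n",
              x$engine, nrow(x$hits), x$stats$windows_scanned))
  if (inherits(x$threshold, "threshold_result")) print(x$threshold)
  if (nrow(x$hits)) print(utils::head(x$hits, 10))
  invisible(x)
}

#' Write hits as TSV or BED
#'
#' The TSV carries 1-based inclusive positions (columns record_id,
#' position, strand, score); BED6 uses 0-based half-open intervals with
#' the match score in the score column.
#'
#' @param scan_result A [scan_sequences()] result (or a bare hits
#'   data.frame for `write_hits_tsv`).
#' @param path Output path.
#' @export
write_hits_tsv <- function(scan_result, path) {
  hits <- if (inherits(scan_result, "pwm_scan")) scan_result$hits
          else scan_result
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
write_hits_bed <- function(scan_result, path) {
  stopifnot(inherits(scan_result, "pwm_scan"))
  hits <- scan_result$hits
  n <- motif_width(scan_result$matrix)
  bed <- data.frame(
    chrom = hits$record_id,
    start = hits$position - 1L,
    end = hits$position - 1L + n,
    name = if (is.null(scan_result$matrix$name)) "motif"
           else scan_result$matrix$name,
    score = hits$score,
    strand = hits$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
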