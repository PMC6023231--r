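#' Hardware-independent engine benchmark
#'
#' Runs the three engines on identical seeded inputs across a sweep and
#' reports algorithmic cost — mean matrix-cell lookups per scanned window
#' and mean scan depth — rather than wall-clock time, which depends on
#' hardware. Three sweep designs are available:
#'
#' * `"mod1"`: width-22 matrices across target IC levels (conservation
#'   sweep).
#' * `"mod2"`: matrices of increasing width at 70% of maximal IC (width
#'   sweep).
#' * `"pvalue"`: a fixed matrix design across p-values `10^-1 .. 10^-6`
#'   (threshold sweep).
#'
#' @param sweep `"mod1"`, `"mod2"`, or `"pvalue"`.
#' @param replicates Matrices per sweep cell (default 10).
#' @param seq_length Length of the shared random background sequence
#'   (default 1e5).
#' @param p P-value for the mod sweeps (default 1e-4).
#' @param seed Integer seed.
#' @param bg A [background()] (default uniform) used for sequence
#'   generation, matrix generation, and thresholds.
#' @param ic_levels Target ICs for `"mod1"` (default `c(5, 15, 25)`).
#' @param widths Widths for `"mod2"` (default `5:30`).
#' @param pvalue_width,pvalue_ic_frac Matrix design for the `"pvalue"`
#'   sweep: width (default 21) and IC as a fraction of maximum (default
#'   0.7).
#' @return A data.frame with one row per (cell, engine): columns `cell`
#'   (IC, width, or p), `engine`, `mean_lookups_per_window`,
#'   `mean_hits`, `windows`, and `replicates`.
#' @export
run_bench <- function(sweep = c("mod1", "mod2", "pvalue"),
                      replicates = 10L, seq_length = 1e5, p = 1e-4,
                      seed = 1L, bg = uniform_background(),
                      ic_levels = c(5, 15, 25), widths = 5:30,
                      pvalue_width = 21L, pvalue_ic_frac = 0.7) {
  sweep <- match.arg(sweep)
  seq <- random_sequence(seq_length, bg, seed = seed)
  codes <- encode_dna_cpp(seq)
  engines <- c("na", "ls", "fls")

  cells <- switch(sweep,
    mod1 = lapply(ic_levels, function(ic)
      list(cell = ic, width = 22L, target_ic = ic, p = p)),
    mod2 = lapply(widths, function(w)
      list(cell = w, width = as.integer(w), target_ic = 0.7 * 2 * w,
           p = p)),
    pvalue = lapply(10^-(1:6), function(pv)
      list(cell = pv, width = pvalue_width,
           target_ic = pvalue_ic_frac * 2 * pvalue_width, p = pv))
  )

  rows <- list()
  for (ci in seq_along(cells)) {
    cell <- cells[[ci]]
    acc <- setNames(numeric(3), engines)
    hits_acc <- setNames(numeric(3), engines)
    windows <- 0
    for (r in seq_len(replicates)) {
      # common random numbers: replicate r shares its matrix seed across
      # all sweep cells, so cell contrasts are paired and between-matrix
      # variance cancels out of the comparison
      mat_seed <- (seed * 10007L + r * 977L) %% 2147483647L
      I <- random_matrix_with_ic(cell$width, cell$target_ic, bg = bg,
                                 seed = mat_seed)
      M <- log_odds(I, bg)
      thr <- p_to_threshold(compute_pmf(M, bg), cell$p)
      ordE <- matching_order(failure_expectations(M, bg))
      for (e in engines) {
        res <- switch(e,
          na = naive_search(codes, M, thr$k),
          ls = lookahead_search(codes, M, thr$k),
          fls = fls_search(codes, M, bg, thr$k, order = ordE))
        w <- res$stats$windows_scanned
        acc[e] <- acc[e] + res$stats$column_lookups / w
        hits_acc[e] <- hits_acc[e] + res$stats$hits
        if (e == "na") windows <- w
      }
    }
    for (e in engines) {
      rows[[length(rows) + 1L]] <- data.frame(
        cell = cell$cell, engine = e,
        mean_lookups_per_window = acc[e] / replicates,
        mean_hits = hits_acc[e] / replicates,
        windows = windows, replicates = replicates
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
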