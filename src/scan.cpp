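#include <Rcpp.h>
using namespace Rcpp;

// Encode a DNA string to 1..4 for A,C,G,T (case-insensitive), 0 for any
// other symbol. 1-based codes index matrix columns directly from R.
// [[Rcpp::export]]
IntegerVector encode_dna_cpp(std::string seq) {
  const R_xlen_t m = seq.size();
  IntegerVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    switch (seq[i]) {
    case 'A': case 'a': out[i] = 1; break;
    case 'C': case 'c': out[i] = 2; break;
    case 'G': case 'g': out[i] = 3; break;
    case 'T': case 't': out[i] = 4; break;
    default: out[i] = 0;
    }
  }
  return out;
}

// Sliding-window scan over integer-encoded sequence with integer grid
// scores. `ord` is the 1-based column visiting order, `thr` the per-depth
// intermediate thresholds T[t] (T[n] equals the significance threshold k).
// With prune = false every clean window is scored over all n positions and
// compared against thr[n-1] only (the naive engine); with prune = true the
// window is abandoned at the first depth t where the running score drops
// below thr[t-1] (lookahead engines; identity `ord` gives plain lookahead
// scoring, the failure-expectation permutation gives the faster variant).
// Windows containing any non-ACGT symbol are skipped and counted.
// [[Rcpp::export]]
List scan_codes_cpp(IntegerVector codes, IntegerMatrix int_scores,
                    IntegerVector ord, IntegerVector thr, bool prune) {
  const R_xlen_t m = codes.size();
  const int n = int_scores.nrow();
  const R_xlen_t nwin = m - n + 1;

  std::vector<int> hit_pos;
  std::vector<int> hit_score;
  IntegerVector prune_hist(n);
  double lookups = 0.0;
  R_xlen_t scanned = 0, skipped = 0;

  if (nwin >= 1) {
    // number of ambiguous symbols in the current window
    int amb = 0;
    for (int j = 0; j < n; ++j) amb += (codes[j] == 0);
    for (R_xlen_t i = 0; i < nwin; ++i) {
      if (i > 0) {
        amb += (codes[i + n - 1] == 0) - (codes[i - 1] == 0);
      }
      if (amb > 0) { ++skipped; continue; }
      ++scanned;
      long R = 0;
      if (prune) {
        bool pruned = false;
        for (int t = 0; t < n; ++t) {
          const int col = ord[t] - 1;           // matrix position
          const int sym = codes[i + col] - 1;   // 0..3
          R += int_scores(col, sym);
          ++lookups;
          if (R < (long)thr[t]) {
            ++prune_hist[t];
            pruned = true;
            break;
          }
        }
        if (!pruned) {
          hit_pos.push_back((int)(i + 1));
          hit_score.push_back((int)R);
        }
      } else {
        for (int t = 0; t < n; ++t) {
          const int col = ord[t] - 1;
          const int sym = codes[i + col] - 1;
          R += int_scores(col, sym);
          ++lookups;
        }
        if (R >= (long)thr[n - 1]) {
          hit_pos.push_back((int)(i + 1));
          hit_score.push_back((int)R);
        }
      }
    }
  }

  return List::create(
    _["positions"] = wrap(hit_pos),
    _["scores"] = wrap(hit_score),
    _["windows_scanned"] = (double)scanned,
    _["column_lookups"] = lookups,
    _["prune_hist"] = prune_hist,
    _["skipped_windows"] = (double)skipped);
}
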