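---
title: "Lookahead PWM scanning: model, thresholds, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lookahead PWM scanning: model, thresholds, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flscan)
```

## The scanning problem

A transcription factor motif of width $n$ over the DNA alphabet
$\{A,C,G,T\}$ is modelled by per-position base probabilities $I(i,a)$.
Against a background distribution $q$, the motif becomes the log-odds
position weight matrix $M(i,a) = \log I(i,a)/q_a$, and a sequence window
$s_i \dots s_{i+n-1}$ scores $g_i = \sum_t M(t, s_{i+t-1})$. The task is
to report every window with $g_i \ge k$, together with its score. Exact
string matching is the special case of a 0/1 matrix with $k = n$, which
the test suite uses as an independent oracle.

Two assumptions are inherited by everything downstream: window symbols
are treated as independent draws from $q$ when computing significance,
and $q$ is a single zeroth-order distribution (no Markov structure).
These are the standard PWM-scanning assumptions; both are wrong in
detail for real genomes (see *Limitations*).

## From p-value to threshold

Users rarely know a meaningful raw score cutoff, so `scan_sequences()`
derives one from a p-value. Scores are first discretized to an integer
grid, $\tilde M = \operatorname{round}(M \cdot 10^d)$ with $d = 3$ by
default (rounding half away from zero). On that grid the distribution of
the score $X$ of a random background window is computed exactly by the
classic column-by-column recursion: starting from a point mass at zero,
position $i$ transforms $f(x)$ into $\sum_a q_a f(x - \tilde M(i,a))$.
The complementary CDF $G(\gamma) = P(X \ge \gamma)$ then yields the
threshold as the discrete quantile
$k = \min\{\gamma : G(\gamma) \le p\}$, and the attained significance
$G(k)$ is reported alongside (`p_achieved`), since a discrete
distribution cannot in general hit $p$ exactly. When even the grid
maximum has tail probability above $p$ — short or weakly informative
motifs at stringent $p$ — the threshold is placed one step past the
maximum and nothing can pass; this conservative behaviour is reported
via `p_achieved = 0` rather than silently relaxing $p$.

Three numerical choices matter here:

* **Grid scale $d = 3$.** The DP table spans
  $\sum_i (\max_a \tilde M(i,a) - \min_a \tilde M(i,a))$ cells, about
  $2 \times 10^5$ for a width-22 motif with the default generator floor
  (below), far under the $10^7$-cell cap; discretization error is
  bounded by $n \cdot 0.5 \cdot 10^{-3}$ in score units, two orders of
  magnitude below typical column score gaps. A cap violation aborts with
  advice to lower `scale_digits` rather than exhausting memory.
* **One integer matrix everywhere.** The same $\tilde M$ feeds the DP
  *and* the scanning engines, and all engine comparisons happen on the
  grid. Mixing real-score scanning with grid-score thresholds would
  silently break the p-value semantics of reported hits.
* **Tail sums.** $G$ is accumulated from the top of the grid downward
  (smallest masses first) and clamped at 1, since the full suffix sum
  can exceed 1 by a few ulps, which would otherwise break the $p = 1$
  contract $k = \text{grid minimum}$.

## Lookahead pruning and the permuted order

Lookahead scoring precomputes the best achievable suffix score past each
depth $t$, $P_t = \sum_{j > t} \max_a \tilde M(\pi(j), a)$, and abandons
a window at the first depth where the running score drops below
$T_t = k - P_t$. The suffix starts at $t + 1$: summing from $t$ itself
would double-count the column just added to the running score and is
unsound when a column maximum is negative, a case the test suite
exercises with adversarial matrices. Since $T_n = k$, the final prune
check *is* the hit check, which is how pruning can never change the hit
set — only the amount of work.

The faster variant chooses the visiting order $\pi$ before scanning:
positions are sorted by decreasing matching-failure expectation
$E_i = |\min_a M(i,a)| + \max_a M(i,a) - \sum_a q_a M(i,a)$ (computed on
real scores; ties broken by ascending position so runs are
deterministic). $E_i$ is large where the column has a wide score range
and a low background-expected score — exactly the positions where a
random window loses the most margin per lookup. The absolute value on
the minimum is applied literally even for all-positive columns (where a
constant column $c \ge 0$ gives $E = c$); no natural counterexample
dictates otherwise.

Windows containing non-ACGT symbols are skipped and counted, not scored
with a penalty: the score model is defined over the four-letter alphabet
only. Reverse-strand scanning (opt-in) scores the reverse-complement
matrix on the forward sequence, computes that matrix's own threshold at
the same $p$ (the two distributions differ under a non-palindromic
background), and reports hits on forward coordinates with strand `-`.

## The synthetic data generators

The generators define the benchmark conditions rather than approximating
any particular genome.

**Background sequences** are i.i.d. draws from a specified background,
uniform by default — the regime in which the p-value machinery is exact.
The test suite checks that a 1 Mb draw recovers its generating
distribution to within 0.01 in max-norm and passes a chi-square
goodness-of-fit test at $\alpha = 0.001$.

**IC-targeted matrices.** Benchmarking needs motif models whose total
information content (relative entropy against the background, in bits;
at most 2 bits per position under a uniform background) is controlled.
Each position is drawn from a symmetric Dirichlet ($\alpha = 1$), and a
single per-matrix sharpening exponent $\beta$ (position probabilities
$\propto p^\beta$, renormalised, evaluated in log space) is found by
bisection until the total IC hits the target within 0.1 bits; total IC
is continuous and monotone in $\beta$, so bisection between $\beta = 0$
(zero IC) and a doubling upper bracket converges in well under the
100-iteration cap. Positions are floored by mixing with
$\varepsilon = 5 \times 10^{-5}$ uniform, keeping log-odds magnitudes
below $\sim$8.6 nats so the DP grid stays small; the ceiling cost is
$\approx 0.004$ bits per position, still inside the 0.1-bit tolerance at
width 22. Two standard sweeps are packaged: fixed width 22 with integer
IC targets 5–30 (conservation sweep), and widths 5–30 at 70% of maximal
IC (width sweep).

What passing tests on these inputs do **not** show: real promoters have
dinucleotide structure, repeats, and composition drift, all of which
violate the i.i.d. assumption behind the p-value (the hit *set* is still
exact for whatever threshold is used — only its probabilistic
interpretation degrades); and the Dirichlet-plus-sharpening family is
one convenient distribution over matrices of a given IC, not a claim
about how real motifs of that IC look.

## Benchmark design

Engine cost is reported as matrix-cell lookups per scanned window, a
machine-independent quantity; wall-clock time is printed for information
but never asserted. Sweep comparisons use common random numbers:
replicate $r$ shares its matrix seed across all sweep cells, so the same
base Dirichlet draws are sharpened to each IC target and cell contrasts
are paired. Between-matrix variance in lookup cost is large compared to
adjacent-cell differences (the IC 5 → 15 contrast for plain lookahead
scoring is ~0.02 lookups/window), so unpaired designs at 100 replicates
measure mostly matrix-sampling noise.

Problem sizes in the shipped test suite — 10 kb sequences and 200
instances for the exactness sweep, 100 kb and 100 matrices per IC level
for the pruning-trend check, exhaustive $4^n$ enumeration up to width 8
for the threshold oracle — were chosen as the smallest sizes at which
the measured quantities are stable and the enumerated oracles remain
exact.

## Limitations

* DNA only: the formulas generalise to other alphabets, but formats,
  defaults, and the alphabet size are fixed at 4.
* Zeroth-order background only; no Markov background models and no
  analytic tail approximations.
* The p-value calibration is exact for the i.i.d. model, conservative in
  the sense of `p_achieved <= p`, and only approximate on real genomes.
* Single-threaded scanning; the engines are embarrassingly parallel over
  records, but no threading contract is offered.
* The expectation-permuted order is a heuristic: it minimises expected
  scan depth on background, and adds a small constant per-window
  overhead that can outweigh its benefit for very short motifs.
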