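Package: flscan
Title: Fast Position Weight Matrix Scanning with Lookahead Pruning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scans DNA sequences for candidate transcription factor binding
    sites with a position weight matrix (PWM). Implements three exact
    scanning engines: a naive full-scoring scan, lookahead scoring with
    precomputed intermediate score thresholds, and a faster lookahead
    variant that visits matrix columns in decreasing order of a
    matching-failure expectation derived from the background distribution.
    Significance thresholds are obtained from a user-supplied p-value via a
    pseudopolynomial dynamic program over the discretized score
    distribution. Includes JASPAR-style matrix and FASTA readers, motif
    information content, synthetic background-sequence and
    fixed-information-content matrix generators, a hardware-independent
    benchmark harness based on column-lookup counts, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    optparse,
    yaml,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
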