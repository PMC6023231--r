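#' Packaged GATA-3 example matrix
#'
#' A ready-made log-odds position weight matrix for the GATA-3
#' transcription factor (width 6), shipped together with the non-uniform
#' background distribution it was derived against (A 0.278, C 0.312,
#' G 0.212, T 0.198). The matrix is stored as printed log-odds scores;
#' the underlying count matrix is not distributed, so the scores are used
#' verbatim rather than regenerated.
#'
#' @return A list with `matrix` (a scoring matrix, natural-log scores,
#'   scale 3) and `background` (a [background()]).
#' @examples
#' ex <- gata3_example()
#' score_kmer(ex$matrix, "AGATAG")  # 5.69
#' @export
gata3_example <- function() {
  dir <- system.file("extdata", package = "flscan")
  scores <- as.matrix(utils::read.table(
    file.path(dir, "gata3_logodds.tsv"), sep = "\t"))
  bg <- read_background(file.path(dir, "gata3_background.txt"))
  list(matrix = scoring_matrix(t(scores), scale_digits = 3L,
                               base = "natural", name = "GATA3"),
       background = bg)
}
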