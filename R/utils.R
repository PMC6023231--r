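# Internal helpers shared across modules.

# Round half away from zero, the convention used for score discretization.
round_half_out <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. seed = NULL evaluates as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Normalise sequence input (character vector, single string, or a
# Biostrings XStringSet) to a named character vector of records.
as_records <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- x
  } else {
    stop("sequences must be a character vector or a DNAStringSet")
  }
  if (length(out) == 0L) stop("empty record set")
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    nm <- names(out)
    if (is.null(nm)) nm <- rep("", length(out))
    nm[!nzchar(nm)] <- paste0("seq", seq_along(out))[!nzchar(nm)]
    names(out) <- nm
  }
  out
}
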