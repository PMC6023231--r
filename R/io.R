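#' Read a JASPAR-style motif matrix
#'
#' Accepts the bracketed JASPAR PFM dialect
#' (`A [ 4 19 0 ... ]`), the bare whitespace dialect (`A 4 19 0 ...`), and
#' unlabeled 4-row numeric text (rows taken in A, C, G, T order). An
#' optional leading `>` header supplies the motif name.
#'
#' @param path Path to the motif file.
#' @param as One of `"counts"` (default, a [count_matrix()]) or
#'   `"probabilities"` (a [probability_matrix()], for files that store
#'   per-position probabilities).
#' @return A motif matrix object; the motif name, if present, is in
#'   `attr(x, "name")`.
#' @export
read_jaspar <- function(path, as = c("counts", "probabilities")) {
  as <- match.arg(as)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  name <- NULL
  if (length(lines) && startsWith(lines[1L], ">")) {
    name <- trimws(sub("^>\\s*", "", lines[1L]))
    name <- strsplit(name, "\\s+")[[1L]][1L]
    lines <- lines[-1L]
  }
  if (length(lines) < 4L) stop("motif file must contain 4 base rows: ", path)
  lines <- lines[seq_len(4L)]
  labels <- toupper(substr(lines, 1L, 1L))
  rows <- vector("list", 4L)
  row_base <- character(4L)
  for (i in seq_len(4L)) {
    body <- lines[i]
    if (labels[i] %in% DNA_BASES) {
      row_base[i] <- labels[i]
      body <- sub("^[ACGTacgt][:]?", "", body)
    } else {
      row_base[i] <- DNA_BASES[i]
    }
    body <- gsub("[][]", " ", body)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1L]]))
    if (anyNA(vals) || !length(vals)) {
      stop("cannot parse motif row ", i, " in ", path)
    }
    rows[[i]] <- vals
  }
  if (length(unique(lengths(rows))) != 1L) {
    stop("motif rows have unequal lengths in ", path)
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- row_base
  if (!setequal(row_base, DNA_BASES)) {
    stop("motif rows must cover A, C, G, T in ", path)
  }
  mat <- mat[DNA_BASES, , drop = FALSE]
  if (as == "counts") count_matrix(t(mat), name = name)
  else probability_matrix(t(mat), name = name)
}

#' @rdname read_jaspar
#' @param x A count or probability matrix to write.
#' @param dialect `"bracket"` for `A [ ... ]` rows or `"bare"` for plain
#'   whitespace rows.
#' @export
write_jaspar <- function(x, path, dialect = c("bracket", "bare")) {
  dialect <- match.arg(dialect)
  mat <- t(unclass(as.matrix(x)))  # 4 x width, rows A,C,G,T
  nm <- attr(x, "name")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(nm)) writeLines(paste0(">", nm), con)
  for (i in seq_len(4L)) {
    # 15 significant digits so probability matrices round-trip exactly
    vals <- paste(format(mat[i, ], trim = TRUE, digits = 15),
                  collapse = " ")
    if (dialect == "bracket") {
      writeLines(paste0(DNA_BASES[i], " [ ", vals, " ]"), con)
    } else {
      writeLines(paste(DNA_BASES[i], vals), con)
    }
  }
  invisible(path)
}

#' Read or write a plain 4 x width motif TSV
#'
#' Tab-separated numeric text with 4 rows in A, C, G, T order and one
#' column per motif position, no labels.
#'
#' @param path File path.
#' @param as `"counts"` or `"probabilities"`.
#' @return [read_matrix_tsv()] returns a motif matrix object.
#' @export
read_matrix_tsv <- function(path, as = c("counts", "probabilities")) {
  as <- match.arg(as)
  mat <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
  if (nrow(mat) != 4L) stop("motif TSV must have exactly 4 rows")
  if (as == "counts") count_matrix(t(mat)) else probability_matrix(t(mat))
}

#' @rdname read_matrix_tsv
#' @param x A count or probability matrix.
#' @export
write_matrix_tsv <- function(x, path) {
  mat <- t(unclass(as.matrix(x)))
  utils::write.table(mat, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read sequences
#'
#' `read_fasta()` reads a multi-record FASTA file (records are scanned
#' independently downstream). `read_sequence_txt()` reads raw sequence
#' text: all lines concatenated, whitespace stripped, one record.
#'
#' @param path File path.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path) {
  as_records(Biostrings::readDNAStringSet(path))
}

#' @rdname read_fasta
#' @export
read_sequence_txt <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  txt <- gsub("\\s+", "", txt)
  if (!nzchar(txt)) stop("empty sequence file: ", path)
  setNames(txt, basename(path))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(as_records(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Detect and read a sequence input: FASTA if the first non-blank character
# is '>', raw text otherwise.
read_sequences_auto <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && startsWith(trimws(first), ">")) {
    read_fasta(path)
  } else {
    read_sequence_txt(path)
  }
}

#' Read or write a background distribution file
#'
#' Four whitespace-separated probabilities in A, C, G, T order.
#'
#' @param path File path.
#' @return A [background()].
#' @export
read_background <- function(path) {
  vals <- scan(path, what = numeric(), quiet = TRUE)
  if (length(vals) != 4L) stop("background file must hold 4 numbers")
  background(setNames(vals, DNA_BASES))
}

#' @rdname read_background
#' @param bg A [background()].
#' @export
write_background <- function(bg, path) {
  stopifnot(inherits(bg, "background"))
  writeLines(paste(format(unclass(bg), trim = TRUE), collapse = " "), path)
  invisible(path)
}

# Parse a background given on the command line: "estimate", a path, or
# four comma/space separated numbers. Returns NULL for "estimate".
parse_background_arg <- function(arg) {
  if (is.null(arg) || identical(arg, "estimate")) return(NULL)
  if (file.exists(arg)) return(read_background(arg))
  vals <- suppressWarnings(as.numeric(strsplit(arg, "[,\\s]+")[[1L]]))
  if (length(vals) == 4L && !anyNA(vals)) {
    return(background(setNames(vals, DNA_BASES)))
  }
  stop("cannot interpret background '", arg,
       "': not a file, 'estimate', or 4 probabilities")
}

# Read a motif file by extension/content: .tsv -> plain TSV, otherwise
# JASPAR dialects.
read_motif_auto <- function(path, as = "counts") {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    first <- readLines(path, n = 1L, warn = FALSE)
    if (!grepl("^[>ACGTacgt]", trimws(first))) {
      return(read_matrix_tsv(path, as = as))
    }
  }
  read_jaspar(path, as = as)
}
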