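# Substitution matrices: NCBI-format parsing and the bundled BLOSUM62.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
# residue alphabet accepted in sequences: the 20 amino acids plus unknown
AA_ALPHABET <- c(AA20, "X")
GAP <- "-"

#' Read a substitution matrix in NCBI format
#'
#' Parses the plain-text matrix format used by NCBI BLAST (and EMBOSS): `#`
#' comment lines, a header row of residue letters, then one row per residue.
#'
#' @param path Path to an NCBI-format matrix file.
#' @return A symmetric numeric matrix with residue letters as dimnames.
#' @examples
#' S <- read_score_matrix(system.file("extdata", "BLOSUM62.txt",
#'                                    package = "adaptmsa"))
#' S["W", "W"]
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a valid NCBI-format matrix file: ", path)
  letters <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  n <- length(letters)
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  if (length(rows) != n)
    stop("matrix file has ", length(rows), " rows for ", n, " columns")
  m <- matrix(NA_real_, n, n, dimnames = list(letters, letters))
  for (r in rows) {
    if (length(r) != n + 1L)
      stop("malformed matrix row: ", paste(r, collapse = " "))
    m[r[[1L]], ] <- as.numeric(r[-1L])
  }
  if (anyNA(m)) stop("matrix file has missing entries")
  if (!isTRUE(all.equal(m, t(m))))
    stop("substitution matrix is not symmetric")
  m
}

.matrix_cache <- new.env(parent = emptyenv())

#' The bundled BLOSUM62 substitution matrix
#'
#' @return The BLOSUM62 matrix (half-bit scores) including ambiguity codes.
#' @export
blosum62 <- function() {
  if (is.null(.matrix_cache$blosum62)) {
    .matrix_cache$blosum62 <- read_score_matrix(
      system.file("extdata", "BLOSUM62.txt", package = "adaptmsa"))
  }
  .matrix_cache$blosum62
}

#' Alignment scoring parameters
#'
#' Bundles the substitution matrix and affine gap penalties used by the
#' pairwise and profile aligners.  A gap of length k costs
#' `gap_open + (k - 1) * gap_extend`.  Defaults are the classical EMBOSS
#' protein settings: BLOSUM62, open 10, extend 1.
#'
#' @param matrix Symmetric substitution matrix with residue-letter dimnames;
#'   must cover the 20 amino acids and X.
#' @param gap_open Positive gap-opening penalty.
#' @param gap_extend Positive gap-extension penalty, at most `gap_open`.
#' @param mode `"global"` (Needleman-Wunsch) or `"local"` (Smith-Waterman).
#' @return An object of class `align_params`.
#' @export
align_params <- function(matrix = blosum62(), gap_open = 10, gap_extend = 1,
                         mode = c("global", "local")) {
  mode <- match.arg(mode)
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix) ||
      is.null(rownames(matrix)))
    stop("matrix must be square with residue-letter dimnames")
  if (!all(AA_ALPHABET %in% rownames(matrix)))
    stop("matrix must cover the 20 amino acids and X")
  if (!isTRUE(all.equal(unname(matrix), unname(t(matrix)))))
    stop("substitution matrix must be symmetric")
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be positive")
  if (gap_extend > gap_open) stop("gap_extend must not exceed gap_open")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, mode = mode),
            class = "align_params")
}

#' @export
print.align_params <- function(x, ...) {
  cat("Alignment parameters: mode =", x$mode,
      "| gap open", x$gap_open, "| gap extend", x$gap_extend, "\n")
  invisible(x)
}
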