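# Optimal pairwise alignment (global and local, affine gaps) and the
# percent-identity statistic PID = N_identity / L_alignment.

.as_residues <- function(x, what = "sequence") {
  if (is.character(x) && length(x) == 1L) {
    if (!nzchar(x)) stop("empty ", what)
    chars <- strsplit(x, "", fixed = TRUE)[[1L]]
    bad <- !(chars %in% AA_ALPHABET)
    if (any(bad))
      stop("illegal residue character '", chars[which(bad)[[1L]]],
           "' at position ", which(bad)[[1L]])
    return(chars)
  }
  stop(what, " must be a single character string of residues")
}

.pairwise_result <- function(chars_a, chars_b, path, score, mode) {
  row_a <- ifelse(path$path_a == 0L, GAP, chars_a[pmax(path$path_a, 1L)])
  row_b <- ifelse(path$path_b == 0L, GAP, chars_b[pmax(path$path_b, 1L)])
  ident <- sum(row_a == row_b & row_a != GAP & row_a != "X")
  structure(list(row_a = paste(row_a, collapse = ""),
                 row_b = paste(row_b, collapse = ""),
                 n_identity = as.integer(ident),
                 l_alignment = length(row_a),
                 score = score, mode = mode),
            class = "pairwise_alignment")
}

.align_pair <- function(a, b, params, local) {
  chars_a <- .as_residues(a, "sequence a")
  chars_b <- .as_residues(b, "sequence b")
  S <- params$matrix
  M <- S[chars_a, chars_b, drop = FALSE]
  res <- .affine_dp(M, params$gap_open, params$gap_extend, local)
  .pairwise_result(chars_a, chars_b, res, res$score,
                   if (local) "local" else "global")
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Finds the maximum-scoring global alignment of two protein sequences under
#' affine-gap scoring (a gap of length k costs open + (k-1) * extend).  The
#' traceback is deterministic: ties prefer a match/mismatch column, then a
#' gap in `b`, then a gap in `a`.
#'
#' @param a,b Residue strings (no gaps).
#' @param params An [align_params()] object.
#' @return A `pairwise_alignment`: gapped rows `row_a`/`row_b`, the identity
#'   count `n_identity` (columns with identical non-gap, non-X residues),
#'   `l_alignment` (column count) and `score`.
#' @examples
#' aln <- global_align("HEAGAWGHEE", "PAWHEAE")
#' percent_identity(aln)
#' @export
global_align <- function(a, b, params = align_params()) {
  .align_pair(a, b, params, local = FALSE)
}

#' Local pairwise alignment (Smith-Waterman, affine gaps)
#'
#' Maximum-scoring alignment of a contiguous segment of `a` against a
#' contiguous segment of `b`; the score is never negative.  When no segment
#' pair scores positively, the degenerate empty alignment (length 0, score 0)
#' is returned.
#'
#' @inheritParams global_align
#' @return A `pairwise_alignment`; see [global_align()].
#' @export
local_align <- function(a, b, params = align_params()) {
  .align_pair(a, b, params, local = TRUE)
}

#' Percent identity of a pairwise alignment
#'
#' PID = N_identity / L_alignment: the number of identical residue pairs in
#' the optimal pairwise alignment divided by the alignment length (gap
#' columns included in the denominator).  Unknown residues (X) never count
#' as identities.  The degenerate empty local alignment has PID 0.
#'
#' @param aln A `pairwise_alignment` from [global_align()] or [local_align()].
#' @return A fraction in \[0, 1\].
#' @export
percent_identity <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  if (aln$l_alignment == 0L) return(0)
  aln$n_identity / aln$l_alignment
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("%s alignment: score %g, identity %d/%d (%.1f%%)\n",
              x$mode, x$score, x$n_identity, x$l_alignment,
              if (x$l_alignment) 100 * x$n_identity / x$l_alignment else 0))
  if (x$l_alignment) cat(" ", x$row_a, "\n ", x$row_b, "\n")
  invisible(x)
}
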