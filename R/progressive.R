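# Progressive alignment: per-column frequency profiles, profile-profile
# alignment by affine-gap DP on expected substitution scores, and the
# post-order merge driven by a guide tree.

PROFILE_LETTERS <- c(AA20, "X")  # frequency rows; gap frequency is the last row

#' Build an alignment profile
#'
#' A profile is a set of aligned rows summarized by per-column residue
#' frequencies over the 20 amino acids, X, and the gap character; each
#' column's frequencies sum to 1.
#'
#' @param x Named character vector of sequences (treated as single-row
#'   profiles stacked into an alignment of equal length) or an `msa` object /
#'   named vector of equal-length gapped rows.
#' @return A `profile`: list with `rows` (gapped strings), `freq`
#'   (22 x L matrix: 21 residue rows plus gap) and `length`.
#' @export
build_profile <- function(x) {
  rows <- unclass(x)
  if (!is.character(rows) || is.null(names(rows)))
    stop("profile rows must be a named character vector")
  if (length(unique(nchar(rows))) != 1L)
    stop("profile rows must have equal length")
  chars <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  L <- ncol(chars)
  lev <- c(PROFILE_LETTERS, GAP)
  freq <- matrix(0, length(lev), L, dimnames = list(lev, NULL))
  for (l in lev) freq[l, ] <- colMeans(chars == l)
  structure(list(rows = rows, freq = freq, length = L), class = "profile")
}

#' Align two profiles
#'
#' Global affine-gap dynamic programming over profile columns.  The score
#' for matching column i of `p1` against column j of `p2` is the expected
#' substitution score: the frequency-weighted sum of matrix scores over
#' residue pairs (gap frequencies contribute nothing to the match score;
#' gap columns inserted by the DP pay the affine penalties).  The merged
#' profile contains all rows of both inputs; stripping gaps from any row
#' recovers its original residues.
#'
#' @param p1,p2 `profile` objects.
#' @param params An [align_params()] object (global mode is always used).
#' @return The merged `profile`, with attribute `score`.
#' @export
profile_align <- function(p1, p2, params = align_params()) {
  stopifnot(inherits(p1, "profile"), inherits(p2, "profile"))
  S <- params$matrix[PROFILE_LETTERS, PROFILE_LETTERS]
  f1 <- p1$freq[PROFILE_LETTERS, , drop = FALSE]
  f2 <- p2$freq[PROFILE_LETTERS, , drop = FALSE]
  M <- crossprod(f1, S %*% f2)  # M[i, j] = sum_rs f1[r,i] S[r,s] f2[s,j]
  res <- .affine_dp(M, params$gap_open, params$gap_extend, FALSE)
  rows1 <- .thread_rows(p1$rows, res$path_a)
  rows2 <- .thread_rows(p2$rows, res$path_b)
  out <- build_profile(c(rows1, rows2))
  attr(out, "score") <- res$score
  out
}

# project each gapped row through a DP path (0 = new gap column)
.thread_rows <- function(rows, path) {
  mats <- strsplit(rows, "", fixed = TRUE)
  out <- vapply(mats, function(ch) {
    col <- ifelse(path == 0L, GAP, ch[pmax(path, 1L)])
    paste(col, collapse = "")
  }, character(1L))
  names(out) <- names(rows)
  out
}

#' Progressive multiple sequence alignment
#'
#' Aligns sequences by successive profile merges in post-order over the
#' guide tree, so that the most related sequences (deepest cherries) are
#' aligned first.  Columns that become all-gap during merging are removed in
#' a final sweep; output rows follow the input order.
#'
#' @param seqs Named character vector of residue strings.
#' @param tree A rooted guide tree ([ape::phylo]) whose leaf labels equal
#'   `names(seqs)`.  Multifurcating trees are binarized first.
#' @param params An [align_params()] object for the profile merges.
#' @return An `msa` object.
#' @export
progressive_align <- function(seqs, tree, params = align_params()) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (is.null(names(seqs))) stop("sequences must be named")
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (!setequal(tree$tip.label, names(seqs)) ||
      length(tree$tip.label) != length(seqs))
    stop("guide-tree leaves do not match the sequence ids")
  if (!ape::is.binary(tree)) tree <- .binarize(tree)
  ntip <- length(tree$tip.label)

  merge_node <- function(node) {
    if (node <= ntip) {
      id <- tree$tip.label[[node]]
      return(build_profile(setNames(seqs[[id]], id)))
    }
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    profile_align(merge_node(kids[[1L]]), merge_node(kids[[2L]]), params)
  }
  prof <- merge_node(ntip + 1L)
  rows <- prof$rows[names(seqs)]
  # drop columns that are gaps in every row
  chars <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  keep <- colSums(chars != GAP) > 0L
  rows <- apply(chars[, keep, drop = FALSE], 1L, paste, collapse = "")
  msa(setNames(rows, names(seqs)))
}
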