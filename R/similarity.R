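# All-pairs percent-identity matrix, average PID, and the three similarity
# regimes of the adaptive scheme.

#' All-pairs percent-identity matrix
#'
#' Computes PID for every unordered pair of sequences from their optimal
#' pairwise alignments under `params` (global or local mode).
#'
#' @param seqs Named character vector of at least two residue strings.
#' @param params An [align_params()] object; its `mode` selects global or
#'   local optimal alignment.
#' @return Symmetric n x n matrix of fractions with unit diagonal and the
#'   sequence ids as dimnames.
#' @export
pid_matrix <- function(seqs, params = align_params()) {
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  local <- identical(params$mode, "local")
  m <- diag(1, n)
  dimnames(m) <- list(names(seqs), names(seqs))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      aln <- .align_pair(seqs[[i]], seqs[[j]], params, local)
      m[i, j] <- m[j, i] <- percent_identity(aln)
    }
  }
  m
}

#' Average percent identity of a family
#'
#' The unweighted mean of the PIDs over every unordered pair of sequences
#' (the strict upper triangle of the PID matrix).
#'
#' @param pid A symmetric PID matrix as produced by [pid_matrix()].
#' @return A fraction in \[0, 1\].
#' @export
average_pid <- function(pid) {
  stopifnot(is.matrix(pid), nrow(pid) == ncol(pid), nrow(pid) >= 2L)
  mean(pid[upper.tri(pid)])
}

#' Classify a family into the three similarity regimes
#'
#' Families with average PID strictly above 40% are HIGH (very similar,
#' aligned globally); between 25% and 40% inclusive, MODERATE (aligned
#' locally); strictly below 25%, LOW (twilight zone, global/local consensus).
#'
#' @param avg_pid Average PID as a fraction in \[0, 1\].
#' @return One of `"HIGH"`, `"MODERATE"`, `"LOW"`.
#' @export
classify_similarity <- function(avg_pid) {
  if (!is.numeric(avg_pid) || length(avg_pid) != 1L || is.na(avg_pid) ||
      avg_pid < 0 || avg_pid > 1)
    stop("avg_pid must be a single fraction in [0, 1]")
  if (avg_pid > 0.40) "HIGH"
  else if (avg_pid >= 0.25) "MODERATE"
  else "LOW"
}

#' Similarity profile of a sequence family
#'
#' One pass over all pairs with global optimal alignment yields the PID
#' matrix, its average, and the similarity class used by the adaptive
#' guide-tree scheme.
#'
#' @param seqs Named character vector of at least two residue strings.
#' @param params An [align_params()] object (mode forced to global for the
#'   classification pass).
#' @return A `similarity_profile`: list with `n`, `pid`, `avg_pid`, `klass`,
#'   `mode_used`.
#' @export
similarity_profile <- function(seqs, params = align_params()) {
  params$mode <- "global"
  pid <- pid_matrix(seqs, params)
  avg <- average_pid(pid)
  structure(list(n = length(seqs), pid = pid, avg_pid = avg,
                 klass = classify_similarity(avg), mode_used = "global"),
            class = "similarity_profile")
}

#' @export
print.similarity_profile <- function(x, ...) {
  cat(sprintf("Similarity profile: %d sequences, average PID %.1f%% -> %s\n",
              x$n, 100 * x$avg_pid, x$klass))
  invisible(x)
}
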