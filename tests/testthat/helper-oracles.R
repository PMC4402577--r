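# Independent oracles used across the suite.  These deliberately take
# different computational routes from the package implementation:
#  - enumeration oracles recurse over alignments / clusterings explicitly;
#  - the general-gap DP oracle uses the O(nm(n+m)) Waterman-Smith-Beyer
#    formulation (explicit max over gap lengths) instead of Gotoh states;
#  - SP/TC oracles enumerate residue pairs / columns as string keys.

gap_cost <- function(k, go, ge) ifelse(k <= 0, 0, go + (k - 1) * ge)

# exhaustive enumeration over all global alignments (tiny inputs only)
oracle_enum_global <- function(a, b, S = adaptmsa::blosum62(),
                               go = 10, ge = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  best <- -Inf
  rec <- function(i, j, last, sc) {
    if (i == n && j == m) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1L, j + 1L, 0L, sc + S[A[i + 1L], B[j + 1L]])
    if (i < n) rec(i + 1L, j, 1L, sc - if (last == 1L) ge else go)
    if (j < m) rec(i, j + 1L, 2L, sc - if (last == 2L) ge else go)
  }
  rec(0L, 0L, -1L, 0)
  best
}

# general-gap-penalty DP, global mode
oracle_dp_global <- function(a, b, S = adaptmsa::blosum62(),
                             go = 10, ge = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  H <- matrix(-Inf, n + 1L, m + 1L)
  H[1L, ] <- -gap_cost(0:m, go, ge)
  H[, 1L] <- -gap_cost(0:n, go, ge)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cand <- H[i, j] + S[A[[i]], B[[j]]]
      cand <- max(cand, max(H[seq_len(i), j + 1L] -
                              gap_cost(i:1, go, ge)))
      cand <- max(cand, max(H[i + 1L, seq_len(j)] -
                              gap_cost(j:1, go, ge)))
      H[i + 1L, j + 1L] <- cand
    }
  }
  H[n + 1L, m + 1L]
}

# general-gap-penalty DP, local mode (score of best segment pair, >= 0)
oracle_dp_local <- function(a, b, S = adaptmsa::blosum62(),
                            go = 10, ge = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  H <- matrix(0, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cand <- H[i, j] + S[A[[i]], B[[j]]]
      cand <- max(cand, max(H[seq_len(i), j + 1L] - gap_cost(i:1, go, ge)))
      cand <- max(cand, max(H[i + 1L, seq_len(j)] - gap_cost(j:1, go, ge)))
      H[i + 1L, j + 1L] <- max(0, cand)
      best <- max(best, H[i + 1L, j + 1L])
    }
  }
  best
}

# brute-force average-linkage clustering: recompute every inter-cluster
# average from the ORIGINAL matrix over explicit member lists each step
oracle_upgma <- function(d, ids = rownames(d)) {
  n <- nrow(d)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  clusters <- lapply(seq_len(n), function(i)
    list(members = i, nwk = ids[[i]], height = 0))
  while (length(clusters) > 1L) {
    k <- length(clusters)
    bi <- bj <- 0L
    bd <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        dij <- mean(d[clusters[[i]]$members, clusters[[j]]$members])
        if (dij < bd) {
          bd <- dij
          bi <- i
          bj <- j
        }
      }
    }
    h <- bd / 2
    ci <- clusters[[bi]]
    cj <- clusters[[bj]]
    merged <- list(
      members = c(ci$members, cj$members),
      nwk = sprintf("(%s:%.12g,%s:%.12g)", ci$nwk, max(h - ci$height, 0),
                    cj$nwk, max(h - cj$height, 0)),
      height = h)
    clusters[[bi]] <- merged
    clusters[[bj]] <- NULL
  }
  ape::read.tree(text = paste0(clusters[[1L]]$nwk, ";"))
}

# SP/TC by explicit enumeration of residue-pair / column keys
oracle_sp_tc <- function(test, ref) {
  pair_keys <- function(aln) {
    chars <- do.call(rbind, strsplit(unclass(aln)[sort(names(aln))], "",
                                     fixed = TRUE))
    ids <- sort(names(aln))
    n <- nrow(chars)
    counts <- t(apply(chars != "-", 1L, cumsum))  # residue index per cell
    keys <- character(0L)
    for (col in seq_len(ncol(chars))) {
      present <- which(chars[, col] != "-")
      if (length(present) < 2L) next
      for (ii in seq_len(length(present) - 1L)) {
        for (jj in seq.int(ii + 1L, length(present))) {
          i <- present[[ii]]
          j <- present[[jj]]
          keys <- c(keys, paste(ids[[i]], counts[i, col],
                                ids[[j]], counts[j, col], sep = "/"))
        }
      }
    }
    keys
  }
  column_keys <- function(aln) {
    chars <- do.call(rbind, strsplit(unclass(aln)[sort(names(aln))], "",
                                     fixed = TRUE))
    ids <- sort(names(aln))
    counts <- t(apply(chars != "-", 1L, cumsum))
    keys <- character(0L)
    for (col in seq_len(ncol(chars))) {
      present <- which(chars[, col] != "-")
      if (length(present) < 2L) next
      keys <- c(keys, paste(ids[present], counts[cbind(present, col)],
                            sep = "/", collapse = "|"))
    }
    keys
  }
  ref_pairs <- pair_keys(ref)
  test_pairs <- pair_keys(test)
  sp <- if (!length(ref_pairs)) 100 else
    100 * sum(ref_pairs %in% test_pairs) / length(ref_pairs)
  ref_cols <- column_keys(ref)
  test_cols <- column_keys(test)
  # a ref column is reproduced when its full correspondence appears as a
  # subset of one test column's correspondence
  hit <- vapply(ref_cols, function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
    any(vapply(test_cols, function(tk) {
      all(parts %in% strsplit(tk, "|", fixed = TRUE)[[1L]])
    }, logical(1L)))
  }, logical(1L))
  tc <- if (!length(ref_cols)) 100 else 100 * sum(hit) / length(ref_cols)
  list(sp = sp, tc = tc)
}

# random residue strings / gapped alignments for property tests
random_seq <- function(len, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_gapping <- function(seqs, extra = 4L) {
  width <- max(nchar(seqs)) + extra
  rows <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1L]]
    pos <- sort(sample.int(width, length(ch)))
    row <- rep("-", width)
    row[pos] <- ch
    paste(row, collapse = "")
  }, character(1L))
  # drop all-gap columns so msa() is happy with minimal width
  chars <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  keep <- colSums(chars != "-") > 0L
  adaptmsa::msa(setNames(
    apply(chars[, keep, drop = FALSE], 1L, paste, collapse = ""),
    names(seqs)))
}
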