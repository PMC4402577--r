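# Guide-tree construction: class-dependent distance matrices, UPGMA,
# uniform random topologies, reference trees, and tree comparison.
# Trees are ape "phylo" objects throughout; guide trees are rooted binary.

.fmt_len <- function(x) sprintf("%.12g", max(x, 0))

#' Class-appropriate distance matrix for guide-tree building
#'
#' Converts percent identity into an evolutionary dissimilarity according to
#' the family's similarity regime: HIGH uses global-alignment PID
#' (d = 1 - PID_global), MODERATE uses local-alignment PID, and LOW uses the
#' consensus of the two estimates (d = 1 - (PID_global + PID_local) / 2).
#'
#' @param seqs Named character vector of at least two residue strings.
#' @param klass `"HIGH"`, `"MODERATE"` or `"LOW"` (see
#'   [classify_similarity()]).
#' @param params An [align_params()] object (gap penalties and matrix; the
#'   mode is set per class).
#' @param pid_global Optional precomputed global PID matrix (reused from the
#'   classification pass to avoid realigning).
#' @return Symmetric distance matrix with zero diagonal, entries in \[0, 1\].
#' @export
distances_for_class <- function(seqs, klass, params = align_params(),
                                pid_global = NULL) {
  klass <- match.arg(klass, c("HIGH", "MODERATE", "LOW"))
  need_global <- klass %in% c("HIGH", "LOW")
  need_local <- klass %in% c("MODERATE", "LOW")
  if (need_global && is.null(pid_global)) {
    params$mode <- "global"
    pid_global <- pid_matrix(seqs, params)
  }
  pid_local <- NULL
  if (need_local) {
    params$mode <- "local"
    pid_local <- pid_matrix(seqs, params)
  }
  pid <- switch(klass,
                HIGH = pid_global,
                MODERATE = pid_local,
                LOW = (pid_global + pid_local) / 2)
  d <- 1 - pid
  diag(d) <- 0
  d
}

#' UPGMA clustering of a distance matrix
#'
#' Average-linkage agglomerative clustering producing a rooted binary
#' ultrametric tree.  Node height is half the average-linkage merge
#' distance.  Ties are broken deterministically by the lowest (i, j) pair of
#' current cluster positions, scanning i then j; the merged cluster takes
#' position i.
#'
#' @param d Symmetric non-negative distance matrix with zero diagonal.
#' @param ids Leaf labels; defaults to `rownames(d)`.
#' @return A rooted binary ultrametric [ape::phylo] tree with branch lengths.
#' @export
upgma <- function(d, ids = rownames(d)) {
  if (!is.matrix(d) || nrow(d) != ncol(d) || nrow(d) < 2L)
    stop("d must be a square matrix with n >= 2")
  if (anyNA(d) || any(!is.finite(d))) stop("distance matrix has NaN/Inf entries")
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix is not symmetric")
  n <- nrow(d)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  if (length(ids) != n || anyDuplicated(ids)) stop("ids must be n unique labels")

  nw <- as.character(ids)   # newick fragment per active cluster
  height <- numeric(n)
  size <- rep(1L, n)
  active <- seq_len(n)
  dm <- d
  while (length(active) > 1L) {
    k <- length(active)
    # lowest (i, j) among minimal-distance pairs, scanning i then j
    bi <- bj <- 0L
    bd <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        dij <- dm[active[i], active[j]]
        if (dij < bd) { bd <- dij; bi <- i; bj <- j }
      }
    }
    ci <- active[bi]; cj <- active[bj]
    h <- bd / 2
    nw[ci] <- paste0("(", nw[ci], ":", .fmt_len(h - height[ci]), ",",
                     nw[cj], ":", .fmt_len(h - height[cj]), ")")
    # average-linkage update (size-weighted)
    others <- active[-c(bi, bj)]
    if (length(others)) {
      upd <- (size[ci] * dm[ci, others] + size[cj] * dm[cj, others]) /
        (size[ci] + size[cj])
      dm[ci, others] <- upd
      dm[others, ci] <- upd
    }
    height[ci] <- h
    size[ci] <- size[ci] + size[cj]
    active <- active[-bj]
  }
  ape::read.tree(text = paste0(nw[active], ";"))
}

#' Adaptive guide tree
#'
#' The adaptive scheme: estimate family similarity by the average global
#' percent identity, pick the distance estimate for the regime (global PID
#' above 40%, local PID between 25% and 40%, global/local consensus below
#' 25%), and cluster with UPGMA.
#'
#' @param seqs Named character vector of at least two residue strings.
#' @param params An [align_params()] object.
#' @return A rooted binary [ape::phylo] guide tree with attributes `klass`
#'   (similarity regime) and `avg_pid` (average global PID, fraction).
#' @export
adaptive_guide_tree <- function(seqs, params = align_params()) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  prof <- similarity_profile(seqs, params)
  d <- distances_for_class(seqs, prof$klass, params, pid_global = prof$pid)
  tree <- upgma(d, ids = names(seqs))
  attr(tree, "klass") <- prof$klass
  attr(tree, "avg_pid") <- prof$avg_pid
  tree
}

#' Uniform random guide tree
#'
#' Draws a rooted binary topology by random sequential coalescence:
#' repeatedly join a uniformly chosen pair of current lineages until one
#' remains.  For a fixed seed the result is bit-reproducible; over seeds the
#' law is uniform over labeled rooted binary topologies.  No branch lengths
#' (progressive alignment uses topology only).
#'
#' @param ids Character vector of at least two leaf labels.
#' @param seed Integer seed (required: the null model must be reproducible).
#' @return A rooted binary [ape::phylo] tree without branch lengths.
#' @export
random_tree <- function(ids, seed) {
  if (length(ids) < 2L) stop("need at least 2 leaf labels")
  if (anyDuplicated(ids)) stop("duplicate leaf labels")
  if (missing(seed)) stop("a seed is required")
  with_seed(seed, {
    nodes <- as.character(ids)
    while (length(nodes) > 1L) {
      pick <- sample.int(length(nodes), 2L)
      joined <- paste0("(", nodes[[pick[[1L]]]], ",", nodes[[pick[[2L]]]], ")")
      nodes <- c(nodes[-pick], joined)
    }
    ape::read.tree(text = paste0(nodes, ";"))
  })
}

# Recursively rebuild a (possibly multifurcating) phylo as a left-nested
# binary newick string; new internal edges get length 0 when lengths exist.
.binary_newick <- function(tree, node, use_len) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[[node]])
  rows <- which(tree$edge[, 1L] == node)
  kids <- tree$edge[rows, 2L]
  parts <- character(length(kids))
  for (i in seq_along(kids)) {
    s <- .binary_newick(tree, kids[[i]], use_len)
    if (use_len) s <- paste0(s, ":", .fmt_len(tree$edge.length[[rows[[i]]]]))
    parts[[i]] <- s
  }
  out <- parts[[1L]]
  for (i in seq_along(parts)[-1L]) {
    out <- paste0("(", out, ",", parts[[i]], ")")
    if (i < length(parts) && use_len) out <- paste0(out, ":0")
  }
  out
}

.binarize <- function(tree) {
  use_len <- !is.null(tree$edge.length)
  root <- length(tree$tip.label) + 1L
  ape::read.tree(text = paste0(.binary_newick(tree, root, use_len), ";"))
}

#' Load a reference phylogeny for use as a guide tree
#'
#' Reference trees (e.g. inferred from a trusted alignment) are consumed as
#' Newick.  Unrooted trees are rooted at the midpoint of the longest path;
#' multifurcations are binarized by deterministic left-nesting, e.g.
#' `((a,b,c),d)` becomes `(((a,b),c),d)`.
#'
#' @param tree A Newick file path or an [ape::phylo] tree.
#' @param ids Sequence ids the leaf set must match exactly.
#' @return A rooted binary [ape::phylo] guide tree.
#' @export
load_reference_tree <- function(tree, ids) {
  if (is.character(tree) && length(tree) == 1L) tree <- read_newick(tree)
  stopifnot(inherits(tree, "phylo"))
  missing_ <- setdiff(ids, tree$tip.label)
  extra <- setdiff(tree$tip.label, ids)
  if (length(missing_) || length(extra))
    stop("reference tree leaf set mismatch",
         if (length(missing_)) paste0("; missing: ",
                                      paste(missing_, collapse = ", ")),
         if (length(extra)) paste0("; extra: ",
                                   paste(extra, collapse = ", ")))
  if (!ape::is.rooted(tree)) {
    if (is.null(tree$edge.length))
      tree$edge.length <- rep(1, nrow(tree$edge))
    tree <- phangorn::midpoint(tree)
  }
  if (!ape::is.binary(tree)) tree <- .binarize(tree)
  tree
}

#' Neighbor-joining tree from a reference alignment
#'
#' A stand-in for a maximum-likelihood reference phylogeny: neighbor joining
#' on p-distances computed column-wise from the reference alignment
#' (columns gapped in either row are ignored), midpoint-rooted and
#' binarized.
#'
#' @param ref_msa An `msa` object with at least 3 rows.
#' @return A rooted binary [ape::phylo] guide tree.
#' @export
nj_reference_tree <- function(ref_msa) {
  stopifnot(inherits(ref_msa, "msa"))
  n <- length(ref_msa)
  if (n < 2L) stop("need at least 2 aligned rows")
  mat <- do.call(rbind, strsplit(unclass(ref_msa), "", fixed = TRUE))
  rownames(mat) <- names(ref_msa)
  d <- matrix(0, n, n, dimnames = list(names(ref_msa), names(ref_msa)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      both <- mat[i, ] != GAP & mat[j, ] != GAP
      if (!any(both))
        stop("rows '", names(ref_msa)[[i]], "' and '", names(ref_msa)[[j]],
             "' share no aligned residue columns; p-distance undefined")
      d[i, j] <- d[j, i] <- mean(mat[i, both] != mat[j, both])
    }
  }
  if (n == 2L)
    return(ape::read.tree(text = sprintf("(%s:%s,%s:%s);",
                                         names(ref_msa)[[1L]],
                                         .fmt_len(d[1L, 2L] / 2),
                                         names(ref_msa)[[2L]],
                                         .fmt_len(d[1L, 2L] / 2))))
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- phangorn::midpoint(tr)
  if (!ape::is.binary(tr)) tr <- .binarize(tr)
  tr
}

# descendant-tip sets per internal node, as canonical split keys
.split_keys <- function(tree, all_tips) {
  ntip <- length(tree$tip.label)
  n_all <- length(all_tips)
  keys <- character(0L)
  tipsets <- vector("list", ntip + tree$Nnode)
  # accumulate tip sets bottom-up over edges in postorder
  for (k in seq_len(ntip)) tipsets[[k]] <- tree$tip.label[[k]]
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    tipsets[[p]] <- c(tipsets[[p]], tipsets[[ch]])
  }
  root <- ntip + 1L
  anchor <- min(all_tips)
  for (node in seq.int(ntip + 1L, ntip + tree$Nnode)) {
    if (node == root) next
    side <- sort(tipsets[[node]])
    if (length(side) < 2L || length(side) > n_all - 2L) next  # trivial
    if (!(anchor %in% side)) side <- sort(setdiff(all_tips, side))
    keys <- c(keys, paste(side, collapse = "\r"))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two trees
#'
#' The number of non-trivial bipartitions (unrooted splits) present in
#' exactly one of the two trees.  Both trees must have the same leaf set.
#'
#' @param t1,t2 [ape::phylo] trees on the same leaves.
#' @return Non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label) ||
      length(t1$tip.label) != length(t2$tip.label))
    stop("trees have different leaf sets")
  all_tips <- sort(t1$tip.label)
  k1 <- .split_keys(t1, all_tips)
  k2 <- .split_keys(t2, all_tips)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}
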