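# Synthetic protein families: a Yule tree with exponential branch lengths,
# i.i.d. substitutions, and Poisson indels with geometric lengths, evolved
# while tracking residue homology so the true alignment is exact.

#' Parameters of the sequence-evolution simulator
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param root_length Root sequence length in residues.
#' @param branch_mean Mean of the exponential branch-length distribution
#'   (substitutions-per-site time units).
#' @param sub_prob Per-site substitution probability per unit branch length
#'   (capped at 1 per branch); replacements are drawn uniformly from the 20
#'   amino acids.
#' @param indel_rate Insertion rate and deletion rate, each per site per
#'   unit branch length (events are Poisson along each branch).
#' @param indel_p Geometric length parameter: indel length is
#'   1 + Geom(indel_p), mean 1/indel_p residues.
#' @return An `evolution_params` list.
#' @export
evolution_params <- function(n_taxa = 8L, root_length = 100L,
                             branch_mean = 0.2, sub_prob = 1.0,
                             indel_rate = 0.05, indel_p = 0.4) {
  stopifnot(n_taxa >= 2L, root_length >= 1L, branch_mean > 0,
            sub_prob >= 0, indel_rate >= 0, indel_p > 0, indel_p <= 1)
  structure(list(n_taxa = as.integer(n_taxa),
                 root_length = as.integer(root_length),
                 branch_mean = branch_mean, sub_prob = sub_prob,
                 indel_rate = indel_rate, indel_p = indel_p),
            class = "evolution_params")
}

#' Sample a random dated tree (Yule topology, exponential branch lengths)
#'
#' Topology is drawn by random sequential coalescence (repeatedly join a
#' uniformly chosen pair of lineages), which induces the Yule law on labeled
#' rooted topologies; every branch length is an independent Exponential
#' draw with mean `branch_mean`.
#'
#' @param n Number of leaves (>= 2); leaves are labeled `t1..tn`.
#' @param branch_mean Mean branch length.
#' @param seed Integer seed for reproducibility.
#' @return A rooted binary [ape::phylo] tree with branch lengths.
#' @export
sample_tree <- function(n, branch_mean = 0.2, seed = NULL) {
  if (n < 2L) stop("need at least 2 taxa")
  with_seed(seed, {
    nodes <- paste0("t", seq_len(n))
    while (length(nodes) > 1L) {
      pick <- sample.int(length(nodes), 2L)
      joined <- paste0("(", nodes[[pick[[1L]]]], ",", nodes[[pick[[2L]]]], ")")
      nodes <- c(nodes[-pick], joined)
    }
    tr <- ape::read.tree(text = paste0(nodes, ";"))
    tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / branch_mean)
    tr
  })
}

#' Evolve a synthetic protein family along a tree
#'
#' The root sequence is drawn uniformly over the 20 amino acids.  Along each
#' branch of length t: every site substitutes independently with probability
#' `min(1, sub_prob * t)`; insertion and deletion events are Poisson with
#' mean `indel_rate * t * L` each, with uniform positions and geometric
#' lengths.  Every residue carries a persistent homology id, so the true
#' multiple alignment of the leaves is recorded exactly.
#'
#' @param tree A rooted binary [ape::phylo] tree with branch lengths.
#' @param params An [evolution_params()] object.
#' @param seed Integer seed.
#' @param scale Multiplier applied to all branch lengths (used by
#'   [calibrate_divergence()]).
#' @param compute_pid Compute the realized average PID of the leaf
#'   sequences (global pairwise alignment); set `FALSE` to skip.
#' @return A `synthetic_family`: list with `true_tree`, `sequences` (named
#'   character vector), `true_msa` (`msa`), and `realized_avg_pid`.
#' @export
evolve_family <- function(tree, params = evolution_params(), seed = NULL,
                          scale = 1, compute_pid = TRUE) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length), scale > 0)
  ntip <- length(tree$tip.label)
  with_seed(seed, {
    env <- new.env(parent = emptyenv())
    env$columns <- seq_len(params$root_length)  # homology ids, MSA order
    env$next_id <- params$root_length
    root_seq <- list(ids = seq_len(params$root_length),
                     chars = sample(AA20, params$root_length, replace = TRUE))
    leaves <- vector("list", ntip)

    descend <- function(node, state) {
      if (node <= ntip) {
        leaves[[node]] <<- state
        return(invisible())
      }
      rows <- which(tree$edge[, 1L] == node)
      for (r in rows) {
        child <- tree$edge[r, 2L]
        t_br <- tree$edge.length[[r]] * scale
        descend(child, .evolve_branch(state, t_br, params, env))
      }
    }
    root_node <- ntip + 1L
    descend(root_node, root_seq)

    rows <- vapply(seq_len(ntip), function(i) {
      pos <- match(leaves[[i]]$ids, env$columns)
      stopifnot(!anyNA(pos), !is.unsorted(pos, strictly = TRUE))
      row <- rep(GAP, length(env$columns))
      row[pos] <- leaves[[i]]$chars
      paste(row, collapse = "")
    }, character(1L))
    names(rows) <- tree$tip.label
    # drop columns gapped in every surviving leaf
    chars <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    keep <- colSums(chars != GAP) > 0L
    rows <- apply(chars[, keep, drop = FALSE], 1L, paste, collapse = "")
    true_msa <- msa(setNames(rows, tree$tip.label))
    seqs <- ungap(true_msa)
    pid <- if (compute_pid && ntip >= 2L)
      average_pid(pid_matrix(seqs)) else NA_real_
    structure(list(true_tree = tree, sequences = seqs, true_msa = true_msa,
                   realized_avg_pid = pid),
              class = "synthetic_family")
  })
}

# evolve one lineage along a branch of length t; updates the global column
# order in `env` when insertions create new homology ids
.evolve_branch <- function(state, t, params, env) {
  ids <- state$ids
  chars <- state$chars
  L <- length(chars)
  # substitutions
  p_sub <- min(1, params$sub_prob * t)
  if (p_sub > 0 && L > 0L) {
    hit <- runif(L) < p_sub
    if (any(hit)) chars[hit] <- sample(AA20, sum(hit), replace = TRUE)
  }
  # deletions (never delete the entire sequence)
  n_del <- rpois(1L, params$indel_rate * t * L)
  for (k in seq_len(n_del)) {
    L <- length(chars)
    if (L <= 1L) break
    len <- 1L + rgeom(1L, params$indel_p)
    pos <- sample.int(L, 1L)
    drop <- pos:min(pos + len - 1L, L)
    if (length(drop) >= L) drop <- drop[-length(drop)]
    if (!length(drop)) next
    ids <- ids[-drop]
    chars <- chars[-drop]
  }
  # insertions
  n_ins <- rpois(1L, params$indel_rate * t * L)
  for (k in seq_len(n_ins)) {
    L <- length(chars)
    len <- 1L + rgeom(1L, params$indel_p)
    slot <- sample.int(L + 1L, 1L) - 1L  # insert after this many residues
    new_ids <- env$next_id + seq_len(len)
    env$next_id <- env$next_id + len
    new_chars <- sample(AA20, len, replace = TRUE)
    anchor_pos <- if (slot == 0L) match(ids[[1L]], env$columns) - 1L
                  else match(ids[[slot]], env$columns)
    env$columns <- append(env$columns, new_ids, after = anchor_pos)
    ids <- append(ids, new_ids, after = slot)
    chars <- append(chars, new_chars, after = slot)
  }
  list(ids = ids, chars = chars)
}

#' Calibrate divergence to a target average PID
#'
#' Finds a global branch-length scale such that the mean realized average
#' PID over `k` seeded replicate families is within `tol` of `target`.
#' Realized similarity decreases monotonically in the scale (checked
#' stochastically), so bisection applies.
#'
#' @param target Target average PID, a fraction in (0, 1).
#' @param params An [evolution_params()] object.
#' @param k Replicates averaged per evaluation.
#' @param tol Calibration tolerance on the mean realized PID.
#' @param bounds Search interval for the scale.
#' @param seed Integer seed; each evaluation reuses the same replicate seeds
#'   so the objective is a deterministic function of the scale.
#' @param max_iter Bisection iteration cap.
#' @return The branch-length scale factor.
#' @export
calibrate_divergence <- function(target, params = evolution_params(), k = 5L,
                                 tol = 0.03, bounds = c(1e-3, 30),
                                 seed = 1L, max_iter = 40L) {
  stopifnot(target > 0, target < 1)
  seeds <- derive_seeds(seed, 2L * k)
  tree_seeds <- seeds[seq_len(k)]
  evo_seeds <- seeds[k + seq_len(k)]
  f <- function(scale) {
    mean(vapply(seq_len(k), function(i) {
      tr <- sample_tree(params$n_taxa, params$branch_mean, tree_seeds[[i]])
      evolve_family(tr, params, seed = evo_seeds[[i]], scale = scale,
                    compute_pid = TRUE)$realized_avg_pid
    }, numeric(1L)))
  }
  lo <- bounds[[1L]]; hi <- bounds[[2L]]
  f_lo <- f(lo); f_hi <- f(hi)
  if (abs(f_lo - target) <= tol) return(lo)
  if (abs(f_hi - target) <= tol) return(hi)
  if (f_lo < target || f_hi > target)
    stop(sprintf("target PID %.3f unreachable in scale bounds [%g, %g] (PID range %.3f..%.3f)",
                 target, lo, hi, f_hi, f_lo))
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)  # bisect in log scale: divergence spans decades
    f_mid <- f(mid)
    if (abs(f_mid - target) <= tol) return(mid)
    if (f_mid > target) lo <- mid else hi <- mid
  }
  stop("calibration did not converge within ", max_iter, " iterations")
}

#' Simulate one synthetic family
#'
#' Convenience wrapper: sample a tree, optionally rescale it to hit a target
#' average PID (via a precomputed scale), and evolve sequences.
#'
#' @param params An [evolution_params()] object.
#' @param seed Integer seed (drives both tree and evolution stages).
#' @param scale Branch-length scale factor (e.g. from
#'   [calibrate_divergence()]).
#' @return A `synthetic_family`; see [evolve_family()].
#' @export
simulate_family <- function(params = evolution_params(), seed = NULL,
                            scale = 1) {
  seeds <- derive_seeds(if (is.null(seed)) sample.int(1e9, 1L) else seed, 2L)
  tr <- sample_tree(params$n_taxa, params$branch_mean, seeds[[1L]])
  evolve_family(tr, params, seed = seeds[[2L]], scale = scale)
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat(sprintf("Synthetic family: %d sequences, true MSA %d columns, realized avg PID %.3f\n",
              length(x$sequences), nchar(x$true_msa[[1L]]),
              x$realized_avg_pid))
  invisible(x)
}
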