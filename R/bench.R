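# Benchmark harness: compare guide-tree strategies on families with a known
# reference alignment, and summarize paired scores against the diagonal.

#' Compare guide-tree strategies on a set of families
#'
#' For every family and strategy: build the guide tree, run the progressive
#' aligner, and score the result against the family's reference alignment
#' (SP and TC).  When the true tree is known, the Robinson-Foulds distance
#' of the guide tree to it is also recorded.
#'
#' Strategies: `"adaptive"` (the PID scheme), `"random"` (uniform topology,
#' one seed per family), `"reference"` (the family's own true/reference tree),
#' `"nj-reference"` (neighbor joining on the reference alignment).
#'
#' @param families List of families; each is a `synthetic_family` or a list
#'   with `sequences`, a reference `msa` in `true_msa` (or `ref_msa`), and
#'   optionally `true_tree`.
#' @param strategies Character vector of strategies to run.
#' @param params An [align_params()] object for alignment.
#' @param seed Integer seed (drives the random strategy, one draw per family).
#' @return An `experiment_result`: list with `records` (one data-frame row
#'   per family x strategy: `family`, `strategy`, `avg_pid`, `sp`, `tc`,
#'   `rf`) and `summary` (per-strategy mean SP/TC).
#' @export
run_comparison <- function(families,
                           strategies = c("adaptive", "random"),
                           params = align_params(), seed = 1L) {
  strategies <- match.arg(strategies,
                          c("adaptive", "random", "reference", "nj-reference"),
                          several.ok = TRUE)
  if (!length(families)) stop("no families supplied")
  seeds <- derive_seeds(seed, length(families))
  recs <- list()
  for (fi in seq_along(families)) {
    fam <- families[[fi]]
    seqs <- fam$sequences
    ref <- if (!is.null(fam$true_msa)) fam$true_msa else fam$ref_msa
    if (is.null(ref)) stop("family ", fi, " has no reference alignment")
    if (is.null(seqs)) seqs <- ungap(ref)
    avg_pid <- fam$realized_avg_pid
    if (is.null(avg_pid) || is.na(avg_pid))
      avg_pid <- average_pid(pid_matrix(seqs, params))
    for (st in strategies) {
      tree <- switch(st,
        adaptive = adaptive_guide_tree(seqs, params),
        random = random_tree(names(seqs), seed = seeds[[fi]]),
        reference = {
          if (is.null(fam$true_tree)) stop("family ", fi, " has no true tree")
          load_reference_tree(fam$true_tree, names(seqs))
        },
        `nj-reference` = nj_reference_tree(ref))
      aln <- progressive_align(seqs, tree, params)
      rf <- if (!is.null(fam$true_tree))
        robinson_foulds(tree, fam$true_tree) else NA_integer_
      recs[[length(recs) + 1L]] <- data.frame(
        family = fi, strategy = st, avg_pid = 100 * avg_pid,
        sp = sp_score(aln, ref), tc = tc_score(aln, ref), rf = rf,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  summary <- aggregate(records[, c("sp", "tc")],
                       by = list(strategy = records$strategy), FUN = mean)
  structure(list(records = records, summary = summary),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment:", length(unique(x$records$family)), "families x",
      length(unique(x$records$strategy)), "strategies\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Diagonal summary of a paired strategy comparison
#'
#' For a scatter of (score under `strategy_x`, score under `strategy_y`),
#' counts families below, on, and above the diagonal for each metric: a
#' family is "below" when strategy_y scored lower than strategy_x.
#'
#' @param result An `experiment_result` from [run_comparison()].
#' @param strategy_x,strategy_y Strategy names present in `result`.
#' @return Data frame with one row per metric (`sp`, `tc`) and counts
#'   `below`, `on`, `above`.
#' @export
diagonal_summary <- function(result, strategy_x, strategy_y) {
  stopifnot(inherits(result, "experiment_result"))
  r <- result$records
  rx <- r[r$strategy == strategy_x, ]
  ry <- r[r$strategy == strategy_y, ]
  if (!nrow(rx) || !nrow(ry)) stop("strategy not present in result")
  if (!setequal(rx$family, ry$family))
    stop("strategies are not paired over the same families")
  ry <- ry[match(rx$family, ry$family), ]
  out <- lapply(c("sp", "tc"), function(metric) {
    x <- rx[[metric]]; y <- ry[[metric]]
    data.frame(metric = metric,
               below = sum(y < x), on = sum(y == x), above = sum(y > x))
  })
  do.call(rbind, out)
}
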