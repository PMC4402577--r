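# Alignment accuracy against a reference: sum-of-pairs (SP) and total-column
# (TC) scores, plus similarity-binned reporting of benchmark results.

# check ids match and gap-stripped rows are identical; return char matrices
.score_prep <- function(test, ref) {
  stopifnot(inherits(test, "msa"), inherits(ref, "msa"))
  if (!setequal(names(test), names(ref)) || length(test) != length(ref))
    stop("test and reference alignments have different sequence ids")
  test <- test[names(ref)]
  if (!identical(unname(ungap(test)), unname(ungap(ref))))
    stop("test and reference rows differ after gap removal")
  list(test = do.call(rbind, strsplit(unclass(test), "", fixed = TRUE)),
       ref = do.call(rbind, strsplit(unclass(ref), "", fixed = TRUE)))
}

# per-row map: residue index -> column index of the alignment matrix
.residue_cols <- function(chars) {
  lapply(seq_len(nrow(chars)), function(i) which(chars[i, ] != GAP))
}

#' Sum-of-pairs score
#'
#' The percentage of residue pairs aligned in the reference (residue i of one
#' row in the same column as residue j of another row) that the test
#' alignment also aligns.  Only residue-residue pairs count; gap columns do
#' not contribute.
#'
#' @param test,ref `msa` objects over the same sequences (identical rows
#'   after gap removal).
#' @return A percentage in \[0, 100\].
#' @export
sp_score <- function(test, ref) {
  m <- .score_prep(test, ref)
  rc_test <- .residue_cols(m$test)
  rc_ref <- .residue_cols(m$ref)
  n <- nrow(m$ref)
  total <- 0L
  matched <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      # residue index of row j aligned to residue k of row i (NA if gap)
      ref_pair <- .pair_by_column(rc_ref[[i]], rc_ref[[j]])
      test_pair <- .pair_by_column(rc_test[[i]], rc_test[[j]])
      has <- !is.na(ref_pair)
      total <- total + sum(has)
      matched <- matched + sum(has & !is.na(test_pair) &
                                 ref_pair == test_pair, na.rm = TRUE)
    }
  }
  if (total == 0L) return(100)
  100 * matched / total
}

# For rows i, j with residue->column maps ci, cj: for each residue k of row i,
# the residue index of row j occupying the same column (NA when gapped).
.pair_by_column <- function(ci, cj) {
  match(ci, cj)
}

#' Total-column score
#'
#' The percentage of reference columns containing at least two residues
#' whose complete residue correspondence is reproduced within a single test
#' column.
#'
#' @inheritParams sp_score
#' @return A percentage in \[0, 100\].
#' @export
tc_score <- function(test, ref) {
  m <- .score_prep(test, ref)
  n <- nrow(m$ref)
  # residue index per cell (NA for gaps)
  idx_of <- function(chars) {
    t(apply(chars != GAP, 1L, function(r) {
      out <- rep(NA_integer_, length(r))
      out[r] <- seq_len(sum(r))
      out
    }))
  }
  ref_idx <- idx_of(m$ref)
  test_idx <- idx_of(m$test)
  # for each row, column of the test alignment holding residue k
  test_col <- lapply(seq_len(n), function(i) which(m$test[i, ] != GAP))
  denom <- 0L
  hits <- 0L
  for (col in seq_len(ncol(m$ref))) {
    rows <- which(!is.na(ref_idx[, col]))
    if (length(rows) < 2L) next
    denom <- denom + 1L
    cols_in_test <- vapply(rows, function(i) test_col[[i]][ref_idx[i, col]],
                           integer(1L))
    if (length(unique(cols_in_test)) == 1L) hits <- hits + 1L
  }
  if (denom == 0L) return(100)
  100 * hits / denom
}

#' Similarity-binned accuracy report
#'
#' Aggregates per-family SP/TC scores into similarity bins in percent
#' identity.  Bins are left-closed and right-open except the last, which is
#' closed, so a family at exactly 20% falls in the "20%-40%" bin.  Preset
#' edges: `"oxbench"` = 0/20/40/70/100 and `"balibase"` (also SABmark-style)
#' = 0/30/60.
#'
#' @param records Data frame with columns `avg_pid` (percent, 0-100), `sp`
#'   and `tc` (percent).
#' @param edges Strictly increasing numeric bin edges in percent, or a
#'   preset name.
#' @return A `binned_report` data frame: one row per bin with `bin`,
#'   `mean_sp`, `mean_tc`, `n_families`.
#' @export
bin_report <- function(records, edges = "oxbench") {
  if (is.character(edges))
    edges <- switch(match.arg(edges, c("oxbench", "balibase", "sabmark")),
                    oxbench = c(0, 20, 40, 70, 100),
                    balibase = c(0, 30, 60),
                    sabmark = c(0, 30, 60))
  if (length(edges) < 2L || any(diff(edges) <= 0))
    stop("edges must be strictly increasing")
  stopifnot(is.data.frame(records),
            all(c("avg_pid", "sp", "tc") %in% names(records)))
  pid <- records$avg_pid
  if (any(pid < edges[[1L]] | pid > edges[[length(edges)]]))
    stop("family avg_pid outside the binning range [", edges[[1L]], ", ",
         edges[[length(edges)]], "]")
  k <- length(edges) - 1L
  bin <- findInterval(pid, edges, rightmost.closed = TRUE)
  labels <- paste0(edges[-length(edges)], "%-", edges[-1L], "%")
  out <- data.frame(bin = labels,
                    mean_sp = NA_real_, mean_tc = NA_real_,
                    n_families = 0L, stringsAsFactors = FALSE)
  for (b in seq_len(k)) {
    sel <- bin == b
    out$n_families[[b]] <- sum(sel)
    if (any(sel)) {
      out$mean_sp[[b]] <- round(mean(records$sp[sel]), 3L)
      out$mean_tc[[b]] <- round(mean(records$tc[sel]), 3L)
    }
  }
  class(out) <- c("binned_report", "data.frame")
  out
}
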