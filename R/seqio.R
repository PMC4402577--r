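# FASTA / aligned-FASTA / Newick input and output.
#
# Sequences are represented as a named character vector (names are the
# sequence ids, values the residue strings); an optional "descriptions"
# attribute carries the rest of each FASTA header line.  A multiple
# alignment is the same thing with class "msa": equal-length gapped rows.

#' Read unaligned protein sequences from a FASTA file
#'
#' Residues are upper-cased; `*` (stop) and whitespace are stripped.  Ids must
#' be unique and residues must come from the 20 amino-acid letters plus X.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of residue strings, in file order, with a
#'   `descriptions` attribute.
#' @export
read_fasta <- function(path) {
  recs <- .read_fasta_raw(path)
  seqs <- gsub("[*[:space:]]", "", toupper(recs$seq))
  seqs <- gsub("\\.", "-", seqs)  # '.' is an input-side gap alias
  if (any(grepl("-", seqs, fixed = TRUE)))
    stop("gap characters found; use read_msa() for aligned FASTA")
  .validate_seqs(seqs, recs$id)
  structure(setNames(seqs, recs$id), descriptions = recs$desc)
}

#' Read a multiple sequence alignment from an aligned FASTA file
#'
#' Gap characters `-` and `.` are accepted on input and normalized to `-`.
#' All rows must have the same length.
#'
#' @param path Path to an aligned FASTA file.
#' @return An `msa` object: named character vector of equal-length gapped rows.
#' @export
read_msa <- function(path) {
  recs <- .read_fasta_raw(path)
  rows <- gsub("[*[:space:]]", "", toupper(recs$seq))
  rows <- gsub("\\.", "-", rows)
  .validate_seqs(gsub("-", "", rows), recs$id, context = path)
  msa(setNames(rows, recs$id))
}

.read_fasta_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  list(id = ids, seq = as.character(set), desc = desc)
}

.validate_seqs <- function(seqs, ids, context = NULL) {
  if (any(!nzchar(ids))) stop("empty sequence id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(seqs)))
    stop("empty sequence: ", paste(ids[!nzchar(seqs)], collapse = ", "))
  ok <- paste0("^[", paste(AA_ALPHABET, collapse = ""), "]*$")
  bad <- !grepl(ok, seqs)
  if (any(bad)) {
    i <- which(bad)[[1L]]
    pos <- regexpr(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"),
                   seqs[[i]])
    stop("illegal residue character '",
         substr(seqs[[i]], pos, pos), "' in sequence '", ids[[i]],
         "' at position ", pos)
  }
  invisible(TRUE)
}

#' Construct / validate an MSA object
#'
#' @param rows Named character vector of equal-length gapped rows (gap `-`).
#' @return The rows with class `msa`.
#' @export
msa <- function(rows) {
  if (!is.character(rows) || length(rows) == 0L || is.null(names(rows)))
    stop("an MSA needs a non-empty named character vector of rows")
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("MSA rows differ in length")
  if (w < 1L) stop("MSA has zero columns")
  if (anyDuplicated(names(rows)))
    stop("duplicate sequence id(s) in MSA: ",
         paste(unique(names(rows)[duplicated(names(rows))]), collapse = ", "))
  structure(rows, class = "msa")
}

#' Remove gaps from alignment rows
#'
#' @param x An `msa` object or character vector of gapped strings.
#' @return Named character vector of ungapped residue strings.
#' @export
ungap <- function(x) {
  out <- gsub("-", "", unclass(x), fixed = TRUE)
  attributes(out) <- list(names = names(x))
  out
}

#' @export
print.msa <- function(x, ...) {
  cat("MSA:", length(x), "sequences x", nchar(x[[1L]]), "columns\n")
  show <- if (length(x) > 8L) x[1:8] else x
  for (i in seq_along(show)) {
    row <- show[[i]]
    if (nchar(row) > 60L) row <- paste0(substr(row, 1L, 57L), "...")
    cat(sprintf("  %-12s %s\n", names(show)[[i]], row))
  }
  if (length(x) > 8L) cat("  ...\n")
  invisible(x)
}

#' Write sequences or an alignment to FASTA
#'
#' Lines are wrapped at 60 characters.  Round-trips ids and residues exactly.
#'
#' @param x Named character vector of sequences, or an `msa` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (length(x) == 0L) stop("refusing to write an empty sequence set")
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("all sequences must be named")
  set <- Biostrings::BStringSet(unclass(x))
  names(set) <- names(x)
  desc <- attr(x, "descriptions")
  if (!is.null(desc) && any(nzchar(desc)))
    names(set) <- trimws(paste(names(x), desc))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a guide tree from a Newick file
#'
#' @param path Path to a Newick tree file.
#' @return An [ape::phylo] tree.  Multifurcations are accepted here and
#'   binarized when the tree is used as a guide tree
#'   (see [load_reference_tree()]).
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) NULL)
  if (is.null(tr)) stop("cannot parse Newick file: ", path)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("cannot parse Newick file: ", path)
  tr
}

#' Write a guide tree to a Newick file
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
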