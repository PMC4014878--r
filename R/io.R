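#' Read an aligned multi-FASTA file
#'
#' Reads a gapped DNA alignment (gap character `-`) from FASTA. Sequences
#' are uppercased; record order becomes row order. Ragged records, illegal
#' characters and duplicate identifiers are errors.
#'
#' @param path path to an aligned multi-FASTA file.
#' @param allowN tolerate `N` as a universal-mismatch wildcard?
#' @return a [PhyloMSA-class].
#' @seealso [writeAlignment()]
#' @export
readAlignment <- function(path, allowN = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  s <- as.character(set)
  ## FASTA descriptions: the id is the first whitespace-delimited token
  names(s) <- sub("\\s.*$", "", names(s))
  if (anyDuplicated(names(s))) stop("duplicate row id")
  if (length(unique(nchar(s))) > 1L)
    stop("not an alignment: records have unequal lengths")
  PhyloMSA(s, allowN = allowN)
}

#' Write an alignment to multi-FASTA
#'
#' The written file round-trips: `readAlignment(writeAlignment(a, f))`
#' reproduces `a` exactly, including row order.
#'
#' @param aln a [PhyloMSA-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(aln, path) {
  stopifnot(is(aln, "PhyloMSA"))
  set <- Biostrings::BStringSet(alnStrings(aln))
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}

#' Read a rooted binary Newick tree
#'
#' Parses a Newick string or file into an `ape` `phylo` object and checks
#' the contract the scorer relies on: the tree is rooted, every internal
#' node has exactly two children, and every leaf is labeled (uniquely).
#' Branch lengths are parsed but ignored by scoring, which sums over unit
#' edges.
#'
#' @param x a file path or a Newick string (detected by the presence of
#'   `(`/`;`).
#' @return an `ape::phylo` object.
#' @export
readTree <- function(x) {
  tr <- if (length(x) == 1L && grepl("[(;]", x)) {
    ape::read.tree(text = x)
  } else {
    if (!file.exists(x)) stop("file not found: ", x)
    ape::read.tree(x)
  }
  if (is.null(tr)) stop("could not parse Newick input")
  validateTree(tr)
  tr
}

validateTree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a 'phylo' tree")
  labs <- tr$tip.label
  if (is.null(labs) || anyNA(labs) || any(labs == ""))
    stop("unlabeled leaf")
  if (anyDuplicated(labs)) stop("duplicate leaf label")
  ## binary rooted: every internal node (incl. the root) has 2 children
  kids <- tabulate(tr$edge[, 1L], nbins = max(tr$edge))
  internal <- (length(labs) + 1L):(length(labs) + tr$Nnode)
  if (any(kids[internal] != 2L))
    stop("unsupported topology: tree must be rooted and binary")
  invisible(tr)
}

#' Write a tree as Newick
#' @param tree an `ape::phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Restrict a tree to a subset of leaves
#'
#' Induced subtree on `keep` with single-child internal nodes suppressed;
#' the result is again rooted and binary. Needed because casual blocks
#' include only the non-empty rows of their region, a subset of the full
#' species set.
#'
#' @param tree an `ape::phylo` (rooted, binary).
#' @param keep character vector of leaf labels to retain (at least 2).
#' @return an `ape::phylo` on exactly the `keep` leaves.
#' @export
restrictTree <- function(tree, keep) {
  validateTree(tree)
  keep <- unique(as.character(keep))
  if (!all(keep %in% tree$tip.label))
    stop("'keep' contains labels absent from the tree")
  if (length(keep) < 2L) stop("need at least 2 leaves to restrict to")
  if (length(keep) == length(tree$tip.label)) return(tree)
  sub <- ape::keep.tip(tree, keep)
  validateTree(sub)
  sub
}

#' Does a tree match an alignment?
#'
#' A tree is compatible with an alignment iff its leaf-label set equals the
#' alignment's row-id set.
#'
#' @param aln a [PhyloMSA-class]
#' @param tree an `ape::phylo`
#' @return `TRUE` or `FALSE`.
#' @export
isCompatible <- function(aln, tree) {
  setequal(rowIds(aln), tree$tip.label)
}

assertCompatible <- function(aln, tree) {
  validateTree(tree)
  if (!isCompatible(aln, tree))
    stop("tree leaves and alignment rows do not match")
  invisible(TRUE)
}
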