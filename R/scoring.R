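## Bit encoding of the five states, in the fixed tie-break order
## A < C < G < T < '-'. The wildcard N maps to {A,C,G,T} in set space.
STATE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, "-" = 16L)

## lowest set bit in the A<C<G<T<'-' order, for masks 1..31
.lowbit <- vapply(1:31, function(m) {
  bits <- c(1L, 2L, 4L, 8L, 16L)
  bits[which(bitwAnd(m, bits) != 0L)[1L]]
}, integer(1))

.bit2char <- c(`1` = "A", `2` = "C", `4` = "G", `8` = "T", `16` = "-")

charToMask <- function(ch) {
  m <- STATE_BITS[ch]
  m[ch == "N"] <- 15L
  unname(m)
}

## children list and bottom-up / top-down node orders of a rooted tree
treeOrders <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  kids <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2L])
  }
  root <- n + 1L
  depth <- integer(nn)
  queue <- root
  bfs <- integer(0)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    bfs <- c(bfs, v)
    for (w in kids[[v]]) {
      depth[w] <- depth[v] + 1L
      queue <- c(queue, w)
    }
  }
  internal <- bfs[bfs > n]
  list(children = kids, root = root,
       bottomUp = rev(internal),   # deepest internal nodes first
       topDown = internal)         # root first
}

#' Infer ancestral sequences by per-column Fitch parsimony
#'
#' Reconstructs one sequence per internal node of a rooted binary tree by
#' the two-pass Fitch algorithm applied independently to every alignment
#' column, with the gap treated as a fifth character. Bottom-up, each node
#' gets the intersection of its children's state sets, or their union when
#' the intersection is empty (one union event = one substitution counted).
#' Top-down, the root takes the smallest state of its set in the fixed
#' order `A < C < G < T < '-'`; every other node keeps its parent's state
#' when that state is in its own set, and otherwise takes the smallest
#' state of its set. The per-column substitution count (the number of
#' union events) attains the parsimony minimum over all possible internal
#' assignments.
#'
#' @param aln a [PhyloMSA-class].
#' @param tree a rooted binary `ape::phylo` whose leaf labels equal the
#'   alignment's row ids.
#' @return an [AncestralLabeling-class]; `columnCounts()` gives the
#'   per-column substitution counts.
#' @examples
#' aln <- PhyloMSA(c(X = "ACGT", Y = "ACGT"))
#' ancestorStrings(inferAncestors(aln, readTree("(X,Y);")))
#' @export
inferAncestors <- function(aln, tree) {
  assertCompatible(aln, tree)
  n <- length(tree$tip.label)
  nc <- ncol(aln)
  ord <- treeOrders(tree)
  m <- alnMatrix(aln)

  masks <- matrix(0L, nrow = n + tree$Nnode, ncol = nc)
  for (i in seq_len(n))
    masks[i, ] <- charToMask(m[tree$tip.label[i], ])

  counts <- integer(nc)
  for (v in ord$bottomUp) {
    ch <- ord$children[[v]]
    a <- bitwAnd(masks[ch[1L], ], masks[ch[2L], ])
    u <- a == 0L
    if (any(u)) {
      a[u] <- bitwOr(masks[ch[1L], u], masks[ch[2L], u])
      counts[u] <- counts[u] + 1L
    }
    masks[v, ] <- a
  }

  states <- matrix(0L, nrow = n + tree$Nnode, ncol = nc)
  root <- ord$root
  states[root, ] <- .lowbit[masks[root, ]]
  for (v in ord$topDown) {
    if (v != root) {
      p <- treeParent(tree, v)
      keep <- bitwAnd(masks[v, ], states[p, ]) != 0L
      states[v, ] <- ifelse(keep, states[p, ], .lowbit[masks[v, ]])
    }
  }

  internal <- (n + 1L):(n + tree$Nnode)
  labels <- vapply(internal, function(v) {
    paste0(.bit2char[as.character(states[v, ])], collapse = "")
  }, character(1))
  names(labels) <- as.character(internal)
  sets <- lapply(internal, function(v) masks[v, ])
  names(sets) <- as.character(internal)
  AncestralLabeling(labels, colCounts = counts, sets = sets)
}

treeParent <- function(tree, v) {
  tree$edge[match(v, tree$edge[, 2L]), 1L]
}

#' Induced pairwise alignment of two rows
#'
#' Drops every column in which both sequences carry a gap; the relative
#' order of the remaining columns is preserved. This is the projection
#' under which each tree edge is scored.
#'
#' @param s1,s2 gapped sequences of equal length (strings or character
#'   vectors of single characters).
#' @return a list with `s1`, `s2` (character vectors) and `dropped`, the
#'   number of both-gap columns removed.
#' @export
inducedPairwise <- function(s1, s2) {
  x <- if (length(s1) == 1L) strsplit(s1, "", fixed = TRUE)[[1L]] else s1
  y <- if (length(s2) == 1L) strsplit(s2, "", fixed = TRUE)[[1L]] else s2
  if (length(x) != length(y)) stop("sequences have unequal lengths")
  both <- x == GAP & y == GAP
  list(s1 = x[!both], s2 = y[!both], dropped = sum(both))
}

## full affine scoring detail of one induced pair (no both-gap columns)
scorePairDetail <- function(x, y, params) {
  L <- length(x)
  out <- list(score = 0L, matches = 0L, mismatches = 0L, gapOpenings = 0L,
              gapExtensions = 0L, terminalGapCols = 0L)
  if (L == 0L) return(out)
  if (any(x == GAP & y == GAP)) stop("unnormalized pair: both-gap column")

  bothNuc <- x != GAP & y != GAP
  isMatch <- bothNuc & x == y & x != "N"
  out$matches <- sum(isMatch)
  out$mismatches <- sum(bothNuc) - out$matches

  gapRuns <- function(g) {
    r <- rle(g)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(start = starts[keep], end = ends[keep], len = r$lengths[keep])
  }
  runs <- rbind(gapRuns(x == GAP), gapRuns(y == GAP))
  if (nrow(runs)) {
    terminal <- runs$start == 1L | runs$end == L
    out$terminalGapCols <- sum(runs$len[terminal])
    inner <- runs[!terminal, , drop = FALSE]
    out$gapOpenings <- nrow(inner)
    out$gapExtensions <- if (params@openCoversFirst)
      sum(inner$len - 1L) else sum(inner$len)
  }
  out$score <- params@match * out$matches +
    params@mismatch * out$mismatches +
    params@gapOpen * out$gapOpenings +
    params@gapExtend * out$gapExtensions
  out
}

#' Affine score of an induced pairwise alignment
#'
#' Scores one induced pair under the game's affine gap model in a single
#' left-to-right scan: an aligned nucleotide pair scores `match` or
#' `mismatch`; a maximal gap run of length `k` that does not touch either
#' end of the alignment costs `gapOpen + (k-1) * gapExtend` (or
#' `gapOpen + k * gapExtend` when `openCoversFirst = FALSE`); gap runs
#' touching the beginning or the end of the pairwise alignment are free,
#' and the columns they span contribute nothing. Both-gap columns must
#' already have been removed by [inducedPairwise()].
#'
#' @param pair a list as returned by [inducedPairwise()], or a gapped
#'   sequence (in which case `s2` must be given and the pair is induced
#'   first).
#' @param s2 optional second sequence.
#' @param params a [ScoringParams-class].
#' @return integer score.
#' @examples
#' scorePairwise(inducedPairwise("AC--GT", "ACAAGT"))  # -1
#' scorePairwise("--ACGT", "GGACGT")                   # +4, leading gap free
#' @export
scorePairwise <- function(pair, s2 = NULL, params = ScoringParams()) {
  if (!is.null(s2)) pair <- inducedPairwise(pair, s2)
  if (!is.list(pair) || is.null(pair$s1))
    stop("'pair' must come from inducedPairwise()")
  as.integer(scorePairDetail(pair$s1, pair$s2, params)$score)
}

## shared edge-sum over a full node-sequence matrix
edgeSum <- function(tree, nodeSeqs, params) {
  n <- length(tree$tip.label)
  nodeLabel <- function(v)
    if (v <= n) tree$tip.label[v] else paste0("node", v)
  rows <- vector("list", nrow(tree$edge))
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    v <- tree$edge[i, 2L]
    ind <- inducedPairwise(nodeSeqs[p, ], nodeSeqs[v, ])
    d <- scorePairDetail(ind$s1, ind$s2, params)
    rows[[i]] <- data.frame(
      parent = p, child = v,
      parentLabel = nodeLabel(p), childLabel = nodeLabel(v),
      score = as.integer(d$score), matches = d$matches,
      mismatches = d$mismatches, gapOpenings = d$gapOpenings,
      gapExtensions = d$gapExtensions, terminalGapCols = d$terminalGapCols,
      bothGapCols = ind$dropped, stringsAsFactors = FALSE)
  }
  perEdge <- do.call(rbind, rows)
  new("ScoreBreakdown", total = as.integer(sum(perEdge$score)),
      perEdge = perEdge)
}

nodeSeqMatrix <- function(aln, tree, labels) {
  n <- length(tree$tip.label)
  nc <- ncol(aln)
  m <- alnMatrix(aln)
  nodeSeqs <- matrix(GAP, nrow = n + tree$Nnode, ncol = nc)
  for (i in seq_len(n)) nodeSeqs[i, ] <- m[tree$tip.label[i], ]
  for (nm in names(labels))
    nodeSeqs[as.integer(nm), ] <- strsplit(labels[[nm]], "", fixed = TRUE)[[1L]]
  nodeSeqs
}

#' Game score of an alignment on a tree
#'
#' The full game score: ancestral sequences are reconstructed with
#' [inferAncestors()], then for every edge of the tree the induced pairwise
#' alignment of the parent and child sequences is scored under the affine
#' model of [scorePairwise()], and the edge scores are summed. The result
#' is deterministic given the inputs.
#'
#' @inheritParams inferAncestors
#' @param params a [ScoringParams-class].
#' @return a [ScoreBreakdown-class]; `totalScore()` gives the total.
#' @examples
#' aln <- PhyloMSA(c(X = "ACGT", Y = "ACGT"))
#' totalScore(gameScore(aln, readTree("(X,Y);")))  # 8
#' @export
gameScore <- function(aln, tree, params = ScoringParams()) {
  anc <- inferAncestors(aln, tree)
  edgeSum(tree, nodeSeqMatrix(aln, tree, ancestorStrings(anc)), params)
}

#' Score an alignment under user-supplied ancestors
#'
#' The same edge-sum computation as [gameScore()], but with the ancestral
#' sequences supplied by the caller instead of reconstructed by Fitch, as
#' in expert-mode ancestor editing. No parsimony minimality is required;
#' because the per-column Fitch reconstruction ignores the affine coupling
#' between neighbouring columns, a hand-merged gap run can score strictly
#' higher than the Fitch labeling.
#'
#' @inheritParams gameScore
#' @param labeling an [AncestralLabeling-class], or a character vector of
#'   ancestral strings named by internal node number (`"6"` or `"node6"`).
#'   Every internal node must be covered, at the alignment's full width,
#'   over the alphabet `{A,C,G,T,-}`.
#' @return a [ScoreBreakdown-class].
#' @seealso [suboptimalAncestorFixture()] for a worked example where an
#'   edited labeling beats Fitch.
#' @export
scoreWithAncestors <- function(aln, tree, labeling, params = ScoringParams()) {
  assertCompatible(aln, tree)
  labels <- if (is(labeling, "AncestralLabeling"))
    ancestorStrings(labeling) else toupper(labeling)
  if (is.null(names(labels))) stop("labeling must be named by node number")
  names(labels) <- sub("^node", "", names(labels))
  n <- length(tree$tip.label)
  internal <- as.character((n + 1L):(n + tree$Nnode))
  missing <- setdiff(internal, names(labels))
  if (length(missing))
    stop("missing node(s) in labeling: ", paste(missing, collapse = ", "))
  labels <- labels[internal]
  if (any(nchar(labels) != ncol(aln)))
    stop("wrong length: ancestral strings must span ", ncol(aln), " columns")
  chars <- unique(unlist(strsplit(labels, "", fixed = TRUE)))
  if (!all(chars %in% ALN_ALPHABET))
    stop("illegal character in ancestral labeling")
  edgeSum(tree, nodeSeqMatrix(aln, tree, labels), params)
}
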