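#' @import methods
NULL

ALN_ALPHABET <- c("A", "C", "G", "T", "-")
GAP <- "-"
## fixed state order used for every deterministic tie-break: A < C < G < T < '-'
STATE_ORDER <- c("A", "C", "G", "T", "-")

#' Gapped DNA multiple sequence alignment
#'
#' A rectangular alignment of two or more DNA sequences over the alphabet
#' `{A, C, G, T, -}`, stored as a character matrix of single characters with
#' unique row names (the sequence identifiers). Column coordinates are
#' 1-based and inclusive throughout the package.
#'
#' @slot seqs character matrix, one row per sequence, one column per
#'   alignment column; `rownames(seqs)` are the sequence identifiers.
#' @slot allowN logical; if `TRUE` the wildcard character `N` is tolerated
#'   and scored as a mismatch against every state (never a gap).
#'
#' @seealso [PhyloMSA()], [readAlignment()], [gameScore()]
#' @export
setClass("PhyloMSA", representation(seqs = "matrix", allowN = "logical"))

setValidity("PhyloMSA", function(object) {
  m <- object@seqs
  if (!is.character(m)) return("'seqs' must be a character matrix")
  if (nrow(m) < 2L) return("an alignment needs at least 2 rows")
  if (ncol(m) < 1L) return("an alignment needs at least 1 column")
  ids <- rownames(m)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    return("every row must carry a non-empty identifier")
  if (anyDuplicated(ids)) return("duplicate row id")
  alpha <- ALN_ALPHABET
  if (isTRUE(object@allowN)) alpha <- c(alpha, "N")
  if (!all(m %in% alpha))
    return(paste0("alphabet error: characters outside {",
                  paste(alpha, collapse = ","), "}"))
  TRUE
})

#' Construct a PhyloMSA
#'
#' @param x a named character vector of equal-length gapped sequences, or a
#'   character matrix of single characters with row names.
#' @param allowN tolerate the wildcard `N` (scored as universal mismatch)?
#'   Default `FALSE`: any character outside `{A,C,G,T,-}` is an error.
#'
#' Input is uppercased before validation. Ragged sequences raise
#' "not an alignment"; characters outside the alphabet (including `.` and
#' `*` and, unless `allowN`, any IUPAC ambiguity code) raise an alphabet
#' error.
#'
#' @return a [PhyloMSA-class] object.
#' @examples
#' PhyloMSA(c(human = "ACGT", mouse = "AC-T"))
#' @export
PhyloMSA <- function(x, allowN = FALSE) {
  if (is.matrix(x)) {
    m <- toupper(x)
  } else {
    ids <- names(x)
    x <- toupper(as.character(x))
    names(x) <- ids
    if (length(unique(nchar(x))) > 1L)
      stop("not an alignment: rows have unequal lengths")
    m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
    rownames(m) <- names(x)
  }
  new("PhyloMSA", seqs = m, allowN = isTRUE(allowN))
}

#' @describeIn PhyloMSA-class number of rows (sequences)
#' @param x,object a `PhyloMSA`
#' @export
setMethod("nrow", "PhyloMSA", function(x) nrow(x@seqs))

#' @describeIn PhyloMSA-class number of alignment columns
#' @export
setMethod("ncol", "PhyloMSA", function(x) ncol(x@seqs))

#' Sequence identifiers of an alignment
#' @param x a [PhyloMSA-class]
#' @return character vector of row ids, in row order.
#' @export
rowIds <- function(x) rownames(x@seqs)

#' Alignment as a character matrix of single characters
#' @param x a [PhyloMSA-class]
#' @export
alnMatrix <- function(x) x@seqs

#' Alignment rows as collapsed strings
#' @param x a [PhyloMSA-class]
#' @return named character vector, one gapped string per row.
#' @export
alnStrings <- function(x) {
  s <- apply(x@seqs, 1L, paste0, collapse = "")
  names(s) <- rownames(x@seqs)
  s
}

setMethod("show", "PhyloMSA", function(object) {
  cat(sprintf("PhyloMSA: %d rows x %d columns\n",
              nrow(object@seqs), ncol(object@seqs)))
  s <- alnStrings(object)
  shown <- utils::head(s, 6L)
  wide <- nchar(shown) > 60L
  shown[wide] <- paste0(substr(shown[wide], 1L, 57L), "...")
  for (i in seq_along(shown))
    cat(sprintf("  %-12s %s\n", names(shown)[i], shown[i]))
  if (length(s) > 6L) cat(sprintf("  ... and %d more rows\n", length(s) - 6L))
})

#' Integer game scores for alignment evaluation
#'
#' The four integer scores of the game scoring scheme: +1 for a match, -1
#' for a mismatch, -4 for opening a gap and -1 for extending it (values
#' approximating the BLASTZ substitution/gap costs). A maximal gap run of
#' length k costs `gapOpen + (k-1) * gapExtend` under the default
#' convention (`openCoversFirst = TRUE`); setting `openCoversFirst = FALSE`
#' switches to `gapOpen + k * gapExtend`.
#'
#' @slot match positive integer score for an identical nucleotide pair.
#' @slot mismatch non-positive score for a differing nucleotide pair.
#' @slot gapOpen non-positive score charged once per non-terminal gap run.
#' @slot gapExtend non-positive score per additional gap column in a run.
#' @slot openCoversFirst logical, see above.
#' @export
setClass("ScoringParams",
         representation(match = "integer", mismatch = "integer",
                        gapOpen = "integer", gapExtend = "integer",
                        openCoversFirst = "logical"))

setValidity("ScoringParams", function(object) {
  if (object@match <= 0L) return("'match' must be > 0")
  if (object@mismatch > 0L || object@gapOpen > 0L || object@gapExtend > 0L)
    return("'mismatch', 'gapOpen' and 'gapExtend' must be <= 0")
  TRUE
})

#' @rdname ScoringParams-class
#' @param match,mismatch,gapOpen,gapExtend integer game scores.
#' @param openCoversFirst does the opening charge cover the first gap
#'   column of a run (default), or is every gap column also extended?
#' @export
ScoringParams <- function(match = 1L, mismatch = -1L, gapOpen = -4L,
                          gapExtend = -1L, openCoversFirst = TRUE) {
  new("ScoringParams", match = as.integer(match),
      mismatch = as.integer(mismatch), gapOpen = as.integer(gapOpen),
      gapExtend = as.integer(gapExtend),
      openCoversFirst = isTRUE(openCoversFirst))
}

setMethod("show", "ScoringParams", function(object) {
  cat(sprintf(
    "ScoringParams: match %+d, mismatch %+d, gap open %+d, gap extend %+d\n",
    object@match, object@mismatch, object@gapOpen, object@gapExtend))
})

#' Ancestral sequence labeling of a tree's internal nodes
#'
#' One gapped string per internal node of a rooted binary tree, at the full
#' width of the alignment it labels. Produced by [inferAncestors()] (in
#' which case each column attains the per-column parsimony minimum with gap
#' as a fifth state) or supplied by the user to [scoreWithAncestors()]
#' (expert-style ancestor editing; no minimality is required).
#'
#' @slot labels named character vector; names are internal node numbers (as
#'   characters, `ape` numbering: tips `1..n`, root `n+1`).
#' @slot colCounts integer vector of per-column substitution counts (the
#'   Fitch union-event count); empty when the labeling was user-supplied.
#' @slot sets optional list of per-node candidate-state bitmasks kept for
#'   diagnostics (may be empty).
#' @export
setClass("AncestralLabeling",
         representation(labels = "character", colCounts = "integer",
                        sets = "list"))

setValidity("AncestralLabeling", function(object) {
  if (is.null(names(object@labels)) || anyDuplicated(names(object@labels)))
    return("'labels' must be uniquely named by internal node number")
  if (length(unique(nchar(object@labels))) > 1L)
    return("all ancestral strings must have equal length")
  TRUE
})

#' @rdname AncestralLabeling-class
#' @param labels named character vector of ancestral strings (names =
#'   internal node numbers).
#' @param colCounts optional per-column substitution counts.
#' @param sets optional diagnostic candidate sets.
#' @export
AncestralLabeling <- function(labels, colCounts = integer(0), sets = list()) {
  new("AncestralLabeling", labels = toupper(labels),
      colCounts = as.integer(colCounts), sets = sets)
}

#' Ancestral strings of a labeling
#' @param x an [AncestralLabeling-class]
#' @export
ancestorStrings <- function(x) x@labels

#' Per-column substitution counts of a Fitch labeling
#' @param x an [AncestralLabeling-class]
#' @export
columnCounts <- function(x) x@colCounts

setMethod("show", "AncestralLabeling", function(object) {
  cat(sprintf("AncestralLabeling: %d internal nodes, %d columns\n",
              length(object@labels),
              if (length(object@labels)) nchar(object@labels[[1L]]) else 0L))
  if (length(object@colCounts))
    cat(sprintf("  total per-column substitutions: %d\n",
                sum(object@colCounts)))
})

#' Edge-decomposed alignment score
#'
#' The total game score of an alignment together with its decomposition
#' over the edges of the tree: per edge, the affine score of the induced
#' pairwise alignment of the parent and child sequences, plus tallies of
#' matches, mismatches, gap openings, gap extensions, columns excluded as
#' terminal gaps and columns dropped because both sequences were gapped.
#' `total` always equals the sum of the per-edge scores.
#'
#' @slot total integer total score.
#' @slot perEdge data.frame with columns `parent`, `child` (node numbers),
#'   `parentLabel`, `childLabel`, `score`, `matches`, `mismatches`,
#'   `gapOpenings`, `gapExtensions`, `terminalGapCols`, `bothGapCols`.
#' @export
setClass("ScoreBreakdown",
         representation(total = "integer", perEdge = "data.frame"))

setValidity("ScoreBreakdown", function(object) {
  if (nrow(object@perEdge) &&
      sum(object@perEdge$score) != object@total)
    return("'total' must equal the sum of per-edge scores")
  TRUE
})

#' Total game score
#' @param x a [ScoreBreakdown-class]
#' @export
totalScore <- function(x) x@total

#' Per-edge score table
#' @param x a [ScoreBreakdown-class]
#' @export
perEdgeScores <- function(x) x@perEdge

setMethod("show", "ScoreBreakdown", function(object) {
  cat(sprintf("ScoreBreakdown: total %d over %d edges\n",
              object@total, nrow(object@perEdge)))
  cat(sprintf("  matches %d, mismatches %d, gap openings %d, extensions %d\n",
              sum(object@perEdge$matches), sum(object@perEdge$mismatches),
              sum(object@perEdge$gapOpenings),
              sum(object@perEdge$gapExtensions)))
})

#' A puzzle block cut from a parent alignment
#'
#' A contiguous column range of a parent alignment together with the subset
#' of rows it includes and a snapshot of that sub-alignment. Casual blocks
#' are 10-20 columns wide and keep exactly the non-empty rows of the
#' region; expert blocks are up to 300 columns wide and keep every row.
#'
#' @slot parentId identifier of the parent alignment.
#' @slot start,end 1-based inclusive column range in the parent.
#' @slot rowIds identifiers of the included rows, in parent row order.
#' @slot snapshot character matrix: the parent slice restricted to
#'   `rowIds`.
#' @slot kind `"casual"` or `"expert"`.
#' @slot timesPlayed non-negative integer used for task routing.
#' @export
setClass("PuzzleBlock",
         representation(parentId = "character", start = "integer",
                        end = "integer", rowIds = "character",
                        snapshot = "matrix", kind = "character",
                        timesPlayed = "integer"))

setValidity("PuzzleBlock", function(object) {
  w <- object@end - object@start + 1L
  if (w < 1L) return("empty column range")
  if (!object@kind %in% c("casual", "expert"))
    return("'kind' must be \"casual\" or \"expert\"")
  if (object@kind == "casual" && (w < 10L || w > 20L))
    return("casual blocks must span 10-20 columns")
  if (object@kind == "expert" && w > 300L)
    return("expert blocks must span at most 300 columns")
  if (length(object@rowIds) < 2L) return("a block needs at least 2 rows")
  if (!identical(dim(object@snapshot),
                 c(length(object@rowIds), w)))
    return("snapshot dimensions do not match the block")
  if (object@timesPlayed < 0L) return("'timesPlayed' must be >= 0")
  TRUE
})

PuzzleBlock <- function(parentId, start, end, rowIds, snapshot, kind,
                        timesPlayed = 0L) {
  new("PuzzleBlock", parentId = as.character(parentId),
      start = as.integer(start), end = as.integer(end),
      rowIds = as.character(rowIds), snapshot = snapshot,
      kind = kind, timesPlayed = as.integer(timesPlayed))
}

#' Column range of a block
#' @param x a [PuzzleBlock-class]
#' @return integer vector `c(start, end)` (1-based, inclusive).
#' @export
blockRange <- function(x) c(x@start, x@end)

#' Width of a block in columns
#' @param x a [PuzzleBlock-class]
#' @export
blockWidth <- function(x) x@end - x@start + 1L

#' Rows included in a block
#' @param x a [PuzzleBlock-class]
#' @export
blockRows <- function(x) x@rowIds

#' Block snapshot as a PhyloMSA
#' @param x a [PuzzleBlock-class]
#' @export
blockSnapshot <- function(x) PhyloMSA(x@snapshot)

#' Number of times a block has been played
#' @param x a [PuzzleBlock-class]
#' @export
timesPlayed <- function(x) x@timesPlayed

setMethod("show", "PuzzleBlock", function(object) {
  cat(sprintf("PuzzleBlock (%s): parent '%s', columns %d-%d, %d rows, played %d\n",
              object@kind, object@parentId, object@start, object@end,
              length(object@rowIds), object@timesPlayed))
})

#' A candidate realignment of a puzzle block
#'
#' A player (or robot-player) solution: a realignment of a block's rows,
#' possibly of different width, that preserves every row's ungapped
#' sequence, together with its game score. Solutions are only constructed
#' through [admit()] or [hillClimb()], which enforce the admission rules.
#'
#' @slot blockKey identifier tying the solution to its block
#'   (`"parentId:start-end"`).
#' @slot seqs character matrix over the block's rows.
#' @slot score integer game score on the pruned tree.
#' @slot submitter optional free-text tag.
#' @slot seqNo submission sequence number used to break ranking ties
#'   (earlier first).
#' @export
setClass("PuzzleSolution",
         representation(blockKey = "character", seqs = "matrix",
                        score = "integer", submitter = "character",
                        seqNo = "integer"))

PuzzleSolution <- function(blockKey, seqs, score, submitter = "", seqNo = 1L) {
  new("PuzzleSolution", blockKey = as.character(blockKey), seqs = seqs,
      score = as.integer(score), submitter = as.character(submitter),
      seqNo = as.integer(seqNo))
}

#' Game score of a solution
#' @param x a [PuzzleSolution-class]
#' @export
solutionScore <- function(x) x@score

#' Solution matrix
#' @param x a [PuzzleSolution-class]
#' @export
solutionMatrix <- function(x) x@seqs

#' Key of the block a solution belongs to
#' @param x a [PuzzleSolution-class]
#' @export
solutionBlockKey <- function(x) x@blockKey

setMethod("show", "PuzzleSolution", function(object) {
  cat(sprintf("PuzzleSolution #%d for block %s: score %d, width %d\n",
              object@seqNo, object@blockKey, object@score,
              ncol(object@seqs)))
})

blockKey <- function(block) {
  sprintf("%s:%d-%d", block@parentId, block@start, block@end)
}
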