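degapRow <- function(chars) paste0(chars[chars != GAP], collapse = "")

## score a block snapshot or candidate on the tree pruned to its rows
blockScore <- function(seqs, rows, tree, params) {
  sub <- if (length(rows) == length(tree$tip.label)) tree
         else restrictTree(tree, rows)
  totalScore(gameScore(PhyloMSA(seqs), sub, params))
}

#' Admit a candidate realignment of a block
#'
#' Verifies that the candidate preserves every row's ungapped sequence
#' (players slide bricks; they never create or destroy nucleotides), that
#' its width fits the game grid, and computes its game score on the tree
#' restricted to the block's rows. The candidate is stored iff its score
#' is greater than or equal to the score of the initial block.
#'
#' @param block a [PuzzleBlock-class].
#' @param candidate character matrix (or [PhyloMSA-class]) over exactly the
#'   block's rows; width may differ from the block's.
#' @param tree the full `ape::phylo` tree (pruned internally).
#' @param params a [ScoringParams-class].
#' @param gridWidth maximal admissible width (the expert game grid has 400
#'   columns; the casual grid is configurable).
#' @param submitter,seqNo metadata stored on the admitted solution.
#' @return a [PuzzleSolution-class], or `NULL` when the candidate scores
#'   below the initial block (rejection). Content changes and grid
#'   overflow are errors, not rejections.
#' @export
admit <- function(block, candidate, tree, params = ScoringParams(),
                  gridWidth = 400L, submitter = "", seqNo = 1L) {
  cand <- if (is(candidate, "PhyloMSA")) alnMatrix(candidate)
          else toupper(candidate)
  rows <- blockRows(block)
  if (is.null(rownames(cand)) || !setequal(rownames(cand), rows))
    stop("candidate rows do not match the block's rows")
  cand <- cand[rows, , drop = FALSE]
  if (ncol(cand) > gridWidth)
    stop("grid overflow: candidate is wider than ", gridWidth, " columns")
  snap <- block@snapshot
  for (r in rows) {
    if (!identical(degapRow(cand[r, ]), degapRow(snap[r, ])))
      stop("illegal edit: row '", r, "' changed its nucleotide content")
  }
  initScore <- blockScore(snap, rows, tree, params)
  candScore <- blockScore(cand, rows, tree, params)
  if (candScore < initScore) return(NULL)
  PuzzleSolution(blockKey(block), cand, candScore,
                 submitter = submitter, seqNo = seqNo)
}

#' Rank solutions of one block by game score
#'
#' Stable descending sort by game score; ties are broken by submission
#' sequence number, earlier submissions first. Ranks are 1-based.
#'
#' @param solutions list of [PuzzleSolution-class] sharing one block.
#' @return the reordered list.
#' @export
rankSolutions <- function(solutions) {
  if (length(solutions) == 0L) return(list())
  keys <- vapply(solutions, solutionBlockKey, character(1))
  if (length(unique(keys)) > 1L)
    stop("solutions belong to different blocks")
  scores <- vapply(solutions, solutionScore, integer(1))
  seqNos <- vapply(solutions, function(s) s@seqNo, integer(1))
  solutions[order(-scores, seqNos)]
}

#' Keep the top fraction of a ranking
#'
#' Retains the first `ceiling(frac * n)` entries of a ranked solution
#' list; with the default `frac = 0.4` this is the "top 40%" rule under
#' which the crowd pipeline keeps its full performance while evaluating
#' far fewer candidates.
#'
#' @param ranked list of solutions as returned by [rankSolutions()].
#' @param frac fraction in `(0, 1]`.
#' @return the truncated list.
#' @export
topFraction <- function(ranked, frac = 0.4) {
  if (!(frac > 0 && frac <= 1)) stop("'frac' must be in (0, 1]")
  utils::head(ranked, ceiling(frac * length(ranked)))
}

#' Reinsert a solved block into its parent alignment
#'
#' Splices a solution back into the column range it was cut from. The
#' solution matrix is first normalized by deleting columns that are
#' all-gap across its rows; the parent columns `[start, end]` are then
#' replaced by the normalized solution, and rows not included in the block
#' receive a gap run of the normalized width. The resulting width is
#' `ncol(aln) - blockWidth + solutionWidth`, and no row's global ungapped
#' sequence ever changes. Reinserting the unmodified snapshot reproduces
#' the parent alignment exactly.
#'
#' @param aln the parent [PhyloMSA-class].
#' @param block the [PuzzleBlock-class] cut from `aln`.
#' @param sol an admitted [PuzzleSolution-class] for `block` (or a bare
#'   character matrix over the block's rows).
#' @return the spliced [PhyloMSA-class].
#' @export
reinsert <- function(aln, block, sol) {
  m <- alnMatrix(aln)
  rows <- blockRows(block)
  if (!all(rows %in% rownames(m)))
    stop("block/alignment mismatch: block rows absent from the alignment")
  region <- m[rows, block@start:block@end, drop = FALSE]
  if (!identical(unname(region), unname(block@snapshot)))
    stop("block/alignment mismatch: snapshot differs from the parent slice")
  s <- if (is(sol, "PuzzleSolution")) solutionMatrix(sol) else sol
  s <- s[rows, , drop = FALSE]
  keep <- colSums(s != GAP) > 0L
  s <- s[, keep, drop = FALSE]
  insert <- matrix(GAP, nrow = nrow(m), ncol = ncol(s),
                   dimnames = list(rownames(m), NULL))
  insert[rows, ] <- s
  out <- cbind(m[, seq_len(block@start - 1L), drop = FALSE],
               insert,
               if (block@end < ncol(m))
                 m[, (block@end + 1L):ncol(m), drop = FALSE])
  PhyloMSA(out, allowN = aln@allowN)
}

#' Evaluate candidate solutions against a full-MSA objective
#'
#' For each block, reinserts each candidate solution (optionally only the
#' top fraction of the block's ranking) into the parent alignment, scores
#' the full alignment with the chosen objective, and keeps the best. By
#' default the objective is the game score of the full alignment on the
#' full tree; any function `alignment -> numeric` (higher is better) can
#' be plugged in instead. A scorer failure on one candidate is recorded
#' and skipped; it never aborts the batch.
#'
#' @param aln the parent [PhyloMSA-class].
#' @param tree the full `ape::phylo`.
#' @param params a [ScoringParams-class] (used by the default scorer).
#' @param blocks list of [PuzzleBlock-class].
#' @param solutions list (parallel to `blocks`) of lists of admitted
#'   [PuzzleSolution-class] objects.
#' @param frac optional top fraction applied per block before evaluation
#'   (`NULL` evaluates every solution).
#' @param scorer optional objective `function(PhyloMSA) -> numeric`.
#' @return a list with `baseline` (score of the unmodified alignment),
#'   `perBlock` (data.frame: block key, number of candidates evaluated,
#'   best score, delta, chosen sequence number), `improvedFraction`, and
#'   `bestAlignments` (one [PhyloMSA-class] per block, the argmax).
#' @export
evaluateCandidates <- function(aln, tree, params = ScoringParams(),
                               blocks, solutions, frac = NULL,
                               scorer = NULL) {
  stopifnot(length(blocks) == length(solutions))
  if (is.null(scorer))
    scorer <- function(a) totalScore(gameScore(a, tree, params))
  baseline <- scorer(aln)
  if (length(blocks) == 0L)
    return(list(baseline = baseline,
                perBlock = data.frame(block = character(0),
                                      nCandidates = integer(0),
                                      nFailed = integer(0),
                                      bestScore = numeric(0),
                                      delta = numeric(0),
                                      chosenSeqNo = integer(0)),
                improvedFraction = 0, bestAlignments = list()))
  rows <- vector("list", length(blocks))
  bestAlns <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    sols <- rankSolutions(solutions[[i]])
    if (!is.null(frac)) sols <- topFraction(sols, frac)
    bestScore <- -Inf
    bestSeqNo <- NA_integer_
    bestAln <- NULL
    nEval <- 0L
    nFail <- 0L
    for (s in sols) {
      res <- tryCatch({
        cand <- reinsert(aln, blocks[[i]], s)
        list(score = scorer(cand), aln = cand)
      }, error = function(e) e)
      if (inherits(res, "error")) { nFail <- nFail + 1L; next }
      nEval <- nEval + 1L
      if (res$score > bestScore) {
        bestScore <- res$score
        bestSeqNo <- s@seqNo
        bestAln <- res$aln
      }
    }
    delta <- if (nEval > 0L) bestScore - baseline else 0
    rows[[i]] <- data.frame(
      block = blockKey(blocks[[i]]), nCandidates = nEval, nFailed = nFail,
      bestScore = if (nEval > 0L) bestScore else baseline,
      delta = delta, chosenSeqNo = bestSeqNo, stringsAsFactors = FALSE)
    bestAlns[[i]] <- if (is.null(bestAln)) aln else bestAln
  }
  perBlock <- do.call(rbind, rows)
  list(baseline = baseline, perBlock = perBlock,
       improvedFraction = if (length(blocks)) mean(perBlock$delta > 0) else 0,
       bestAlignments = bestAlns)
}

#' Task-routing priority order of puzzle blocks
#'
#' Orders blocks ascending by the number of times each has been played
#' (stable: equal counts keep their input order), so that puzzles with few
#' solutions come first -- the priority-queue routing of the casual game.
#'
#' @param blocks list of [PuzzleBlock-class].
#' @return the reordered list.
#' @export
prioritize <- function(blocks) {
  if (length(blocks) == 0L) return(list())
  blocks[order(vapply(blocks, timesPlayed, integer(1)))]
}
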