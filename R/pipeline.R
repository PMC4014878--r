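#' Pipeline run configuration
#'
#' One flat key-value document holding every tunable of the end-to-end
#' pipeline. Defaults are the deployed game constants: scores +1/-1/-4/-1,
#' acceptance window sd > 1 and ratio in [0.32, 0.38], casual width 20
#' (legal range 10-20), expert width 300 on a 400-column grid, top
#' fraction 0.4. Unknown keys are rejected.
#'
#' @param ... overrides of the default keys (see `runConfigDefaults()`).
#' @return a validated list of class `RunConfig`.
#' @export
runConfig <- function(...) {
  cfg <- runConfigDefaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  ## delegate validation to the per-stage constructors
  sp <- ScoringParams(cfg$match, cfg$mismatch, cfg$gapOpen, cfg$gapExtend,
                      cfg$openCoversFirst)
  ec <- extractionConfig(cfg$frameWidth, cfg$stddevMin, cfg$ratioMin,
                         cfg$ratioMax, cfg$expertWidth, cfg$expertStride)
  if (!(cfg$topFrac > 0 && cfg$topFrac <= 1))
    stop("'topFrac' must be in (0, 1]")
  structure(c(cfg, list(.params = sp, .extraction = ec)),
            class = "RunConfig")
}

#' Default pipeline configuration values
#' @return named list of defaults.
#' @export
runConfigDefaults <- function() {
  list(match = 1L, mismatch = -1L, gapOpen = -4L, gapExtend = -1L,
       openCoversFirst = TRUE,
       frameWidth = 20L, stddevMin = 1, ratioMin = 0.32, ratioMax = 0.38,
       expertWidth = 300L, expertStride = 150L,
       topFrac = 0.4, gridWidth = 400L,
       nLeaves = 12L, rootLength = 600L, subProb = 0.1, indelProb = 0.5,
       indelMean = 3, perturbMoves = 40L,
       solverIterations = 25L, solverRestarts = 2L,
       seed = 1L,
       alnPath = NULL, treePath = NULL, mode = "casual")
}

#' Run the full pipeline
#'
#' Wires the stages end to end: simulate a tree and alignment (or load
#' them from `alnPath`/`treePath`), extract casual puzzle blocks, run the
#' hill-climbing robot player on each block, evaluate the top fraction of
#' the admitted solutions by reinsertion into the full alignment, and
#' report the improved alignment. Deterministic given the configured
#' seed; every stage's parameters and counts appear in the report.
#'
#' @param cfg a [runConfig()].
#' @param quiet suppress progress messages?
#' @return a list with `aln` (input [PhyloMSA-class]), `tree`, `blocks`,
#'   `solutions`, `evaluation` (see [evaluateCandidates()]), `improved`
#'   (the best full alignment found), and `report` (flat summary list).
#' @export
runPipeline <- function(cfg = runConfig(), quiet = TRUE) {
  stopifnot(inherits(cfg, "RunConfig"))
  params <- cfg$.params
  ecfg <- cfg$.extraction
  say <- function(...) if (!quiet) message(sprintf(...))

  if (!is.null(cfg$alnPath)) {
    aln <- readAlignment(cfg$alnPath)
    tree <- readTree(cfg$treePath)
    say("loaded alignment %d x %d", nrow(aln), ncol(aln))
  } else {
    tree <- randomTree(cfg$nLeaves, cfg$seed)
    aln <- evolveAlignment(tree, simConfig(
      nLeaves = cfg$nLeaves, rootLength = cfg$rootLength,
      subProb = cfg$subProb, indelProb = cfg$indelProb,
      indelMean = cfg$indelMean, seed = cfg$seed))
    ## emulate the local inaccuracies of a computed input alignment
    if (cfg$perturbMoves > 0L)
      aln <- perturbAlignment(aln, cfg$perturbMoves, seed = cfg$seed + 7L)
    say("simulated alignment %d x %d (seed %d, %d perturbing slides)",
        nrow(aln), ncol(aln), cfg$seed, cfg$perturbMoves)
  }
  assertCompatible(aln, tree)

  blocks <- if (cfg$mode == "expert")
    extractExpertBlocks(aln, ecfg) else scanCasual(aln, ecfg)
  say("extracted %d %s blocks", length(blocks), cfg$mode)

  solutions <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    solutions[[i]] <- hillClimb(
      blocks[[i]], tree, params,
      solverConfig(maxIterations = cfg$solverIterations,
                   restarts = cfg$solverRestarts,
                   seed = cfg$seed + i, gridWidth = cfg$gridWidth))
  }
  say("solver produced %d solutions", sum(lengths(solutions)))

  ev <- evaluateCandidates(aln, tree, params, blocks, solutions,
                           frac = cfg$topFrac)
  improved <- aln
  bestTotal <- ev$baseline
  if (length(blocks)) {
    best <- which.max(ev$perBlock$bestScore)
    if (ev$perBlock$bestScore[best] > bestTotal) {
      improved <- ev$bestAlignments[[best]]
      bestTotal <- ev$perBlock$bestScore[best]
    }
  }
  report <- list(
    seed = cfg$seed, nRows = nrow(aln), nCols = ncol(aln),
    mode = cfg$mode, nBlocks = length(blocks),
    nSolutions = sum(lengths(solutions)),
    initialScore = ev$baseline, bestScore = bestTotal,
    scoreGain = bestTotal - ev$baseline,
    improvedFraction = ev$improvedFraction)
  say("initial score %d, best %d", report$initialScore, report$bestScore)
  list(aln = aln, tree = tree, blocks = blocks, solutions = solutions,
       evaluation = ev, improved = improved, report = report)
}

#' Serialize a score breakdown to a JSON-ready list
#'
#' @param x a [ScoreBreakdown-class].
#' @return list with integer `total` and the per-edge table.
#' @export
breakdownAsList <- function(x) {
  list(total = totalScore(x), perEdge = perEdgeScores(x))
}

#' Serialize puzzle blocks to a JSON-ready list
#'
#' Records the parent id, the 1-based inclusive column range, the included
#' rows and the snapshot as aligned strings.
#'
#' @param blocks list of [PuzzleBlock-class].
#' @return list of lists.
#' @export
blocksAsList <- function(blocks) {
  lapply(blocks, function(b) {
    list(parent = b@parentId, start = b@start, end = b@end, kind = b@kind,
         rows = b@rowIds, timesPlayed = b@timesPlayed,
         snapshot = as.list(alnStrings(blockSnapshot(b))))
  })
}
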