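#' Solver configuration
#'
#' Settings of the stochastic hill-climbing robot player that stands in
#' for human gamers.
#'
#' @param maxIterations improving moves attempted per restart (>= 0).
#' @param restarts number of independent climbs from the start state.
#' @param seed mandatory integer seed.
#' @param gridWidth game grid width: solutions may widen up to this many
#'   columns (400 on the expert grid).
#' @param seedFrom `"initial"` starts from the block snapshot;
#'   `"best_known"` starts from the best solution found so far
#'   (collaborative seeding), supplied via `bestKnown`.
#' @return a validated list of class `SolverConfig`.
#' @export
solverConfig <- function(maxIterations = 50L, restarts = 1L, seed,
                         gridWidth = 400L,
                         seedFrom = c("initial", "best_known")) {
  if (missing(seed)) stop("'seed' is mandatory for reproducibility")
  seedFrom <- match.arg(seedFrom)
  if (maxIterations < 0L) stop("'maxIterations' must be >= 0")
  if (restarts < 1L) stop("'restarts' must be >= 1")
  structure(list(maxIterations = as.integer(maxIterations),
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 gridWidth = as.integer(gridWidth), seedFrom = seedFrom),
            class = "SolverConfig")
}

#' Legal game moves from a block state
#'
#' Enumerates the moves a player can make: slide one maximal run of
#' nucleotides in one row by one column into an adjacent gap (left or
#' right), or widen the grid by one all-gap column at either end while
#' the state is narrower than `gridWidth`. Every move preserves each
#' row's nucleotide content, and every slide is reversible by the
#' opposite slide.
#'
#' @param state character matrix (rows x columns) over `{A,C,G,T,-}`.
#' @param gridWidth maximal width.
#' @return list of moves; a slide is
#'   `list(type = "slide", row, start, end, dir)` (`dir` is -1 or +1), a
#'   widening is `list(type = "widen", side)` (`"left"` or `"right"`).
#' @export
legalMoves <- function(state, gridWidth = 400L) {
  moves <- list()
  nc <- ncol(state)
  for (i in seq_len(nrow(state))) {
    r <- rle(state[i, ] != GAP)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      if (starts[k] > 1L && state[i, starts[k] - 1L] == GAP)
        moves[[length(moves) + 1L]] <-
          list(type = "slide", row = i, start = starts[k], end = ends[k],
               dir = -1L)
      if (ends[k] < nc && state[i, ends[k] + 1L] == GAP)
        moves[[length(moves) + 1L]] <-
          list(type = "slide", row = i, start = starts[k], end = ends[k],
               dir = 1L)
    }
  }
  if (nc < gridWidth) {
    moves[[length(moves) + 1L]] <- list(type = "widen", side = "left")
    moves[[length(moves) + 1L]] <- list(type = "widen", side = "right")
  }
  moves
}

#' Apply a legal move to a block state
#'
#' @param state character matrix.
#' @param move a move from [legalMoves()].
#' @return the new character matrix.
#' @export
applyMove <- function(state, move) {
  if (move$type == "widen") {
    ids <- rownames(state)
    pad <- matrix(GAP, nrow = nrow(state), ncol = 1L)
    state <- if (move$side == "left") cbind(pad, state) else cbind(state, pad)
    rownames(state) <- ids
    return(state)
  }
  run <- state[move$row, move$start:move$end]
  state[move$row, (move$start + move$dir):(move$end + move$dir)] <- run
  vacated <- if (move$dir < 0L) move$end else move$start
  state[move$row, vacated] <- GAP
  state
}

#' Hill-climbing robot player
#'
#' First-improvement stochastic hill climbing over the legal game moves:
#' in each iteration the moves are enumerated in a seeded random order and
#' the first move that strictly improves the game score (on the tree
#' restricted to the block's rows) is applied; the climb stops at a local
#' optimum or after `maxIterations` improving steps. Every state visited
#' with a score greater than or equal to the initial block's score is
#' recorded as an admissible solution (the snapshot itself is always
#' solution #1), so the best recorded score is never below the initial
#' score and is non-decreasing within a restart. Restarts rerun the climb
#' from the start state with a fresh move order to diversify solutions.
#' Deterministic given `cfg$seed`.
#'
#' @param block a [PuzzleBlock-class].
#' @param tree the full `ape::phylo` (pruned internally to the block's
#'   rows).
#' @param params a [ScoringParams-class].
#' @param cfg a [solverConfig()].
#' @param bestKnown optional [PuzzleSolution-class] used as the start
#'   state when `cfg$seedFrom == "best_known"`.
#' @return list of [PuzzleSolution-class] (unique states, in discovery
#'   order, sequence-numbered from 1).
#' @export
hillClimb <- function(block, tree, params = ScoringParams(),
                      cfg = solverConfig(seed = 1L), bestKnown = NULL) {
  rows <- blockRows(block)
  sub <- if (length(rows) == length(tree$tip.label)) tree
         else restrictTree(tree, rows)
  scoreOf <- function(m) totalScore(gameScore(PhyloMSA(m), sub, params))
  snap <- block@snapshot
  initScore <- scoreOf(snap)
  start <- snap
  if (cfg$seedFrom == "best_known") {
    if (is.null(bestKnown))
      stop("seedFrom = \"best_known\" requires 'bestKnown'")
    start <- solutionMatrix(bestKnown)
  }
  if (ncol(start) > cfg$gridWidth)
    stop("block is wider than the solver grid")

  sols <- list()
  seen <- character(0)
  record <- function(m, score) {
    sig <- paste0(apply(m, 1L, paste0, collapse = ""), collapse = "|")
    if (sig %in% seen) return(invisible(NULL))
    seen[[length(seen) + 1L]] <<- sig
    sols[[length(sols) + 1L]] <<- PuzzleSolution(
      blockKey(block), m, score, submitter = "robot",
      seqNo = length(sols) + 1L)
  }
  record(snap, initScore)
  if (cfg$seedFrom == "best_known") {
    startScore <- scoreOf(start)
    if (startScore >= initScore) record(start, startScore)
  }

  withSeed(cfg$seed, {
    for (r in seq_len(cfg$restarts)) {
      state <- start
      current <- scoreOf(state)
      iter <- 0L
      while (iter < cfg$maxIterations) {
        moves <- legalMoves(state, cfg$gridWidth)
        if (length(moves) == 0L) break
        improved <- FALSE
        for (mv in sample(seq_along(moves))) {
          cand <- applyMove(state, moves[[mv]])
          s <- scoreOf(cand)
          if (s > current) {
            state <- cand
            current <- s
            if (s >= initScore) record(state, s)
            improved <- TRUE
            break
          }
        }
        if (!improved) break
        iter <- iter + 1L
      }
    }
  })
  sols
}
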