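## shared fixture: a 4-species alignment with a plantable region
crowdFixture <- function(seed = 17) {
  set.seed(seed)
  tr <- readTree("((a,b),(c,d));")
  aln <- randAln(4, 40, gapProb = 0.2)
  rownames(aln@seqs) <- c("a", "b", "c", "d")
  aln <- plantCasualFrame(aln, 11)
  block <- manualBlock(aln, 11, 30)
  list(tree = tr, aln = aln, block = block)
}

test_that("admission accepts equal scores, rejects worse, errors on edits", {
  fx <- crowdFixture()
  ## identical candidate: the equality branch of "higher than or equal"
  sol <- admit(fx$block, fx$block@snapshot, fx$tree)
  expect_s4_class(sol, "PuzzleSolution")
  init <- solutionScore(sol)
  ## deleting a nucleotide is an illegal edit
  cand <- fx$block@snapshot
  nucPos <- which(cand[1, ] != "-")[1]
  cand[1, nucPos] <- "-"
  expect_error(admit(fx$block, cand, fx$tree), "illegal edit")
  ## exceeding the grid is an overflow
  wide <- cbind(fx$block@snapshot,
                matrix("-", 4, 30, dimnames = list(rownames(fx$block@snapshot),
                                                   NULL)))
  expect_error(admit(fx$block, wide, fx$tree, gridWidth = 40L),
               "grid overflow")
  ## a candidate scoring below the initial block is rejected, not an error
  worse <- NULL
  for (i in seq_len(200)) {
    cand <- fx$block@snapshot
    mv <- legalMoves(cand, gridWidth = 25L)
    mv <- Filter(function(m) m$type == "slide", mv)
    for (m in sample(mv, min(4, length(mv)))) cand <- applyMove(cand, m)
    s <- totalScore(gameScore(PhyloMSA(cand), fx$tree))
    if (s < init) { worse <- cand; break }
  }
  expect_false(is.null(worse))
  expect_null(admit(fx$block, worse, fx$tree))
})

test_that("ranking sorts by score with earlier submissions winning ties", {
  fx <- crowdFixture()
  mkSol <- function(score, seqNo)
    methods::new("PuzzleSolution",
                 blockKey = phyloPuzzle:::blockKey(fx$block),
                 seqs = fx$block@snapshot, score = as.integer(score),
                 submitter = "", seqNo = as.integer(seqNo))
  ranked <- rankSolutions(list(mkSol(5, 1), mkSol(9, 2), mkSol(7, 3)))
  expect_equal(vapply(ranked, solutionScore, integer(1)), c(9L, 7L, 5L))
  tied <- rankSolutions(list(mkSol(7, 2), mkSol(7, 1)))
  expect_equal(vapply(tied, function(s) s@seqNo, integer(1)), c(1L, 2L))
  expect_equal(rankSolutions(list()), list())
  other <- mkSol(3, 9)
  other@blockKey <- "elsewhere:1-20"
  expect_error(rankSolutions(list(mkSol(1, 1), other)), "different blocks")
})

test_that("top-fraction selection uses the ceiling rule", {
  fx <- crowdFixture()
  mkSol <- function(seqNo)
    methods::new("PuzzleSolution",
                 blockKey = phyloPuzzle:::blockKey(fx$block),
                 seqs = fx$block@snapshot, score = 100L - seqNo,
                 submitter = "", seqNo = as.integer(seqNo))
  sols50 <- rankSolutions(lapply(1:50, mkSol))
  expect_equal(length(topFraction(sols50, 0.4)), 20L)
  expect_identical(topFraction(sols50, 1.0), sols50)
  expect_equal(length(topFraction(rankSolutions(lapply(1:3, mkSol)), 0.4)),
               2L)  # ceiling(1.2)
  expect_error(topFraction(sols50, 0), "frac")
})

test_that("reinsertion is exact for snapshots and tracks width changes", {
  fx <- crowdFixture()
  ## snapshot round-trip is bit-identical
  expect_identical(alnMatrix(reinsert(fx$aln, fx$block, fx$block@snapshot)),
                   alnMatrix(fx$aln))
  ## widening by two columns grows the parent by exactly two columns
  sol <- fx$block@snapshot
  sol <- applyMove(sol, list(type = "widen", side = "left"))
  sol <- applyMove(sol, list(type = "widen", side = "right"))
  mv <- Filter(function(m) m$type == "slide", legalMoves(sol))
  sol2 <- applyMove(sol, mv[[1]])  # occupy a new column so it survives
  out <- reinsert(fx$aln, fx$block, sol2)
  expect_true(ncol(out) <= ncol(fx$aln) + 2L)
  expect_equal(ncol(out),
               ncol(fx$aln) - blockWidth(fx$block) +
                 sum(colSums(sol2 != "-") > 0))
  ## conservation: every row's ungapped sequence is unchanged
  for (r in rowIds(fx$aln))
    expect_identical(degap(alnMatrix(out)[r, ]),
                     degap(alnMatrix(fx$aln)[r, ]))
  ## a block cut from a different alignment is refused
  other <- randAln(4, 40, gapProb = 0.1)
  rownames(other@seqs) <- c("a", "b", "c", "d")
  expect_error(reinsert(other, fx$block, fx$block@snapshot),
               "block/alignment mismatch")
})

test_that("candidate evaluation selects the best reinsertion per block", {
  fx <- crowdFixture()
  base <- totalScore(gameScore(fx$aln, fx$tree))
  snapSol <- admit(fx$block, fx$block@snapshot, fx$tree, seqNo = 1L)
  ## empty solution sets: no improvement, delta 0
  ev0 <- evaluateCandidates(fx$aln, fx$tree, blocks = list(fx$block),
                            solutions = list(list()))
  expect_equal(ev0$improvedFraction, 0)
  expect_equal(ev0$perBlock$delta, 0)
  ## a lone snapshot solution: delta 0, baseline preserved
  ev1 <- evaluateCandidates(fx$aln, fx$tree, blocks = list(fx$block),
                            solutions = list(list(snapSol)))
  expect_equal(ev1$perBlock$delta, 0)
  expect_equal(ev1$baseline, base)
  ## plant an improving solution via the solver and verify the delta
  sols <- hillClimb(fx$block, fx$tree,
                    cfg = solverConfig(maxIterations = 40, restarts = 3,
                                       seed = 23))
  best <- max(vapply(sols, solutionScore, integer(1)))
  ev2 <- evaluateCandidates(fx$aln, fx$tree, blocks = list(fx$block),
                            solutions = list(sols))
  expect_gte(ev2$perBlock$bestScore, base)
  ## with the snapshot among candidates the best score never drops
  expect_gte(ev2$perBlock$delta, 0)
  if (best > solutionScore(snapSol))
    expect_gt(ev2$perBlock$delta, 0)
  ## a failing scorer is surfaced per block, not fatal
  calls <- 0L
  flaky <- function(a) {
    calls <<- calls + 1L
    if (calls > 1L) stop("boom") else 0
  }
  evF <- evaluateCandidates(fx$aln, fx$tree, blocks = list(fx$block),
                            solutions = list(list(snapSol)), scorer = flaky)
  expect_equal(evF$perBlock$nFailed, 1L)
})

test_that("task routing orders blocks by play count, stably", {
  fx <- crowdFixture()
  mkBlock <- function(played) {
    b <- fx$block
    b@timesPlayed <- as.integer(played)
    b
  }
  ord <- prioritize(list(mkBlock(3), mkBlock(0), mkBlock(5)))
  expect_equal(vapply(ord, timesPlayed, integer(1)), c(0L, 3L, 5L))
  same <- prioritize(list(mkBlock(2), mkBlock(2), mkBlock(2)))
  expect_equal(length(same), 3L)
  expect_equal(prioritize(list()), list())
})
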