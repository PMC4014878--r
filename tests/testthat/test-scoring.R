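twoLeaf <- readTree("(X,Y);")
fourLeaf <- readTree("((a,b),(c,d));")

test_that("Fitch reconstruction handles forced, split and tied columns", {
  ## identical leaves: ancestor forced equal
  anc <- inferAncestors(PhyloMSA(c(X = "ACGT", Y = "ACGT")), twoLeaf)
  expect_equal(ancestorStrings(anc)[["3"]], "ACGT")
  expect_equal(sum(columnCounts(anc)), 0L)

  ## (A,A,C,C) on ((a,b),(c,d)): internal nodes A and C, root tie -> A
  anc <- inferAncestors(PhyloMSA(c(a = "A", b = "A", c = "C", d = "C")),
                        fourLeaf)
  labs <- ancestorStrings(anc)
  expect_setequal(unname(labs[c("6", "7")]), c("A", "C"))
  expect_equal(labs[["5"]], "A")        # root tie broken to the smallest state
  expect_equal(columnCounts(anc), 1L)

  ## (A, -) tie: both states are Fitch-minimal; tie-break picks A
  anc <- inferAncestors(PhyloMSA(c(X = "A", Y = "-")), twoLeaf)
  expect_equal(ancestorStrings(anc)[["3"]], "A")
  expect_equal(columnCounts(anc), 1L)
})

test_that("per-column substitution counts attain the exhaustive minimum", {
  set.seed(101)
  for (i in 1:15) {
    nl <- sample(2:5, 1)
    tr <- randomTree(nl, seed = 200 + i)
    aln <- randAln(nl, sample(3:8, 1), gapProb = 0.3, allowAllGapRow = TRUE)
    rownames(aln@seqs) <- tr$tip.label
    expect_identical(columnCounts(inferAncestors(aln, tr)),
                     exhaustiveParsimonyCounts(aln, tr))
  }
})

test_that("induced pairwise alignment drops exactly the both-gap columns", {
  expect_equal(inducedPairwise("A-C", "A-C")[c("s1", "s2")],
               list(s1 = c("A", "C"), s2 = c("A", "C")))
  p <- inducedPairwise("ACGT", "ACGT")
  expect_equal(p$dropped, 0L)
  expect_equal(paste0(p$s1, collapse = ""), "ACGT")
  p <- inducedPairwise("--", "A-")
  expect_equal(list(p$s1, p$s2), list("-", "A"))
  expect_error(inducedPairwise("AC", "ACG"), "unequal lengths")
})

test_that("affine pairwise scoring follows the run and terminal rules", {
  expect_equal(scorePairwise("AC--GT", "ACAAGT"), -1L)   # 4 - 4 - 1
  expect_equal(scorePairwise("--ACGT", "GGACGT"), 4L)    # leading run free
  expect_equal(scorePairwise("ACGT", "ACGT"), 4L)
  expect_equal(scorePairwise("ACGT", "ACGA"), 2L)        # 3 matches - 1
  ## trailing run free on either sequence
  expect_equal(scorePairwise("ACGT--", "ACGTGG"), 4L)
  expect_equal(scorePairwise("ACGTGG", "ACGT--"), 4L)
  ## a both-gap column must have been removed upstream
  expect_error(scorePairwise(list(s1 = c("A", "-"), s2 = c("A", "-"))),
               "unnormalized pair")
  ## alternative affine convention: run of length k costs open + k*extend
  alt <- ScoringParams(openCoversFirst = FALSE)
  expect_equal(scorePairwise("AC--GT", "ACAAGT", params = alt), -2L)
})

test_that("pairwise scoring agrees with the two-state scanner oracle", {
  set.seed(77)
  for (i in 1:100) {
    L <- sample(2:40, 1)
    p <- inducedPairwise(randGappedSeq(L), randGappedSeq(L))
    expect_identical(scorePairwise(p), affineScanOracle(p$s1, p$s2))
  }
})

test_that("game score sums per-edge scores and matches hand-worked cases", {
  bd <- gameScore(PhyloMSA(c(X = "ACGT", Y = "ACGT")), twoLeaf)
  expect_equal(totalScore(bd), 8L)
  expect_equal(sum(perEdgeScores(bd)$score), totalScore(bd))
  expect_equal(perEdgeScores(bd)$score, c(4L, 4L))
  ## one match + one mismatch whatever root state is picked
  expect_equal(totalScore(gameScore(PhyloMSA(c(X = "A", Y = "C")),
                                    twoLeaf)), 0L)
})

test_that("inserting an all-gap column never changes the game score", {
  set.seed(42)
  tr <- randomTree(5, 9)
  aln <- randAln(5, 20, gapProb = 0.25)
  rownames(aln@seqs) <- tr$tip.label
  ref <- totalScore(gameScore(aln, tr))
  for (pos in sample(0:20, 10, replace = TRUE)) {
    m <- alnMatrix(aln)
    m2 <- cbind(m[, seq_len(pos), drop = FALSE],
                matrix("-", 5, 1),
                m[, seq_len(20 - pos) + pos, drop = FALSE])
    expect_identical(totalScore(gameScore(PhyloMSA(m2), tr)), ref)
  }
})

test_that("appending a conserved column adds match * (2n - 2)", {
  ## the property concerns alignments whose final column is gap-free:
  ## otherwise the appended column turns a free terminal gap run into a
  ## charged internal one
  set.seed(43)
  for (nl in c(3L, 5L, 8L)) {
    tr <- randomTree(nl, nl)
    aln <- randAln(nl, 15, gapProb = 0.2)
    m <- alnMatrix(aln)
    m[, 15] <- sample(c("A", "C", "G", "T"), nl, replace = TRUE)
    rownames(m) <- tr$tip.label
    ref <- totalScore(gameScore(PhyloMSA(m), tr))
    m2 <- cbind(m, matrix("G", nl, 1))
    expect_identical(totalScore(gameScore(PhyloMSA(m2), tr)),
                     ref + 1L * (2L * nl - 2L))
  }
})

test_that("consistent leaf and row relabeling never changes the total", {
  set.seed(44)
  tr <- randomTree(6, 13)
  aln <- randAln(6, 18, gapProb = 0.25)
  rownames(aln@seqs) <- tr$tip.label
  ref <- totalScore(gameScore(aln, tr))
  relabel <- stats::setNames(paste0("sp_", rev(seq_len(6))), tr$tip.label)
  tr2 <- tr
  tr2$tip.label <- unname(relabel[tr$tip.label])
  m2 <- alnMatrix(aln)
  rownames(m2) <- unname(relabel[rownames(m2)])
  expect_identical(totalScore(gameScore(PhyloMSA(m2), tr2)), ref)
})

test_that("scoring under supplied ancestors reproduces and extends Fitch", {
  tr <- randomTree(4, 21)
  aln <- randAln(4, 12, gapProb = 0.3)
  rownames(aln@seqs) <- tr$tip.label
  fitch <- inferAncestors(aln, tr)
  expect_identical(totalScore(scoreWithAncestors(aln, tr, fitch)),
                   totalScore(gameScore(aln, tr)))
  ## names may carry a "node" prefix
  labs <- ancestorStrings(fitch)
  names(labs) <- paste0("node", names(labs))
  expect_identical(totalScore(scoreWithAncestors(aln, tr, labs)),
                   totalScore(gameScore(aln, tr)))
  ## malformed labelings
  short <- ancestorStrings(fitch)
  short[[1]] <- substr(short[[1]], 1, 3)
  expect_error(scoreWithAncestors(aln, tr, short), "wrong length")
  expect_error(scoreWithAncestors(aln, tr, ancestorStrings(fitch)[-1]),
               "missing node")
  bad <- ancestorStrings(fitch)
  substr(bad[[1]], 1, 1) <- "N"
  expect_error(scoreWithAncestors(aln, tr, bad), "illegal character")
})

test_that("a merged-gap ancestral labeling can strictly beat Fitch", {
  fx <- suboptimalAncestorFixture()
  fitchTotal <- totalScore(gameScore(fx$aln, fx$tree))
  editedTotal <- totalScore(scoreWithAncestors(fx$aln, fx$tree, fx$edited))
  expect_identical(fitchTotal, 16L)
  expect_identical(editedTotal, 18L)
  expect_gt(editedTotal, fitchTotal)
})

test_that("the N wildcard mismatches everything but never acts as a gap", {
  aln <- PhyloMSA(c(X = "AN", Y = "AN"), allowN = TRUE)
  ## col 2: both leaves wildcard -> ancestor is a nucleotide, N pairs score -1
  expect_equal(totalScore(gameScore(aln, twoLeaf)), 0L)
})
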