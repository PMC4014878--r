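## run expr with a private, seeded RNG stream, restoring the caller's state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Parameters of the seeded tree/alignment simulator used to exercise
#' every pipeline stage without external data. Defaults emulate a small
#' promoter-scale study instance: 12 species, 600 alignment columns,
#' moderate divergence per edge.
#'
#' @param nLeaves number of leaves (>= 2).
#' @param rootLength number of root sequence columns (>= 1).
#' @param subProb per-site, per-edge substitution probability (a
#'   substituted site is resampled uniformly from `A,C,G,T`, so it may
#'   keep its state).
#' @param indelProb probability of one indel event per edge.
#' @param indelMean geometric mean indel length (columns).
#' @param seed mandatory integer seed; all randomness derives from it.
#' @return a validated list of class `SimConfig`.
#' @export
simConfig <- function(nLeaves = 12L, rootLength = 600L, subProb = 0.1,
                      indelProb = 0.5, indelMean = 3, seed) {
  if (missing(seed)) stop("'seed' is mandatory for reproducibility")
  if (nLeaves < 2L) stop("'nLeaves' must be >= 2")
  if (rootLength < 1L) stop("'rootLength' must be >= 1")
  if (subProb < 0 || subProb > 1 || indelProb < 0 || indelProb > 1)
    stop("probabilities must be in [0, 1]")
  if (indelMean < 1) stop("'indelMean' must be >= 1")
  structure(list(nLeaves = as.integer(nLeaves),
                 rootLength = as.integer(rootLength),
                 subProb = subProb, indelProb = indelProb,
                 indelMean = indelMean, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Random rooted binary tree
#'
#' A uniformly shaped random rooted binary tree with leaves labeled
#' `L1..Ln`; deterministic given the seed.
#'
#' @param nLeaves number of leaves (>= 2).
#' @param seed integer seed.
#' @return an `ape::phylo`.
#' @export
randomTree <- function(nLeaves, seed) {
  if (nLeaves < 2L) stop("'nLeaves' must be >= 2")
  withSeed(seed, {
    tr <- ape::rtree(nLeaves, rooted = TRUE,
                     tip.label = paste0("L", seq_len(nLeaves)))
    validateTree(tr)
    tr
  })
}

#' Evolve a gapped alignment down a tree
#'
#' Simulates sequence evolution along each edge of the tree: the root
#' sequence is i.i.d. uniform over `A,C,G,T`; on each edge every site is
#' resampled uniformly with probability `subProb`, and with probability
#' `indelProb` a single indel event of geometric length occurs (deletion
#' or insertion with equal probability, uniform position, uniform `ACGT`
#' insertion content). True homology is preserved as alignment columns:
#' gaps mark where a lineage lost a site or never had an inserted one.
#' Columns gapped in every leaf (sites seen only by internal lineages)
#' are not emitted. Deterministic given `cfg$seed`.
#'
#' @param tree an `ape::phylo`; leaf count must equal `cfg$nLeaves`.
#' @param cfg a [simConfig()].
#' @return a [PhyloMSA-class] with rows in tip order.
#' @export
evolveAlignment <- function(tree, cfg) {
  validateTree(tree)
  n <- length(tree$tip.label)
  if (n != cfg$nLeaves)
    stop("tree has ", n, " leaves but cfg expects ", cfg$nLeaves)
  withSeed(cfg$seed + 1L, {
    ord <- treeOrders(tree)
    ## master ordered list of site ids; each node sequence is a character
    ## vector named by site id, a subsequence of the master order
    master <- as.character(seq_len(cfg$rootLength))
    nextId <- cfg$rootLength + 1L
    seqs <- vector("list", n + tree$Nnode)
    rootSeq <- sample(c("A", "C", "G", "T"), cfg$rootLength, replace = TRUE)
    names(rootSeq) <- master
    seqs[[ord$root]] <- rootSeq
    for (v in ord$topDown) {
      for (w in ord$children[[v]]) {
        s <- seqs[[v]]
        ## substitutions: uniform resampling
        hit <- stats::runif(length(s)) < cfg$subProb
        if (any(hit))
          s[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
        ## at most one indel event per edge
        if (stats::runif(1) < cfg$indelProb && length(s) > 1L) {
          len <- stats::rgeom(1, 1 / cfg$indelMean) + 1L
          if (stats::runif(1) < 0.5) {
            ## deletion of a run of sites from this lineage
            len <- min(len, length(s) - 1L)
            at <- sample.int(length(s) - len + 1L, 1L)
            s <- s[-(at:(at + len - 1L))]
          } else {
            ## insertion of new sites, registered in the master order
            at <- sample.int(length(s) + 1L, 1L) - 1L  # after this position
            ids <- as.character(nextId:(nextId + len - 1L))
            nextId <- nextId + len
            newChars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
            names(newChars) <- ids
            mpos <- if (at == 0L) 0L else match(names(s)[at], master)
            master <- append(master, ids, after = mpos)
            s <- append(s, newChars, after = at)
          }
        }
        seqs[[w]] <- s
      }
    }
    m <- matrix(GAP, nrow = n, ncol = length(master),
                dimnames = list(tree$tip.label, NULL))
    for (i in seq_len(n)) {
      s <- seqs[[i]]
      m[i, match(names(s), master)] <- unname(s)
    }
    m <- m[, colSums(m != GAP) > 0L, drop = FALSE]
    PhyloMSA(m)
  })
}

#' Plant a frame that passes the casual acceptance filter
#'
#' Rewrites the `width` columns starting at `start` so that the frame's
#' recomputed statistics satisfy [acceptFrame()]: per-column blocks of an
#' identical nucleotide among a prefix of rows are sized greedily so the
#' match ratio lands mid-window, and the uneven per-row gap pattern this
#' creates drives the count standard deviation above the threshold.
#' Columns outside the frame are untouched.
#'
#' @param aln a [PhyloMSA-class] with at least 3 rows.
#' @param start first frame column (1-based).
#' @param width frame width (defaults to `cfg$frameWidth`).
#' @param cfg an [extractionConfig()] carrying the target thresholds.
#' @return the modified [PhyloMSA-class].
#' @export
plantCasualFrame <- function(aln, start, width = cfg$frameWidth,
                             cfg = extractionConfig()) {
  m <- alnMatrix(aln)
  n <- nrow(m)
  if (start < 1L || start + width - 1L > ncol(m)) stop("frame out of bounds")
  if (cfg$ratioMax > 1 || cfg$ratioMin <= 0)
    stop("infeasible target: match ratio must lie in (0, 1]")
  if (n < 3L)
    stop("infeasible target: need at least 3 rows")
  pairsPerCol <- choose(n, 2)
  target <- round((cfg$ratioMin + cfg$ratioMax) / 2 * pairsPerCol * width)
  ## per column, k rows sharing one nucleotide contribute choose(k,2) matches
  ks <- integer(width)
  remaining <- target
  for (j in seq_len(width)) {
    k <- n
    while (k > 1L && choose(k, 2) > remaining) k <- k - 1L
    ks[j] <- if (choose(k, 2) <= remaining && k >= 2L) k else 1L
    if (ks[j] >= 2L) remaining <- remaining - choose(ks[j], 2)
  }
  if (remaining > 0L) stop("infeasible target: ratio not reachable")
  bases <- rep(c("A", "C", "G", "T"), length.out = width)
  frame <- matrix(GAP, nrow = n, ncol = width)
  for (j in seq_len(width)) frame[seq_len(ks[j]), j] <- bases[j]
  m[, start:(start + width - 1L)] <- frame
  out <- PhyloMSA(m, allowN = aln@allowN)
  st <- frameStats(out, start, width, cfg)
  if (!acceptFrame(st, cfg))
    stop("infeasible target: planted frame fails the filter (sd ",
         signif(st$sd, 3), ", ratio ", signif(st$matchRatio, 3), ")")
  out
}

#' Perturb an alignment with random content-preserving slides
#'
#' Applies `nMoves` random legal slide moves (one maximal nucleotide run
#' moved one column into an adjacent gap) to random rows, emulating the
#' local inaccuracies of a computed alignment: every row's ungapped
#' sequence is untouched, only the gap placement degrades. This is how
#' the simulator produces improvable pipeline inputs from the simulated
#' truth. Deterministic given the seed.
#'
#' @param aln a [PhyloMSA-class].
#' @param nMoves number of random slides to apply.
#' @param seed integer seed.
#' @return the perturbed [PhyloMSA-class].
#' @export
perturbAlignment <- function(aln, nMoves = 30L, seed) {
  if (missing(seed)) stop("'seed' is mandatory for reproducibility")
  m <- alnMatrix(aln)
  withSeed(seed, {
    for (i in seq_len(nMoves)) {
      mv <- Filter(function(x) x$type == "slide",
                   legalMoves(m, gridWidth = ncol(m)))
      if (length(mv) == 0L) break
      m <- applyMove(m, mv[[sample.int(length(mv), 1L)]])
    }
  })
  PhyloMSA(m, allowN = aln@allowN)
}

#' Fixture where an edited ancestral labeling beats Fitch
#'
#' A minimal constructed instance demonstrating that the column-wise Fitch
#' reconstruction can be sub-optimal under the affine, terminal-gap-free
#' scoring model. On the tree `((a,b),(c,d))` with rows `a = AA--`,
#' `b = AA-C`, `c = d = AACC`, Fitch labels the `(a,b)` ancestor `AA-C`
#' (the parent's `C` propagates into the tie at the last column), leaving
#' a non-terminal single-column gap that costs a full gap opening on the
#' edge to the root. Relabeling that ancestor `AA--` merges the gap into
#' a terminal run, which is free, and strictly raises the total score.
#'
#' @return a list with `aln`, `tree`, `fitch` (the [AncestralLabeling-class]
#'   from [inferAncestors()]), and `edited` (a named character vector for
#'   [scoreWithAncestors()] with the merged-gap ancestor).
#' @export
suboptimalAncestorFixture <- function() {
  aln <- PhyloMSA(c(a = "AA--", b = "AA-C", c = "AACC", d = "AACC"))
  tree <- readTree("((a,b),(c,d));")
  fitch <- inferAncestors(aln, tree)
  edited <- ancestorStrings(fitch)
  ## the internal node whose children are leaves a and b
  ab <- treeParent(tree, match("a", tree$tip.label))
  edited[[as.character(ab)]] <- "AA--"
  list(aln = aln, tree = tree, fitch = fitch, edited = edited)
}
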