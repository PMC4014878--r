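## Independent oracles and random-instance generators. Everything here is
## deliberately written differently from the package implementation
## (enumeration and position-by-position scans instead of bit masks and
## run-length encoding) so the two can check each other.

STATES5 <- c("A", "C", "G", "T", "-")

## exhaustive minimum per-column parsimony count (gap as fifth state):
## enumerate every assignment of the internal nodes over the 5 states and
## count edges whose endpoints differ
exhaustiveParsimonyCounts <- function(aln, tree) {
  n <- length(tree$tip.label)
  I <- tree$Nnode
  A <- as.matrix(expand.grid(rep(list(1:5), I)))
  m <- alnMatrix(aln)
  chmap <- stats::setNames(1:5, STATES5)
  edges <- tree$edge
  vapply(seq_len(ncol(m)), function(j) {
    leafState <- chmap[m[tree$tip.label, j]]
    cost <- integer(nrow(A))
    for (e in seq_len(nrow(edges))) {
      p <- edges[e, 1L] - n
      ch <- edges[e, 2L]
      cost <- cost + if (ch <= n) (A[, p] != leafState[[ch]])
                     else (A[, p] != A[, ch - n])
    }
    as.integer(min(cost))
  }, integer(1))
}

## independent two-state (in-gap / not-in-gap) affine scanner; expects a
## pair with no both-gap columns
affineScanOracle <- function(x, y, params = ScoringParams()) {
  L <- length(x)
  if (L == 0L) return(0L)
  terminalPos <- function(s) {
    g <- s == "-"
    lead <- if (g[1L]) seq_len(which.min(g) - 1L) else integer(0)
    if (all(g)) lead <- seq_len(L)
    trail <- if (g[L] && !all(g)) (L - which.min(rev(g)) + 2L):L else integer(0)
    c(lead, trail)
  }
  tx <- terminalPos(x); ty <- terminalPos(y)
  score <- 0L
  inGapX <- FALSE; inGapY <- FALSE
  for (i in seq_len(L)) {
    gx <- x[i] == "-"; gy <- y[i] == "-"
    if (gx && !(i %in% tx)) {
      score <- score + if (inGapX) params@gapExtend else
        params@gapOpen + (if (params@openCoversFirst) 0L else params@gapExtend)
      inGapX <- TRUE
    } else inGapX <- FALSE
    if (gy && !(i %in% ty)) {
      score <- score + if (inGapY) params@gapExtend else
        params@gapOpen + (if (params@openCoversFirst) 0L else params@gapExtend)
      inGapY <- TRUE
    } else inGapY <- FALSE
    if (!gx && !gy) {
      score <- score + if (x[i] == y[i] && x[i] != "N")
        params@match else params@mismatch
    }
  }
  as.integer(score)
}

## brute-force reference of the casual scan: naive statistics (explicit
## double loops) and an explicit jump/shift loop
refFrameAccept <- function(m, start, width, cfg) {
  fr <- m[, start:(start + width - 1L), drop = FALSE]
  counts <- apply(fr, 1L, function(r) sum(r != "-"))
  mu <- mean(counts)
  sdPop <- sqrt(sum((counts - mu)^2) / length(counts))
  matched <- 0L
  for (j in seq_len(width)) {
    for (a in seq_len(nrow(fr) - 1L)) {
      for (b in (a + 1L):nrow(fr)) {
        if (fr[a, j] != "-" && fr[a, j] != "N" && fr[a, j] == fr[b, j])
          matched <- matched + 1L
      }
    }
  }
  ratio <- matched / (choose(nrow(fr), 2) * width)
  sdPop > cfg$stddevMin && ratio >= cfg$ratioMin && ratio <= cfg$ratioMax
}

refCasualScan <- function(aln, cfg) {
  m <- alnMatrix(aln)
  w <- cfg$frameWidth
  out <- list()
  s <- 1L
  while (s + w - 1L <= ncol(m)) {
    if (refFrameAccept(m, s, w, cfg)) {
      region <- m[, s:(s + w - 1L), drop = FALSE]
      rows <- rownames(region)[apply(region, 1L, function(r) any(r != "-"))]
      if (length(rows) >= 2L) {
        out[[length(out) + 1L]] <- list(start = s, end = s + w - 1L,
                                        rows = rows)
        s <- s + w
        next
      }
    }
    s <- s + 1L
  }
  out
}

## random gapped alignment (uniform characters, iid gaps)
randAln <- function(nRows, nCols, gapProb = 0.2, allowAllGapRow = FALSE) {
  repeat {
    chars <- sample(c("A", "C", "G", "T"), nRows * nCols, replace = TRUE)
    gaps <- stats::runif(nRows * nCols) < gapProb
    chars[gaps] <- "-"
    m <- matrix(chars, nrow = nRows,
                dimnames = list(paste0("s", seq_len(nRows)), NULL))
    if (allowAllGapRow || all(rowSums(m != "-") > 0L)) return(PhyloMSA(m))
  }
}

randGappedSeq <- function(len, gapProb = 0.3) {
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  s[stats::runif(len) < gapProb] <- "-"
  s
}

degap <- function(chars) paste0(chars[chars != "-"], collapse = "")
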