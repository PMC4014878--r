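#' Extraction configuration
#'
#' Parameters of the sliding-window puzzle extraction protocol. Defaults
#' are the deployed constants: casual frames are 20 columns (legal range
#' 10-20), a frame is accepted when the standard deviation of the per-row
#' ungapped nucleotide counts exceeds 1 and the column-wise pairwise match
#' ratio lies in [0.32, 0.38]; expert blocks are 300 columns, cut every
#' 150 columns so that neighbours overlap by half.
#'
#' @param frameWidth casual frame width in columns, in `[10, 20]`.
#' @param stddevMin acceptance threshold on the count standard deviation
#'   (strict: the frame passes when `sd > stddevMin`).
#' @param ratioMin,ratioMax inclusive acceptance window on the match ratio.
#' @param expertWidth expert block width in columns (at most 300).
#' @param expertStride distance between consecutive expert block starts.
#' @param sdType `"population"` (divide by n, default) or `"sample"`
#'   (divide by n-1) standard deviation.
#' @return a validated list of class `ExtractionConfig`.
#' @export
extractionConfig <- function(frameWidth = 20L, stddevMin = 1,
                             ratioMin = 0.32, ratioMax = 0.38,
                             expertWidth = 300L, expertStride = 150L,
                             sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  frameWidth <- as.integer(frameWidth)
  if (frameWidth < 10L || frameWidth > 20L)
    stop("'frameWidth' must be in [10, 20]")
  if (!(ratioMin > 0 && ratioMin < ratioMax && ratioMax < 1))
    stop("need 0 < ratioMin < ratioMax < 1")
  expertWidth <- as.integer(expertWidth)
  if (expertWidth < 1L || expertWidth > 300L)
    stop("'expertWidth' must be in [1, 300]")
  expertStride <- as.integer(expertStride)
  if (expertStride < 1L) stop("'expertStride' must be >= 1")
  structure(list(frameWidth = frameWidth, stddevMin = stddevMin,
                 ratioMin = ratioMin, ratioMax = ratioMax,
                 expertWidth = expertWidth, expertStride = expertStride,
                 sdType = sdType),
            class = "ExtractionConfig")
}

popSd <- function(x, sdType = "population") {
  if (sdType == "sample") return(stats::sd(x))
  sqrt(mean((x - mean(x))^2))
}

#' Per-frame statistics of the casual acceptance filter
#'
#' For the frame of `width` columns starting at column `start` (1-based),
#' computes the per-row ungapped nucleotide counts with their mean and
#' standard deviation, and the match ratio: the number of row pairs per
#' column whose two characters are the same nucleotide, summed over the
#' frame, divided by all `choose(n_rows, 2) * width` possible pairwise
#' comparisons (pairs involving a gap count as non-matches).
#'
#' @param aln a [PhyloMSA-class].
#' @param start first column of the frame, 1-based.
#' @param width frame width in columns.
#' @param cfg an [extractionConfig()] (controls the sd flavour).
#' @return a list with `start`, `width`, `counts`, `mean`, `sd`,
#'   `matchRatio`.
#' @export
frameStats <- function(aln, start, width, cfg = extractionConfig()) {
  m <- alnMatrix(aln)
  if (start < 1L || start + width - 1L > ncol(m))
    stop("frame out of range")
  fr <- m[, start:(start + width - 1L), drop = FALSE]
  counts <- rowSums(fr != GAP)
  nPairsTotal <- choose(nrow(fr), 2) * width
  matched <- sum(apply(fr, 2L, function(col) {
    tab <- table(col[col != GAP & col != "N"])
    sum(choose(tab, 2))
  }))
  list(start = as.integer(start), width = as.integer(width),
       counts = unname(counts), mean = mean(counts),
       sd = popSd(counts, cfg$sdType),
       matchRatio = matched / nPairsTotal)
}

#' Casual acceptance test on frame statistics
#'
#' A frame is accepted when the standard deviation of its per-row ungapped
#' counts is strictly greater than `stddevMin` and its match ratio lies in
#' the inclusive window `[ratioMin, ratioMax]`.
#'
#' @param stats a list from [frameStats()].
#' @param cfg an [extractionConfig()].
#' @return `TRUE` or `FALSE`.
#' @export
acceptFrame <- function(stats, cfg = extractionConfig()) {
  stats$sd > cfg$stddevMin &&
    stats$matchRatio >= cfg$ratioMin && stats$matchRatio <= cfg$ratioMax
}

nonEmptyRows <- function(m) {
  rownames(m)[rowSums(m != GAP) > 0L]
}

makeCasualBlock <- function(aln, parentId, start, width) {
  m <- alnMatrix(aln)
  region <- m[, start:(start + width - 1L), drop = FALSE]
  rows <- nonEmptyRows(region)
  if (length(rows) < 2L) return(NULL)
  PuzzleBlock(parentId, start, start + width - 1L, rows,
              region[rows, , drop = FALSE], "casual")
}

#' Automatic casual puzzle extraction
#'
#' Pans a reading frame of `cfg$frameWidth` columns across the alignment,
#' left to right from column 1. Each frame is tested with [acceptFrame()];
#' on acceptance a casual block containing exactly the non-empty rows of
#' the region is emitted and the frame jumps past the accepted columns (so
#' emitted blocks never overlap), otherwise the frame shifts one column to
#' the right. The scan is deterministic.
#'
#' @param aln a [PhyloMSA-class].
#' @param cfg an [extractionConfig()].
#' @param parentId identifier recorded on the emitted blocks.
#' @return list of [PuzzleBlock-class], sorted by start, pairwise
#'   column-disjoint (possibly empty).
#' @export
scanCasual <- function(aln, cfg = extractionConfig(), parentId = "aln") {
  w <- cfg$frameWidth
  if (ncol(aln) < w) return(list())
  blocks <- list()
  start <- 1L
  while (start + w - 1L <= ncol(aln)) {
    st <- frameStats(aln, start, w, cfg)
    if (acceptFrame(st, cfg)) {
      b <- makeCasualBlock(aln, parentId, start, w)
      if (!is.null(b)) {
        blocks[[length(blocks) + 1L]] <- b
        start <- start + w
        next
      }
    }
    start <- start + 1L
  }
  blocks
}

#' Manually selected casual block
#'
#' Cuts the user-selected region `[start, end]` (1-based, inclusive; 10-20
#' columns) into a casual block containing exactly the non-empty rows of
#' the region (rows with at least one nucleotide).
#'
#' @param aln a [PhyloMSA-class].
#' @param start,end 1-based inclusive column range.
#' @param parentId identifier recorded on the block.
#' @return a [PuzzleBlock-class].
#' @export
manualBlock <- function(aln, start, end, parentId = "aln") {
  width <- end - start + 1L
  if (width < 10L || width > 20L)
    stop("a casual selection must span between 10 and 20 columns")
  if (start < 1L || end > ncol(aln)) stop("region out of bounds")
  b <- makeCasualBlock(aln, parentId, as.integer(start), as.integer(width))
  if (is.null(b)) stop("fewer than 2 non-empty rows in the region")
  b
}

#' Expert block extraction
#'
#' Divides the alignment into expert blocks of `cfg$expertWidth` columns
#' starting at columns 1, 1+stride, 1+2*stride, ... (blocks overlap when
#' the stride is smaller than the width), plus a final right-aligned block
#' ending at the last column so that every column is covered. All rows are
#' included. An alignment narrower than the block width yields a single
#' full-width block.
#'
#' @param aln a [PhyloMSA-class].
#' @param cfg an [extractionConfig()].
#' @param parentId identifier recorded on the blocks.
#' @return list of [PuzzleBlock-class] of kind `"expert"`.
#' @export
extractExpertBlocks <- function(aln, cfg = extractionConfig(),
                                parentId = "aln") {
  m <- alnMatrix(aln)
  w <- min(cfg$expertWidth, ncol(m))
  starts <- seq.int(1L, by = cfg$expertStride,
                    length.out = max(1L, (ncol(m) - w) %/% cfg$expertStride + 1L))
  last <- ncol(m) - w + 1L
  if (starts[length(starts)] != last) starts <- c(starts, last)
  lapply(starts, function(s) {
    PuzzleBlock(parentId, s, s + w - 1L, rownames(m),
                m[, s:(s + w - 1L), drop = FALSE], "expert")
  })
}
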