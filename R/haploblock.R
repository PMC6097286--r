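# SNP calling, density tracks and haploblock segmentation.

#' Call substitution SNPs between two pseudomolecules
#'
#' Substitution columns are read off the one-to-one collinear backbone of
#' best local alignments between the two assemblies; columns within
#' `nExclusion` of an N run or of a backbone gap are skipped. Positions
#' are reported on genotype A.
#'
#' @param pmA,pmB Sequences (character, [Biostrings::DNAString] or
#'   [Pseudomolecule-class]).
#' @param nExclusion Exclusion distance (bp) around Ns and alignment
#'   gaps.
#' @param wordSize,window,maxOcc Backbone parameters (see
#'   [windowCompare()]).
#' @param chain Optional precomputed collinear backbone (internal reuse).
#' @return data.frame with `pos` (1-based on A), `ref` (A base), `alt`
#'   (B base); positions strictly increasing. Empty (with a warning)
#'   when no alignable blocks exist.
#' @export
callSnps <- function(pmA, pmB, nExclusion = 10, wordSize = 31,
                     window = NULL, maxOcc = 10, chain = NULL) {
  a <- if (is(pmA, "Pseudomolecule")) .chr(pmA@sequence) else .chr(pmA)
  b <- if (is(pmB, "Pseudomolecule")) .chr(pmB@sequence) else .chr(pmB)
  S <- if (is.null(chain))
    .collinearChain(a, b, wordSize = wordSize, window = window,
                    maxOcc = maxOcc)
  else chain
  if (nrow(S) == 0) {
    warning("callSnps: no alignable blocks between the assemblies")
    return(data.frame(pos = integer(), ref = character(),
                      alt = character()))
  }
  nrA <- .nRuns(a); nrB <- .nRuns(b)
  out <- list()
  # maximal runs of constant offset form the 1-to-1 blocks
  blockId <- cumsum(c(TRUE, diff(S$diag) != 0))
  for (bi in unique(blockId)) {
    rows <- which(blockId == bi)
    xs <- min(S$xstart[rows]); xe <- max(S$xend[rows])
    off <- S$diag[rows[1]]
    # trim block edges: similarity is only attested from the first to
    # the last exact match
    len <- xe - xs + 1L
    if (len < 2 * nExclusion) next
    mm <- .mismatchOffsetsCpp(a, b, xs, xs + off, len)
    if (!length(mm)) next
    pos <- xs + mm - 1L
    ref <- substring(a, pos, pos)
    alt <- substring(b, pos + off, pos + off)
    keep <- ref %in% .BASES & alt %in% .BASES
    # exclude columns near N runs on either assembly
    if (any(keep) && (nrow(nrA) || nrow(nrB))) {
      for (i in which(keep)) {
        if (.hasNIn(nrA, pos[i] - nExclusion, pos[i] + nExclusion) ||
            .hasNIn(nrB, pos[i] + off - nExclusion,
                    pos[i] + off + nExclusion))
          keep[i] <- FALSE
      }
    }
    # exclude columns near the block edges (alignment-gap exclusion)
    keep <- keep & (pos - xs >= nExclusion) & (xe - pos >= nExclusion)
    if (any(keep))
      out[[length(out) + 1]] <- data.frame(
        pos = pos[keep], ref = ref[keep], alt = alt[keep])
  }
  snps <- if (length(out)) do.call(rbind, out) else
    data.frame(pos = integer(), ref = character(), alt = character())
  snps <- snps[!duplicated(snps$pos), , drop = FALSE]
  snps <- snps[order(snps$pos), , drop = FALSE]
  rownames(snps) <- NULL
  snps
}

#' Sliding-window SNP density track
#'
#' @param snps SNP table from [callSnps()] (or any data.frame with a
#'   `pos` column).
#' @param chromLen Chromosome length in bp.
#' @param w Window width in bp (2.5 Mb at full chromosome scale).
#' @param s Step in bp; defaults to `w / 5`.
#' @return data.frame with `start`, `end`, `count`, `density` (SNPs per
#'   Mb). Windows cover the chromosome; with `s == w` the window counts
#'   sum to the number of SNPs.
#' @export
densityTrack <- function(snps, chromLen, w = 2.5e6, s = w / 5) {
  stopifnot(w <= chromLen, s <= w)
  starts <- seq(1, chromLen, by = s)
  starts <- starts[starts <= chromLen - w + 1 | starts == 1]
  ends <- pmin(chromLen, starts + w - 1)
  # last window anchored at the chromosome end so coverage is complete
  if (max(ends) < chromLen && s < w) {
    starts <- c(starts, chromLen - w + 1)
    ends <- c(ends, chromLen)
  }
  counts <- vapply(seq_along(starts), function(i)
    sum(snps$pos >= starts[i] & snps$pos <= ends[i]), 0L)
  data.frame(start = starts, end = ends, count = counts,
             density = counts / (w / 1e6))
}

#' Segment elevated-density haploblocks
#'
#' Maximal runs of at least `minWindows` consecutive windows whose SNP
#' density reaches `foldThreshold` times the chromosome-wide median are
#' merged into haploblocks.
#'
#' @param track Density track from [densityTrack()].
#' @param foldThreshold Density multiple over the median that qualifies
#'   a window.
#' @param minWindows Minimum consecutive qualifying windows.
#' @param floorDensity Baseline density (SNPs/Mb) used in place of a
#'   zero chromosome-wide median.
#' @return data.frame with `start`, `end`, `meanDensity`, `fold`,
#'   `nWindows`.
#' @export
segmentHaploblocks <- function(track, foldThreshold = 10,
                               minWindows = 2, floorDensity = 1) {
  med <- stats::median(track$density)
  base <- if (med > 0) med else floorDensity
  qual <- track$density >= foldThreshold * base
  out <- data.frame(start = numeric(), end = numeric(),
                    meanDensity = numeric(), fold = numeric(),
                    nWindows = integer())
  if (!any(qual)) return(out)
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in which(r$values & r$lengths >= minWindows)) {
    ix <- starts[i]:ends[i]
    out <- rbind(out, data.frame(
      start = min(track$start[ix]), end = max(track$end[ix]),
      meanDensity = mean(track$density[ix]),
      fold = mean(track$density[ix]) / base,
      nWindows = length(ix)))
  }
  out
}

#' Refine haploblock boundaries by local identity transition
#'
#' Moves each called boundary to the transition where local windowed
#' identity between the two assemblies crosses the midpoint between the
#' inside-block and outside-block mean identity.
#'
#' @param block One row of the [segmentHaploblocks()] output (list or
#'   data.frame row with `start`, `end`).
#' @param pmA,pmB Sequences.
#' @param refineWindow Identity window in bp (5 kb at full scale).
#' @param searchSpan How far (bp) each side of the called boundary to
#'   search. Should cover the window-width overshoot of the density
#'   segmentation (one density window is a good default).
#' @param minContrast Minimum outside-minus-inside mean identity
#'   difference treated as a real transition.
#' @return list with `start`, `end` (refined), `flagged` (TRUE when no
#'   transition was found on a side, whose boundary is then kept).
#' @details Each boundary is re-placed by a change-point fit: local
#'   identity is computed in consecutive `refineWindow` windows across
#'   the search span, each window is classified against the midpoint
#'   between the inside-block and outside-block mean identity, and the
#'   boundary maximising the number of correctly classified windows on
#'   both sides is taken. This is robust to isolated noisy windows.
#' @export
refineBlockBreakpoints <- function(block, pmA, pmB, refineWindow = 5000,
                                   searchSpan = 3e5,
                                   minContrast = 5e-4, chain = NULL) {
  a <- if (is(pmA, "Pseudomolecule")) .chr(pmA@sequence) else .chr(pmA)
  b <- if (is(pmB, "Pseudomolecule")) .chr(pmB@sequence) else .chr(pmB)
  if (is.null(chain)) chain <- .collinearChain(a, b)
  L <- nchar(a)
  # genotype-B offset of the collinear segment covering/nearest to s
  offAt <- function(s) {
    if (!nrow(chain)) return(0L)
    i <- findInterval(s, chain$xstart)
    if (i < 1) i <- 1L
    chain$diag[i]
  }
  idAt <- function(s) {
    e <- min(L, s + refineWindow - 1)
    s <- max(1, s)
    off <- offAt(s)
    if (s + off < 1 || e + off > nchar(b)) return(NA_real_)
    if (e - s + 1 < refineWindow / 2) return(NA_real_)
    id <- 1 - length(.mismatchOffsetsCpp(a, b, s, s + off,
                                         e - s + 1)) / (e - s + 1)
    # windows without collinear support (genotype-specific sequence,
    # e.g. inside a deletion) carry no boundary information
    if (id < 0.5) return(NA_real_)
    id
  }
  refineOne <- function(boundary, side) {
    lo <- max(1, boundary - searchSpan)
    hi <- min(L - refineWindow + 1, boundary + searchSpan)
    starts <- seq(lo, hi, by = refineWindow)
    ids <- vapply(starts, idAt, 0)
    ok <- !is.na(ids)
    starts <- starts[ok]; ids <- ids[ok]
    if (length(starts) < 3) return(NULL)
    inside <- if (side == "left") starts >= boundary else
      starts + refineWindow <= boundary
    if (!any(inside) || !any(!inside)) return(NULL)
    mIn <- mean(ids[inside]); mOut <- mean(ids[!inside])
    if (mOut - mIn < minContrast) return(NULL)  # no transition signal
    midpt <- (mIn + mOut) / 2
    low <- ids < midpt   # divergent (inside-like) windows
    n <- length(starts)
    # change-point: boundary after position k (0..n) maximises agreement
    if (side == "left") {
      # outside (high) to the left, inside (low) to the right
      score <- vapply(0:n, function(k)
        sum(!low[seq_len(k)]) + sum(low[seq_len(n - k) + k]), 0)
      k <- which.max(score) - 1L
      if (k >= n) return(NULL)
      starts[k + 1L]
    } else {
      # inside (low) to the left, outside (high) to the right
      score <- vapply(0:n, function(k)
        sum(low[seq_len(k)]) + sum(!low[seq_len(n - k) + k]), 0)
      k <- which.max(score) - 1L
      if (k < 1) return(NULL)
      starts[k] + refineWindow - 1L
    }
  }
  flagged <- FALSE
  s <- block$start; e <- block$end
  if (block$start > 1) {
    r <- refineOne(block$start, "left")
    if (is.null(r)) flagged <- TRUE else s <- r
  }
  if (block$end < L) {
    r <- refineOne(block$end, "right")
    if (is.null(r)) flagged <- TRUE else e <- r
  }
  list(start = s, end = e, flagged = flagged)
}
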