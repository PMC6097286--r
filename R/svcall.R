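# Large-InDel detection between two pseudomolecules.

# Collinear backbone between two sequences: windowed dot plots are
# collapsed to plus-strand maximal matches, merged along diagonals, and a
# weight-maximal co-monotone chain is selected. Returns data.frame with
# one row per chain segment: xstart, xend, ystart, yend, diag, weight.
.collinearChain <- function(a, b, wordSize = 31, window = NULL,
                            maxOcc = 10, chainGap = 2000) {
  a <- .chr(a); b <- .chr(b)
  la <- nchar(a); lb <- nchar(b)
  if (is.null(window)) window <- ceiling(la / 10)
  slack <- window
  offset <- 0
  xs <- list()
  wi <- 0L
  for (ws in seq(1L, la, by = window)) {
    wi <- wi + 1L
    we <- min(la, ws + window - 1L)
    bs <- max(1L, ws + offset - slack)
    be <- min(lb, we + offset + slack)
    if (bs > lb || be < 1 || be - bs < wordSize) next
    m <- .kmerMatchesCpp(substr(a, ws, we), substr(b, bs, be),
                         as.integer(wordSize), as.integer(maxOcc))
    if (nrow(m) == 0) next
    mm <- data.frame(x = m[, "qstart"] + ws - 1L,
                     y = m[, "tstart"] + bs - 1L,
                     len = m[, "len"])
    xs[[wi]] <- mm
    # track the dominant offset to position the next window pair
    best <- mm[which.max(mm$len), ]
    offset <- best$y - best$x
  }
  M <- do.call(rbind, xs)
  if (is.null(M) || nrow(M) == 0)
    return(data.frame(xstart = integer(), xend = integer(),
                      ystart = integer(), yend = integer(),
                      diag = integer(), weight = numeric()))
  # merge matches along each diagonal, bridging gaps up to chainGap
  M$diag <- M$y - M$x
  M <- M[order(M$diag, M$x), , drop = FALSE]
  newSeg <- c(TRUE, diff(M$diag) != 0 |
                M$x[-1] > (M$x + M$len - 1L)[-nrow(M)] + chainGap)
  seg <- cumsum(newSeg)
  S <- do.call(rbind, lapply(split(seq_len(nrow(M)), seg), function(ix) {
    data.frame(xstart = min(M$x[ix]),
               xend = max(M$x[ix] + M$len[ix] - 1L),
               ystart = min(M$y[ix]),
               yend = max(M$y[ix] + M$len[ix] - 1L),
               diag = M$diag[ix[1]],
               weight = sum(as.numeric(M$len[ix])))
  }))
  S <- S[order(S$xstart, S$ystart), , drop = FALSE]
  rownames(S) <- NULL
  # weight-maximal chain, strictly increasing in x and y (quadratic DP;
  # segment counts are small once diagonals are merged)
  n <- nrow(S)
  if (n > 1) {
    dp <- S$weight
    prev <- rep(NA_integer_, n)
    for (i in 2:n) {
      for (j in 1:(i - 1)) {
        if (S$xend[j] < S$xend[i] && S$yend[j] < S$yend[i] &&
            S$ystart[i] > S$ystart[j] &&
            dp[j] + S$weight[i] > dp[i]) {
          dp[i] <- dp[j] + S$weight[i]
          prev[i] <- j
        }
      }
    }
    i <- which.max(dp)
    keep <- integer()
    while (!is.na(i)) { keep <- c(i, keep); i <- prev[i] }
    S <- S[keep, , drop = FALSE]
  }
  rownames(S) <- NULL
  S
}

#' Windowed comparison of two pseudomolecules for large InDels
#'
#' Compares the two sequences in windows, computing dot plots and
#' following the main diagonal; a candidate InDel is emitted wherever the
#' diagonal offset jumps by at least `minIndelSize`. The genotype with the
#' extra sequence is the carrier.
#'
#' @param pmA,pmB Pseudomolecule sequences (character,
#'   [Biostrings::DNAString] or [Pseudomolecule-class]).
#' @param window Window size in bp; default one tenth of the chromosome,
#'   mirroring 10-Mb windows on a full-size chromosome.
#' @param minIndelSize Minimum InDel size (bp) to report.
#' @param wordSize,maxOcc Dot-plot word size and repeat-masking cutoff.
#' @param chain Optional precomputed collinear backbone (internal reuse).
#' @return data.frame of candidates: `aL`, `bL` (last matched positions
#'   left of the junction on A and B), `aR`, `bR` (first matched positions
#'   right of it), `carrier` ("A"/"B"), `size`.
#' @export
windowCompare <- function(pmA, pmB, window = NULL, minIndelSize = 1e4,
                          wordSize = 31, maxOcc = 10, chain = NULL) {
  a <- if (is(pmA, "Pseudomolecule")) .chr(pmA@sequence) else .chr(pmA)
  b <- if (is(pmB, "Pseudomolecule")) .chr(pmB@sequence) else .chr(pmB)
  S <- if (is.null(chain))
    .collinearChain(a, b, wordSize = wordSize, window = window,
                    maxOcc = maxOcc)
  else chain
  out <- data.frame(aL = integer(), bL = integer(), aR = integer(),
                    bR = integer(), carrier = character(),
                    size = integer())
  if (nrow(S) < 2) return(out)
  for (i in 1:(nrow(S) - 1)) {
    dd <- S$diag[i + 1] - S$diag[i]
    if (abs(dd) >= minIndelSize) {
      out <- rbind(out, data.frame(
        aL = S$xend[i], bL = S$yend[i],
        aR = S$xstart[i + 1], bR = S$ystart[i + 1],
        carrier = if (dd > 0) "B" else "A",
        size = abs(dd)))
    }
  }
  out
}

# base-level boundary of good matching: first position (offset within
# the scanned range) at which mismatches become dense. mm: sorted
# mismatch offsets; returns the largest prefix offset with only sparse
# mismatches.
.denseBoundary <- function(mm, len, run = 16, frac = 0.5) {
  if (!length(mm)) return(len)
  # mismatches within [m_i, m_i + run) for each mismatch m_i
  ahead <- findInterval(mm + run - 0.5, mm) - seq_along(mm) + 1L
  i <- which(ahead >= frac * run)[1]
  if (is.na(i)) len else mm[i] - 1L
}

#' Refine an InDel candidate to base-level breakpoints
#'
#' Bisects exact-match probes toward the junction to localise where
#' sequence similarity breaks down, then scans at base resolution. The
#' deletion interval on the carrier is reported at the leftmost position
#' consistent with the flanking similarity, with the width of the
#' consistent range recorded as `ambiguity` (non-zero at microhomologies
#' and tandem repeats).
#'
#' @param candidate One row of the [windowCompare()] output.
#' @param seqA,seqB The two sequences.
#' @param probe Probe length (bp) for the bisection step.
#' @param flankLen Flank length to extract on each side of the
#'   breakpoints.
#' @return list with `carrier`, `start`, `end` (deleted interval on the
#'   carrier, 1-based closed), `size`, `junction` (first base after the
#'   deletion point on the derived genotype), `ambiguity`, `flanks`
#'   (named character vector: carrier_left, carrier_right, derived_left,
#'   derived_right), `flankTruncated`; or NULL when no flanking homology
#'   is found (with a diagnostic message).
#' @export
refineBreakpoints <- function(candidate, seqA, seqB, probe = 40,
                              flankLen = 5000) {
  a <- .chr(seqA); b <- .chr(seqB)
  if (candidate$carrier == "A") {
    cs <- a; ds <- b
    cL <- candidate$aL; dL <- candidate$bL
    cR <- candidate$aR; dR <- candidate$bR
  } else {
    cs <- b; ds <- a
    cL <- candidate$bL; dL <- candidate$aL
    cR <- candidate$bR; dR <- candidate$aR
  }
  oL <- dL - cL
  oR <- dR - cR
  size <- oL - oR
  if (size <= 0 || cR <= cL) {
    message("refineBreakpoints: inconsistent candidate anchors; dropped")
    return(NULL)
  }
  lc <- nchar(cs); ld <- nchar(ds)
  consistent <- function(x, off, side) {
    # identity of the probe ending (left side) or starting (right side)
    # at carrier position x under offset off; probes are clamped at the
    # sequence edges
    if (side == "L") {
      if (x + off > ld || x > lc) return(FALSE)
      s1 <- x - probe + 1L; s2 <- x + off - probe + 1L
      clip <- max(1L - s1, 1L - s2, 0L)
      s1 <- s1 + clip; s2 <- s2 + clip
      if (x - s1 + 1L < 10L) return(TRUE)  # too little context
      id <- .hammingIdentity(substr(cs, s1, x), substr(ds, s2, x + off))
    } else {
      if (x + off < 1 || x < 1) return(FALSE)
      e1 <- x + probe - 1L; e2 <- x + off + probe - 1L
      clip <- max(e1 - lc, e2 - ld, 0L)
      e1 <- e1 - clip; e2 <- e2 - clip
      if (e1 - x + 1L < 10L) return(TRUE)
      id <- .hammingIdentity(substr(cs, x, e1), substr(ds, x + off, e2))
    }
    !is.na(id) && id >= 0.75
  }
  # bisection: last left-consistent position in [cL, cR]
  lo <- cL; hi <- cR
  if (!consistent(lo, oL, "L")) {
    message("refineBreakpoints: no left flanking homology; dropped")
    return(NULL)
  }
  while (hi - lo > probe) {
    mid <- (lo + hi) %/% 2
    if (consistent(mid, oL, "L")) lo <- mid else hi <- mid
  }
  # base-level scan forward from the known-good probe; the transition
  # is bracketed in [lo, hi] by the bisection
  scanFrom <- max(1L, lo - probe)
  scanLen <- min(lc - scanFrom + 1L, ld - (scanFrom + oL) + 1L,
                 (hi - scanFrom) + 2L * probe + 50L)
  mm <- .mismatchOffsetsCpp(cs, ds, scanFrom, scanFrom + oL, scanLen)
  Lmax <- scanFrom + .denseBoundary(mm, scanLen) - 1L

  # right side: first right-consistent position in [cL, cR]
  lo <- cL; hi <- cR
  if (!consistent(hi, oR, "R")) {
    message("refineBreakpoints: no right flanking homology; dropped")
    return(NULL)
  }
  while (hi - lo > probe) {
    mid <- (lo + hi) %/% 2
    if (consistent(mid, oR, "R")) hi <- mid else lo <- mid
  }
  scanTo <- min(lc, hi + probe, ld - oR)
  scanLen <- min(scanTo, scanTo + oR,
                 (scanTo - lo) + 2L * probe + 50L)
  # mismatches scanning backwards from scanTo under oR
  rcs <- .revString(substr(cs, scanTo - scanLen + 1L, scanTo))
  rds <- .revString(substr(ds, scanTo + oR - scanLen + 1L, scanTo + oR))
  mm <- .mismatchOffsetsCpp(rcs, rds, 1L, 1L, scanLen)
  Rmin <- scanTo - .denseBoundary(mm, scanLen) + 1L

  start <- Rmin - size          # leftmost consistent placement
  end <- start + size - 1L
  ambiguity <- max(0L, (Lmax + 1L) - start)
  junction <- start + oL
  # unmatched derived interval between the flank matches; positive width
  # means unaligned sequence (e.g. an assembly gap) sits at the junction
  junctionGap <- (Rmin + oR) - (Lmax + oL) - 1L
  ext <- function(s, from, to) {
    if (from > to) "" else .sub(s, from, to)
  }
  flanks <- c(
    carrier_left = ext(cs, start - flankLen, start - 1L),
    carrier_right = ext(cs, end + 1L, end + flankLen),
    derived_left = ext(ds, junction - flankLen, junction - 1L),
    derived_right = ext(ds, junction, junction + flankLen - 1L))
  trunc <- nchar(flanks) < c(flankLen, flankLen, flankLen, flankLen)
  list(carrier = candidate$carrier, start = start, end = end,
       size = size, junction = junction, junctionGap = junctionGap,
       ambiguity = ambiguity, flanks = flanks,
       flankTruncated = any(trunc))
}

.revString <- function(s) {
  paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Apply the assembly-gap (N) false-positive filter to an InDel call
#'
#' An InDel whose breakpoints have N runs on both sides is considered a
#' false positive caused by scaffold mis-placement or an unresolved
#' assembly gap and is rejected; Ns on one side only flag the call as
#' partial (kept); clean breakpoints validate it.
#'
#' @param call A refined call ([refineBreakpoints()] output).
#' @param seqA,seqB The two sequences.
#' @param nWindow Breakpoint neighbourhood (bp) searched for N runs.
#' @return The call list with `n_status` ("clean_both_ends", "n_one_end"
#'   or "n_both_ends") and `validity` ("validated", "partial" or
#'   "rejected") added.
#' @export
filterNs <- function(call, seqA, seqB, nWindow = 100) {
  a <- .chr(seqA); b <- .chr(seqB)
  if (call$carrier == "A") { cs <- a; ds <- b } else { cs <- b; ds <- a }
  nrC <- .nRuns(cs)
  nrD <- .nRuns(ds)
  gap <- if (is.null(call$junctionGap)) 0L else max(0L, call$junctionGap)
  # derived-side breakpoints: unaligned junction sequence (e.g. an
  # assembly gap) occupies [junction - gap, junction - 1], adjacent to
  # the left breakpoint at its start and to the right one at its end
  jL <- call$junction - gap
  jR <- call$junction
  leftN <- .hasNIn(nrC, call$start - nWindow, call$start + nWindow) ||
    .hasNIn(nrD, jL - nWindow, jL + nWindow)
  rightN <- .hasNIn(nrC, call$end - nWindow, call$end + nWindow) ||
    .hasNIn(nrD, jR - nWindow, jR + nWindow)
  call$n_status <- if (leftN && rightN) "n_both_ends"
    else if (leftN || rightN) "n_one_end" else "clean_both_ends"
  call$validity <- switch(call$n_status,
                          n_both_ends = "rejected",
                          n_one_end = "partial",
                          clean_both_ends = "validated")
  call
}

#' Call and curate large InDels between two pseudomolecules
#'
#' Runs [windowCompare()], refines every candidate with
#' [refineBreakpoints()] and applies [filterNs()], returning a curated
#' call set.
#'
#' @inheritParams windowCompare
#' @inheritParams refineBreakpoints
#' @inheritParams filterNs
#' @return An [SvCallSet-class]; flank sequences are kept in the
#'   `params$flanks` list, indexed by call id.
#' @export
callLargeIndels <- function(pmA, pmB, window = NULL, minIndelSize = 1e4,
                            wordSize = 31, maxOcc = 10, probe = 40,
                            flankLen = 5000, nWindow = 100,
                            chain = NULL) {
  cand <- windowCompare(pmA, pmB, window = window,
                        minIndelSize = minIndelSize,
                        wordSize = wordSize, maxOcc = maxOcc,
                        chain = chain)
  a <- if (is(pmA, "Pseudomolecule")) .chr(pmA@sequence) else .chr(pmA)
  b <- if (is(pmB, "Pseudomolecule")) .chr(pmB@sequence) else .chr(pmB)
  rows <- list(); flanks <- list()
  for (i in seq_len(nrow(cand))) {
    cl <- refineBreakpoints(cand[i, ], a, b, probe = probe,
                            flankLen = flankLen)
    if (is.null(cl)) next
    cl <- filterNs(cl, a, b, nWindow = nWindow)
    id <- sprintf("indel_%02d", length(rows) + 1L)
    rows[[id]] <- data.frame(
      id = id, carrier = cl$carrier, start = cl$start, end = cl$end,
      size = cl$size, junction = cl$junction,
      junctionGap = cl$junctionGap, ambiguity = cl$ambiguity,
      n_status = cl$n_status, validity = cl$validity,
      mechanism = NA_character_, motif = NA_character_,
      templateA = NA_character_, templateB = NA_character_,
      crossover = NA_integer_)
    flanks[[id]] <- cl$flanks
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), carrier = character(),
               start = integer(), end = integer(), size = integer(),
               junction = integer(), junctionGap = integer(),
               ambiguity = integer(),
               n_status = character(), validity = character(),
               mechanism = character(), motif = character(),
               templateA = character(), templateB = character(),
               crossover = integer())
  rownames(calls) <- NULL
  new("SvCallSet", calls = calls,
      params = list(window = window, minIndelSize = minIndelSize,
                    wordSize = wordSize, nWindow = nWindow,
                    flankLen = flankLen, flanks = flanks))
}
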