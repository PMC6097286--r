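#' Seed-and-extend local alignment of two sequences
#'
#' A desk-scale stand-in for an external nucleotide BLAST: exact k-mer
#' seeds are found on both strands, merged along diagonals into maximal
#' exact matches, chained within a diagonal band, and each chain is scored
#' by Hamming identity over its spanned interval. K-mers occurring more
#' than `maxOcc` times in either sequence are skipped as seeds, so the
#' aligner does not stall on high-copy repeats.
#'
#' @param query,target Sequences (character or [Biostrings::DNAString]).
#' @param k Seed word size (>= 8).
#' @param minLen Minimum reported alignment length in bp.
#' @param minIdentity Minimum reported identity (proportion in \[0,1\]).
#' @param maxOcc Seeds occurring more often than this in either sequence
#'   are skipped.
#' @param band Maximum diagonal drift allowed when chaining seeds.
#' @param maxGap Maximum unseeded gap (bp) bridged within a chain.
#' @return data.frame with one row per local alignment: `qstart`, `qend`,
#'   `tstart`, `tend` (1-based closed; target coordinates always on the
#'   forward strand of `target`), `strand`, `length`, `identity`, `score`
#'   (number of identical columns). Ordered by decreasing score, ties by
#'   decreasing length then leftmost query start.
#' @export
seedExtendAlign <- function(query, target, k = 15, minLen = 50,
                            minIdentity = 0.8, maxOcc = 50,
                            band = 50, maxGap = 2000) {
  stopifnot(k >= 8)
  q <- .chr(query); t <- .chr(target)
  if (nchar(q) == 0 || nchar(t) == 0)
    stop("sequences must be non-empty")
  res <- list()
  for (str in c("+", "-")) {
    qq <- if (str == "+") q else .revcomp(q)
    m <- .kmerMatchesCpp(qq, t, as.integer(k), as.integer(maxOcc))
    if (nrow(m) == 0) next
    ch <- .chainMatches(m, band = band, maxGap = maxGap)
    if (nrow(ch) == 0) next
    al <- .scoreChains(ch, qq, t)
    if (str == "-") {
      nq <- nchar(q)
      qs <- nq - al$qend + 1L
      qe <- nq - al$qstart + 1L
      al$qstart <- qs; al$qend <- qe
    }
    al$strand <- str
    res[[str]] <- al
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- .emptyAlignments()
  out <- out[out$length >= minLen & out$identity >= minIdentity, ,
             drop = FALSE]
  out <- out[order(-out$score, -out$length, out$qstart), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("qstart", "qend", "tstart", "tend", "strand",
          "length", "identity", "score")]
}

.emptyAlignments <- function() {
  data.frame(qstart = integer(), qend = integer(), tstart = integer(),
             tend = integer(), strand = character(), length = integer(),
             identity = numeric(), score = numeric())
}

# Chain maximal exact matches (matrix qstart/tstart/len, one strand) into
# candidate alignments. Greedy single-linkage along the query within a
# diagonal band.
.chainMatches <- function(m, band, maxGap) {
  if (nrow(m) == 0)
    return(data.frame(qstart = integer(), qend = integer(),
                      tstart = integer(), tend = integer(),
                      seeded = integer()))
  diag <- m[, "tstart"] - m[, "qstart"]
  o <- order(diag, m[, "qstart"])
  qs <- m[o, "qstart"]; ts <- m[o, "tstart"]; ln <- m[o, "len"]
  dg <- diag[o]
  n <- length(qs)
  # sort globally by qstart for chaining, keep diagonal for band test
  o2 <- order(qs, dg)
  qs <- qs[o2]; ts <- ts[o2]; ln <- ln[o2]; dg <- dg[o2]
  cluster <- integer(n)
  # chain id -> current end / diagonal
  ends <- numeric(0); dgs <- numeric(0); tend <- numeric(0)
  for (i in seq_len(n)) {
    hit <- 0L
    if (length(ends)) {
      ok <- which(abs(dgs - dg[i]) <= band &
                  qs[i] <= ends + maxGap & qs[i] + ln[i] - 1 > ends &
                  ts[i] + ln[i] - 1 > tend)
      if (length(ok)) hit <- ok[[1L]]
    }
    if (hit == 0L) {
      ends <- c(ends, qs[i] + ln[i] - 1)
      dgs <- c(dgs, dg[i])
      tend <- c(tend, ts[i] + ln[i] - 1)
      cluster[i] <- length(ends)
    } else {
      cluster[i] <- hit
      ends[hit] <- max(ends[hit], qs[i] + ln[i] - 1)
      dgs[hit] <- dg[i]
      tend[hit] <- max(tend[hit], ts[i] + ln[i] - 1)
    }
  }
  sp <- split(seq_len(n), cluster)
  do.call(rbind, lapply(sp, function(ix) {
    data.frame(qstart = min(qs[ix]), qend = max(qs[ix] + ln[ix] - 1L),
               tstart = min(ts[ix]), tend = max(ts[ix] + ln[ix] - 1L),
               seeded = sum(ln[ix]))
  }))
}

# Identity for each chain: ungapped Hamming identity over the spanned
# query interval against the target at the chain's dominant offset. When
# the chain spans unequal query/target widths (an internal indel), the
# seeded fraction is used as a conservative identity estimate.
.scoreChains <- function(ch, q, t) {
  n <- nrow(ch)
  len <- pmax(ch$qend - ch$qstart + 1L, ch$tend - ch$tstart + 1L)
  identity <- numeric(n)
  for (i in seq_len(n)) {
    wq <- ch$qend[i] - ch$qstart[i] + 1L
    wt <- ch$tend[i] - ch$tstart[i] + 1L
    if (wq == wt) {
      mm <- length(.mismatchOffsetsCpp(
        substr(q, ch$qstart[i], ch$qend[i]),
        substr(t, ch$tstart[i], ch$tend[i]), 1L, 1L, wq))
      identity[i] <- 1 - mm / wq
    } else {
      identity[i] <- min(1, ch$seeded[i] / max(wq, wt))
    }
  }
  data.frame(qstart = ch$qstart, qend = ch$qend,
             tstart = ch$tstart, tend = ch$tend,
             length = len, identity = identity,
             score = identity * len)
}

#' Dot plot of two sequences
#'
#' All maximal exact matches of at least `wordSize` bp between two
#' sequences, on both strands. Matches of the minus strand are reported
#' with both coordinates on the forward strands of their sequences, i.e. a
#' minus match at `(x, y, len)` pairs `seqA[x, x+len-1]` with the reverse
#' complement of `seqB[y, y+len-1]`.
#'
#' @param seqA,seqB Sequences (character or [Biostrings::DNAString]).
#' @param wordSize Minimum exact-match length (>= 8).
#' @param maxOcc Words more frequent than this in either sequence are
#'   skipped (repeat masking).
#' @return An object of class `DotPlot`: a list with elements `matches`
#'   (data.frame `x`, `y`, `length`, `strand`), `lenA`, `lenB`,
#'   `wordSize`.
#' @export
dotPlot <- function(seqA, seqB, wordSize = 25, maxOcc = 50) {
  stopifnot(wordSize >= 8)
  a <- .chr(seqA); b <- .chr(seqB)
  fw <- .kmerMatchesCpp(a, b, as.integer(wordSize), as.integer(maxOcc))
  rv <- .kmerMatchesCpp(a, .revcomp(b), as.integer(wordSize),
                        as.integer(maxOcc))
  mk <- function(m, strand, lenB) {
    if (nrow(m) == 0)
      return(data.frame(x = integer(), y = integer(),
                        length = integer(), strand = character()))
    y <- m[, "tstart"]
    if (strand == "-") y <- lenB - (m[, "tstart"] + m[, "len"] - 1L) + 1L
    data.frame(x = m[, "qstart"], y = y, length = m[, "len"],
               strand = strand)
  }
  matches <- rbind(mk(fw, "+", nchar(b)), mk(rv, "-", nchar(b)))
  matches <- matches[order(matches$x, matches$y), , drop = FALSE]
  rownames(matches) <- NULL
  structure(list(matches = matches, lenA = nchar(a), lenB = nchar(b),
                 wordSize = wordSize),
            class = "DotPlot")
}

#' @export
print.DotPlot <- function(x, ...) {
  cat("DotPlot:", x$lenA, "x", x$lenB, "bp, word", x$wordSize, ",",
      nrow(x$matches), "maximal matches\n")
  invisible(x)
}

#' Read tabular alignments from an external aligner
#'
#' Adapter for substituting real BLASTN runs for the internal aligner: a
#' tab-separated table with columns query, target, identity (percent),
#' alignment length, query start/end, target start/end, E-value (BLAST
#' `outfmt 6` subset) is converted to the layout returned by
#' [seedExtendAlign()].
#'
#' @param path Path to the tab-separated file (no header), columns:
#'   qseqid, sseqid, pident, length, qstart, qend, sstart, send, evalue.
#' @param maxEvalue Hits above this E-value are dropped (default `1e-10`,
#'   the cut-off used for gene-presence curation).
#' @return data.frame with `query`, `target`, `qstart`, `qend`, `tstart`,
#'   `tend`, `strand`, `length`, `identity`, `score`.
#' @export
readAlignmentTable <- function(path, maxEvalue = 1e-10) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  colnames(tb)[1:9] <- c("query", "target", "pident", "length",
                         "qstart", "qend", "sstart", "send", "evalue")
  tb <- tb[tb$evalue <= maxEvalue, , drop = FALSE]
  strand <- ifelse(tb$send >= tb$sstart, "+", "-")
  data.frame(query = tb$query, target = tb$target,
             qstart = tb$qstart, qend = tb$qend,
             tstart = pmin(tb$sstart, tb$send),
             tend = pmax(tb$sstart, tb$send),
             strand = strand, length = tb$length,
             identity = tb$pident / 100,
             score = tb$pident / 100 * tb$length)
}
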