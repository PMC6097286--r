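#' Segment-sampling rule for scaffold anchoring
#'
#' Scaffolds are represented in reference searches by sampled segments:
#' scaffolds shorter than `smallCutoff` are used whole; scaffolds between
#' `smallCutoff` and `midCutoff` contribute a `segmentLen` segment every
#' `midStep`; larger scaffolds one every `largeStep`.
#'
#' @param smallCutoff,midCutoff,midStep,largeStep,segmentLen Rule
#'   parameters in bp.
#' @return A list of class `SegmentSamplingRule`.
#' @export
segmentSamplingRule <- function(smallCutoff = 1e4, midCutoff = 2e5,
                                midStep = 3e4, largeStep = 1e5,
                                segmentLen = 1e3) {
  stopifnot(segmentLen <= midStep, midStep <= largeStep)
  structure(list(smallCutoff = smallCutoff, midCutoff = midCutoff,
                 midStep = midStep, largeStep = largeStep,
                 segmentLen = segmentLen),
            class = "SegmentSamplingRule")
}

#' Sample search segments from a scaffold
#'
#' Applies the segment-sampling rule to one scaffold, returning the
#' offsets and lengths of the segments used for reference searches.
#'
#' @param scaffoldLen Scaffold length in bp (or a sequence, whose length
#'   is used).
#' @param rule A [segmentSamplingRule()].
#' @return data.frame with `offset` (1-based start) and `len`.
#' @examples
#' sampleSegments(8e3)          # one whole-scaffold segment
#' sampleSegments(1e5)          # 1-kb segments at 0/30/60/90 kb
#' sampleSegments(2.5e5)        # 1-kb segments at 0/100/200 kb
#' @export
sampleSegments <- function(scaffoldLen, rule = segmentSamplingRule()) {
  if (!is.numeric(scaffoldLen)) scaffoldLen <- nchar(.chr(scaffoldLen))
  L <- as.integer(scaffoldLen)
  stopifnot(L > 0)
  if (L < rule$smallCutoff)
    return(data.frame(offset = 1L, len = L))
  step <- if (L <= rule$midCutoff) rule$midStep else rule$largeStep
  offs <- seq(1L, L, by = step)
  offs <- offs[offs + rule$segmentLen - 1L <= L]
  if (!length(offs)) offs <- 1L
  data.frame(offset = as.integer(offs),
             len = as.integer(pmin(rule$segmentLen, L - offs + 1L)))
}

# best reference hit for each sampled segment of one scaffold
.segmentVotes <- function(scaffold, reference, rule, k, maxOcc) {
  sc <- .chr(scaffold)
  segs <- sampleSegments(nchar(sc), rule)
  votes <- .emptyVotes()
  for (i in seq_len(nrow(segs))) {
    seg <- substr(sc, segs$offset[i], segs$offset[i] + segs$len[i] - 1L)
    al <- seedExtendAlign(seg, reference, k = k, maxOcc = maxOcc,
                          minLen = min(200, nchar(seg)),
                          minIdentity = 0.8)
    if (nrow(al) == 0) next
    best <- al[1, ]
    votes <- rbind(votes, data.frame(
      offset = segs$offset[i], len = segs$len[i], tpos = best$tstart,
      strand = best$strand, score = best$score))
  }
  votes
}

.emptyVotes <- function() {
  data.frame(offset = integer(), len = integer(), tpos = integer(),
             strand = character(), score = numeric())
}

# batched votes for many scaffolds: the reference is k-mer indexed once
# and every sampled segment (both strands) is matched against it
.segmentVotesBatch <- function(seqs, reference, rule, k, maxOcc) {
  ref <- .chr(reference)
  segTab <- list()
  queries <- character()
  for (id in names(seqs)) {
    sc <- .chr(seqs[[id]])
    segs <- sampleSegments(nchar(sc), rule)
    for (i in seq_len(nrow(segs))) {
      seg <- substr(sc, segs$offset[i],
                    segs$offset[i] + segs$len[i] - 1L)
      queries <- c(queries, seg, .revcomp(seg))
      segTab[[length(segTab) + 1]] <- data.frame(
        scaffold = id, offset = segs$offset[i], len = segs$len[i])
    }
  }
  segTab <- do.call(rbind, segTab)
  ml <- .kmerMatchesBatchCpp(queries, ref, as.integer(k),
                             as.integer(maxOcc))
  votes <- stats::setNames(
    replicate(length(seqs), .emptyVotes(), simplify = FALSE),
    names(seqs))
  for (i in seq_len(nrow(segTab))) {
    seg <- queries[2 * i - 1]
    nq <- nchar(seg)
    minLen <- min(200, nq)
    cand <- list()
    for (strandIdx in 1:2) {
      m <- ml[[2 * (i - 1) + strandIdx]]
      if (nrow(m) == 0) next
      ch <- .chainMatches(m, band = 50, maxGap = 2000)
      if (!nrow(ch)) next
      qq <- queries[2 * (i - 1) + strandIdx]
      al <- .scoreChains(ch, qq, ref)
      al$strand <- if (strandIdx == 1) "+" else "-"
      cand[[strandIdx]] <- al
    }
    al <- do.call(rbind, cand)
    if (is.null(al)) next
    al <- al[al$length >= minLen & al$identity >= 0.8, , drop = FALSE]
    if (!nrow(al)) next
    al <- al[order(-al$score, -al$length, al$qstart), , drop = FALSE]
    best <- al[1, ]
    id <- segTab$scaffold[i]
    votes[[id]] <- rbind(votes[[id]], data.frame(
      offset = segTab$offset[i], len = segTab$len[i],
      tpos = best$tstart, strand = best$strand, score = best$score))
  }
  votes
}

# majority-vote placement from a scaffold's segment votes
.placeFromVotes <- function(votes, scaffoldLen, regionGap) {
  if (nrow(votes) == 0)
    return(list(status = "unplaced", position = NA_real_,
                orientation = NA_character_, votes = votes,
                nVotes = 0L, nMajority = 0L))
  reg <- .voteRegions(votes$tpos, regionGap)
  tab <- table(reg)
  top <- as.integer(names(tab)[which.max(tab)])
  nMaj <- max(tab)
  if (nMaj * 2 <= nrow(votes))
    return(list(status = "ambiguous", position = NA_real_,
                orientation = NA_character_, votes = votes,
                nVotes = nrow(votes), nMajority = as.integer(nMaj)))
  vv <- votes[reg == top, , drop = FALSE]
  stab <- table(vv$strand)
  ori <- names(stab)[which.max(stab)]
  vv <- vv[vv$strand == ori, , drop = FALSE]
  # projected reference coordinate of the scaffold's first base
  pos <- if (ori == "+")
    stats::median(vv$tpos - vv$offset + 1)
  else
    stats::median(vv$tpos + vv$offset + vv$len - 1) - scaffoldLen
  list(status = "placed", position = pos, orientation = ori,
       votes = votes, nVotes = nrow(votes),
       nMajority = as.integer(nMaj))
}

# cluster vote positions into reference regions (single linkage, gap <=
# regionGap); returns region id per vote
.voteRegions <- function(tpos, regionGap) {
  o <- order(tpos)
  reg <- integer(length(tpos))
  r <- 1L
  reg[o[1]] <- r
  if (length(tpos) > 1) {
    for (i in 2:length(tpos)) {
      if (tpos[o[i]] - tpos[o[i - 1]] > regionGap) r <- r + 1L
      reg[o[i]] <- r
    }
  }
  reg
}

#' Anchor one scaffold to a reference by majority vote
#'
#' Each sampled segment votes for the reference region of its best
#' alignment; the scaffold is placed at the majority region (more than
#' half of the informative votes) in the majority strand, or reported
#' ambiguous/unplaced.
#'
#' @param scaffold Scaffold sequence.
#' @param reference Reference chromosome sequence.
#' @param rule A [segmentSamplingRule()].
#' @param regionGap Votes within this distance (bp) belong to one
#'   reference region.
#' @param k,maxOcc Aligner parameters (see [seedExtendAlign()]).
#' @return list with `status` ("placed", "ambiguous" or "unplaced"),
#'   `position` (projected reference coordinate of the scaffold start,
#'   used for ordering), `orientation`, `votes` (per-segment vote table),
#'   `nVotes`, `nMajority`.
#' @export
anchorScaffold <- function(scaffold, reference,
                           rule = segmentSamplingRule(),
                           regionGap = 1e6, k = 15, maxOcc = 50) {
  votes <- .segmentVotes(scaffold, reference, rule, k, maxOcc)
  .placeFromVotes(votes, nchar(.chr(scaffold)), regionGap)
}

#' Detect and split chimeric scaffolds from their vote pattern
#'
#' Maximal runs of segment votes that agree in reference region and
#' strand form blocks; when a scaffold has two or more blocks whose
#' regions lie further apart than `chimeraDistance` (or disagree in
#' strand), it is split at the midpoints between the flanking segment
#' hits and each piece is re-anchored independently.
#'
#' @param scaffold Scaffold sequence.
#' @param votes Per-segment vote table from [anchorScaffold()] (ordered
#'   along the scaffold).
#' @param chimeraDistance Reference distance (bp) separating blocks that
#'   indicates a mis-join.
#' @return list with `pieces` (data.frame `start`, `end` in scaffold
#'   coordinates) and `split` (logical).
#' @export
detectAndSplitChimeras <- function(scaffold, votes,
                                   chimeraDistance = 1e6) {
  sc <- .chr(scaffold)
  L <- nchar(sc)
  if (nrow(votes) < 2)
    return(list(pieces = data.frame(start = 1L, end = L), split = FALSE))
  votes <- votes[order(votes$offset), , drop = FALSE]
  n <- nrow(votes)
  newBlock <- c(TRUE, abs(diff(votes$tpos)) > chimeraDistance |
                  votes$strand[-1] != votes$strand[-n])
  block <- cumsum(newBlock)
  if (max(block) == 1)
    return(list(pieces = data.frame(start = 1L, end = L), split = FALSE))
  # split at the midpoint between the last segment of one block and the
  # first segment of the next (scaffold coordinates)
  cutAfter <- which(diff(block) != 0)
  cuts <- floor((votes$offset[cutAfter] + votes$offset[cutAfter + 1]) / 2)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, L)
  list(pieces = data.frame(start = as.integer(starts),
                           end = as.integer(ends)),
       split = TRUE)
}

#' Anchor a scaffold set to a reference
#'
#' Runs [anchorScaffold()] for every scaffold, applies the chimera rule,
#' re-anchors split pieces, and returns the placement report used to
#' build a pseudomolecule.
#'
#' @param scaffolds A [ScaffoldSet-class] or named [Biostrings::DNAStringSet].
#' @param reference Reference chromosome sequence.
#' @param rule A [segmentSamplingRule()].
#' @param regionGap,chimeraDistance,k,maxOcc See [anchorScaffold()] and
#'   [detectAndSplitChimeras()].
#' @return list with `placements` (data.frame: `component`, `scaffold`,
#'   `start`, `end` (scaffold coordinates), `status`, `position`,
#'   `orientation`, `nVotes`, `nMajority`, `fromSplit`) and `sequences`
#'   (DNAStringSet of the placed components, split pieces included).
#' @export
anchorScaffoldSet <- function(scaffolds, reference,
                              rule = segmentSamplingRule(),
                              regionGap = 1e6, chimeraDistance = 1e6,
                              k = 15, maxOcc = 50) {
  seqs <- if (is(scaffolds, "ScaffoldSet")) scaffolds@sequences
          else scaffolds
  ref <- .chr(reference)
  scafChr <- stats::setNames(
    vapply(seq_along(seqs), function(i) as.character(seqs[[i]]), ""),
    names(seqs))
  allVotes <- .segmentVotesBatch(scafChr, ref, rule, k, maxOcc)
  rows <- list()
  outSeqs <- list()
  pieceSeqs <- character()
  pieceMeta <- list()
  for (id in names(scafChr)) {
    sc <- scafChr[[id]]
    a <- .placeFromVotes(allVotes[[id]], nchar(sc), regionGap)
    sp <- detectAndSplitChimeras(sc, a$votes, chimeraDistance)
    if (sp$split) {
      for (j in seq_len(nrow(sp$pieces))) {
        comp <- sprintf("%s_part%d", id, j)
        pieceSeqs[comp] <- substr(sc, sp$pieces$start[j],
                                  sp$pieces$end[j])
        pieceMeta[[comp]] <- data.frame(
          component = comp, scaffold = id,
          start = sp$pieces$start[j], end = sp$pieces$end[j])
      }
    } else {
      rows[[id]] <- data.frame(
        component = id, scaffold = id, start = 1L, end = nchar(sc),
        status = a$status, position = a$position,
        orientation = if (is.na(a$orientation)) NA_character_
                      else a$orientation,
        nVotes = a$nVotes, nMajority = a$nMajority, fromSplit = FALSE)
      outSeqs[[id]] <- sc
    }
  }
  # split pieces are re-anchored independently (second batch)
  if (length(pieceSeqs)) {
    pieceVotes <- .segmentVotesBatch(pieceSeqs, ref, rule, k, maxOcc)
    for (comp in names(pieceSeqs)) {
      aj <- .placeFromVotes(pieceVotes[[comp]], nchar(pieceSeqs[[comp]]),
                            regionGap)
      rows[[comp]] <- cbind(pieceMeta[[comp]], data.frame(
        status = aj$status, position = aj$position,
        orientation = if (is.na(aj$orientation)) NA_character_
                      else aj$orientation,
        nVotes = aj$nVotes, nMajority = aj$nMajority,
        fromSplit = TRUE))
      outSeqs[[comp]] <- pieceSeqs[[comp]]
    }
  }
  pl <- do.call(rbind, rows)
  rownames(pl) <- NULL
  list(placements = pl,
       sequences = DNAStringSet(unlist(outSeqs)))
}

#' Build a gap-joined pseudomolecule from placements
#'
#' Orders placed components by their anchor coordinate, reverse
#' complements minus-orientation components, joins them with fixed-length
#' N gaps and emits the AGP map and assembly statistics. Ambiguous and
#' unplaced components are excluded from the sequence but retained in the
#' placement report.
#'
#' @param anchored Result of [anchorScaffoldSet()].
#' @param gapLen N-gap length between consecutive components.
#' @param object Name of the assembled object in the AGP map.
#' @return A [Pseudomolecule-class].
#' @export
buildPseudomolecule <- function(anchored, gapLen = 100,
                                object = "pseudomolecule") {
  pl <- anchored$placements
  placed <- pl[pl$status == "placed", , drop = FALSE]
  if (anyDuplicated(placed$component))
    stop("assembly error: component placed more than once")
  placed <- placed[order(placed$position), , drop = FALSE]
  comps <- character(nrow(placed))
  agp <- list()
  at <- 1L
  part <- 1L
  for (i in seq_len(nrow(placed))) {
    s <- as.character(anchored$sequences[[placed$component[i]]])
    if (placed$orientation[i] == "-") s <- .revcomp(s)
    comps[i] <- s
    w <- nchar(s)
    agp[[length(agp) + 1]] <- data.frame(
      object = object, object_beg = at, object_end = at + w - 1L,
      part_number = part, component_type = "W",
      component_id = placed$component[i], component_beg = 1L,
      component_end = w, orientation = placed$orientation[i])
    at <- at + w
    part <- part + 1L
    if (i < nrow(placed) && gapLen > 0) {
      agp[[length(agp) + 1]] <- data.frame(
        object = object, object_beg = at, object_end = at + gapLen - 1L,
        part_number = part, component_type = "N",
        component_id = as.character(gapLen), component_beg = NA_integer_,
        component_end = NA_integer_, orientation = "na")
      at <- at + gapLen
      part <- part + 1L
    }
  }
  seq <- paste(comps, collapse = strrep("N", gapLen))
  agp <- if (length(agp)) do.call(rbind, agp) else
    data.frame(object = character(), object_beg = integer(),
               object_end = integer(), part_number = integer(),
               component_type = character(), component_id = character(),
               component_beg = integer(), component_end = integer(),
               orientation = character())
  lens <- nchar(comps)
  st <- assemblyStats(lens)
  stats <- list(n50 = st["n50"], n90 = st["n90"], total = st["total"],
                anchoredFraction = nrow(placed) / nrow(pl))
  new("Pseudomolecule", sequence = DNAString(seq), agp = agp,
      placements = pl, stats = stats)
}

#' Assembly N50/N90 statistics
#'
#' `Nxx` is the length of the component at which the cumulative
#' descending-sorted length first reaches xx% of the total.
#'
#' @param lengths Numeric vector of positive component lengths.
#' @return Named numeric vector `n50`, `n90`, `total`.
#' @examples
#' assemblyStats(c(5, 4, 3, 2, 1) * 1000)  # N50 4000, N90 2000
#' @export
assemblyStats <- function(lengths) {
  if (!length(lengths)) stop("undefined input: empty length list")
  stopifnot(all(lengths > 0))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cs <- cumsum(s)
  tot <- cs[length(cs)]
  c(n50 = s[which(cs >= 0.5 * tot)[1]],
    n90 = s[which(cs >= 0.9 * tot)[1]],
    total = tot)
}
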