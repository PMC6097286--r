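# Molecular-mechanism classification of curated InDel breakpoints.

#' Detect a single-strand-annealing microhomology motif
#'
#' Searches for the longest motif (>= `kMin` bp) that is present adjacent
#' to both breakpoints of the deleted interval in the carrier genotype
#' and exactly once at the junction of the derived genotype -- the
#' signature of a double-strand break repaired by single-strand
#' annealing. Ties among equally long motifs are broken by proximity to
#' the refined breakpoint, then lexicographically.
#'
#' @param carrierLeft Carrier sequence context ending at the left
#'   breakpoint, i.e. the last `searchWindow` bases before the deleted
#'   interval plus up to `searchWindow` bases inside it.
#' @param carrierRight Carrier context around the right breakpoint (the
#'   last `searchWindow` bases of the deleted interval plus the first
#'   `searchWindow` after it).
#' @param derivedJunction Derived-genotype context centred on the
#'   junction (`searchWindow` bases each side).
#' @param kMin Minimum motif length (default 3; the canonical worked
#'   signature is a nucleotide triplet).
#' @param searchWindow Breakpoint neighbourhood (context half-width), bp.
#' @param tol Breakpoint placement tolerance in bp (breakpoints are
#'   refined to at most this uncertainty).
#' @param centerL,centerR,centerJ Offset of the breakpoint within each
#'   context (defaults to `searchWindow`, i.e. centred contexts; override
#'   for contexts truncated at a sequence end).
#' @details A motif `m` of length `k >= kMin` qualifies when (i) it
#'   occurs in the carrier left context ending within `tol` of the left
#'   breakpoint, (ii) it occurs in the carrier right context ending
#'   within `tol` of the right breakpoint (the second repeat copy), and
#'   (iii) it occurs at the derived junction ending within `tol + k` of
#'   the junction point, without an immediately tandem-adjacent second
#'   copy there (two adjacent copies would mean both repeats were
#'   retained, i.e. no annealing-mediated loss). At each pair of end
#'   offsets the candidate tested is the maximal common suffix of the two
#'   carrier contexts. Among qualifying motifs the longest wins; ties are
#'   broken by total distance of the motif ends from the breakpoints,
#'   then lexicographically.
#' @return The motif as a character scalar, or `NULL` when no qualifying
#'   motif exists.
#' @export
detectMicrohomology <- function(carrierLeft, carrierRight,
                                derivedJunction, kMin = 3,
                                searchWindow = 50, tol = 10,
                                centerL = searchWindow,
                                centerR = searchWindow,
                                centerJ = searchWindow) {
  cl <- .chr(carrierLeft); cr <- .chr(carrierRight)
  dj <- .chr(derivedJunction)
  best <- NULL; bestDist <- Inf
  eLs <- seq(max(kMin, centerL - tol), min(nchar(cl), centerL + tol))
  eRs <- seq(max(kMin, centerR - tol), min(nchar(cr), centerR + tol))
  for (eL in eLs) {
    for (eR in eRs) {
      kmax <- min(eL, eR, searchWindow)
      k <- 0L
      while (k < kmax &&
             substr(cl, eL - k, eL - k) == substr(cr, eR - k, eR - k))
        k <- k + 1L
      if (k < kMin) next
      motif <- substr(cl, eL - k + 1L, eL)
      hit <- .junctionOccurrence(motif, dj, centerJ, tol)
      if (is.null(hit)) next
      dist <- abs(eL - centerL) + abs(eR - centerR) +
        abs(hit - centerJ - k)
      if (is.null(best) || nchar(motif) > nchar(best) ||
          (nchar(motif) == nchar(best) &&
           (dist < bestDist ||
            (dist == bestDist && motif < best)))) {
        best <- motif; bestDist <- dist
      }
    }
  }
  best
}

# end position of a single junction-adjacent occurrence of motif in the
# derived junction context, or NULL; an immediately tandem-adjacent
# second copy disqualifies the motif
.junctionOccurrence <- function(motif, dj, centerJ, tol) {
  k <- nchar(motif)
  occ <- gregexpr(motif, dj, fixed = TRUE)[[1]]
  if (occ[1] == -1) return(NULL)
  ends <- occ + k - 1L
  nearby <- ends[ends >= centerJ - tol & ends <= centerJ + tol + k]
  if (!length(nearby)) return(NULL)
  e <- nearby[which.min(abs(nearby - centerJ - k))]
  # tandem second copy adjacent on either side?
  if (any(ends == e - k) || any(ends == e + k)) return(NULL)
  e
}

#' Detect an unequal-crossing-over template pair at an InDel
#'
#' Unequal crossing over happens between repeated sequences in the same
#' orientation; its footprint is a pair of high-identity, same-strand
#' paralogs flanking the deleted interval in the carrier and a single
#' homologous copy spanning the junction in the derived genotype.
#'
#' @param call One row of [svCalls()] (or an equivalent list with
#'   `carrier`, `start`, `end`, `junction`).
#' @param pair A [ChromosomePair-class] (for sequences and annotations).
#' @param templateMinIdentity Minimum pairwise identity of the template
#'   pair (proportion).
#' @param flankSearch Distance (bp) around each breakpoint searched for
#'   template genes.
#' @return list with `templateA`, `templateB` (carrier gene ids),
#'   `identity`, `singleCopy` (derived gene id) and `orientation`, or
#'   `NULL` (with a diagnostic when annotations are absent at the
#'   flanks).
#' @export
detectUcoTemplate <- function(call, pair, templateMinIdentity = 0.9,
                              flankSearch = 5000) {
  if (call$carrier == "A") {
    cs <- .chr(pair@seqA); cg <- pair@genesA
    ds <- .chr(pair@seqB); dg <- pair@genesB
  } else {
    cs <- .chr(pair@seqB); cg <- pair@genesB
    ds <- .chr(pair@seqA); dg <- pair@genesA
  }
  if (length(cg) == 0 || length(dg) == 0) {
    message("detectUcoTemplate: no annotations at flanks")
    return(NULL)
  }
  near <- function(gr, pos) {
    hit <- which(start(gr) <= pos + flankSearch &
                   end(gr) >= pos - flankSearch)
    gr[hit]
  }
  gl <- near(cg, call$start)   # genes overlapping the left breakpoint
  gr <- near(cg, call$end)     # genes overlapping the right breakpoint
  if (!length(gl) || !length(gr)) return(NULL)
  for (i in seq_along(gl)) {
    for (j in seq_along(gr)) {
      if (gl$gene_id[i] == gr$gene_id[j]) next
      if (as.character(strand(gl)[i]) != as.character(strand(gr)[j]))
        next  # unequal crossover requires same orientation
      sA <- substr(cs, start(gl)[i], end(gl)[i])
      sB <- substr(cs, start(gr)[j], end(gr)[j])
      idn <- .pairIdentity(sA, sB)
      if (is.na(idn) || idn < templateMinIdentity) next
      # a single homologous copy must span the derived junction, whose
      # placement is only known up to the recorded ambiguity
      slack <- if (!is.null(call$ambiguity) && !is.na(call$ambiguity))
        call$ambiguity + 10L else 10L
      dspan <- which(start(dg) <= call$junction + slack &
                       end(dg) >= call$junction - slack)
      if (!length(dspan)) next
      for (d in dspan) {
        sD <- substr(ds, start(dg)[d], end(dg)[d])
        if (.pairIdentity(sD, sA) >= templateMinIdentity &&
            .pairIdentity(sD, sB) >= templateMinIdentity) {
          return(list(templateA = gl$gene_id[i],
                      templateB = gr$gene_id[j],
                      identity = idn,
                      singleCopy = dg$gene_id[d],
                      orientation = as.character(strand(gl)[i])))
        }
      }
    }
  }
  NULL
}

# global pairwise identity of two sequences (matches / alignment length)
.pairIdentity <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) return(NA_real_)
  if (nchar(a) == nchar(b)) return(.hammingIdentity(a, b))
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                      Biostrings::DNAString(b),
                                      type = "global")
  Biostrings::pid(al) / 100
}

#' Sliding-window chimera (recombinant) test
#'
#' Tests whether a single gene copy is a recombinant of two templates:
#' per sliding window, its identity to each template is computed on the
#' induced alignment; the copy is recombinant when a prefix run of
#' windows favours one template and the suffix run favours the other.
#' The crossover is estimated as the midpoint between the last window
#' favouring the first template and the first window favouring the
#' second.
#'
#' @param singleCopy,templateA,templateB Sequences, mutually alignable
#'   end to end.
#' @param window,step Sliding-window size and step in bp.
#' @param minRun Minimum run length (windows) on each side.
#' @param resolution Minimum per-window identity difference treated as
#'   informative.
#' @return list with `isRecombinant`, `crossover` (coordinate in the
#'   single copy, NA when not recombinant), `profile` (data.frame
#'   `start`, `end`, `idA`, `idB`), `uninformative` (TRUE when the
#'   templates are nowhere distinguishable).
#' @export
chimeraTest <- function(singleCopy, templateA, templateB, window = 200,
                        step = 50, minRun = 2, resolution = 0.01) {
  s <- .chr(singleCopy); a <- .chr(templateA); b <- .chr(templateB)
  # induce a common coordinate frame on the single copy
  alnA <- .projectOnto(s, a)
  alnB <- .projectOnto(s, b)
  n <- nchar(s)
  starts <- seq(1L, max(1L, n - window + 1L), by = step)
  prof <- data.frame(start = starts,
                     end = pmin(n, starts + window - 1L))
  prof$idA <- vapply(seq_len(nrow(prof)), function(i)
    .windowIdentity(alnA, prof$start[i], prof$end[i]), 0)
  prof$idB <- vapply(seq_len(nrow(prof)), function(i)
    .windowIdentity(alnB, prof$start[i], prof$end[i]), 0)
  dif <- prof$idA - prof$idB
  fav <- ifelse(dif >= resolution, 1L, ifelse(dif <= -resolution, -1L, 0L))
  inf <- fav[fav != 0L]
  if (!length(inf))
    return(list(isRecombinant = FALSE, crossover = NA_real_,
                profile = prof, uninformative = TRUE))
  # recombinant: one sign switch, each side at least minRun windows
  r <- rle(inf)
  rec <- length(r$lengths) == 2 && all(r$lengths >= minRun)
  crossover <- NA_real_
  if (rec) {
    firstSide <- r$values[1]
    idx <- which(fav != 0L)
    lastFirst <- idx[max(which(fav[idx] == firstSide))]
    firstSecond <- idx[min(which(fav[idx] == -firstSide))]
    crossover <- (prof$end[lastFirst] + prof$start[firstSecond]) / 2
  }
  list(isRecombinant = rec, crossover = crossover, profile = prof,
       uninformative = FALSE)
}

# match/mismatch indicator along the single copy vs a template; for
# equal lengths a direct comparison, otherwise via global alignment
.projectOnto <- function(s, t) {
  n <- nchar(s)
  ok <- rep(NA, n)  # NA = position aligned to a gap
  if (nchar(t) == n) {
    mm <- .mismatchOffsetsCpp(s, t, 1L, 1L, n)
    ok <- rep(TRUE, n)
    ok[mm] <- FALSE
    return(ok)
  }
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(s),
                                      Biostrings::DNAString(t),
                                      type = "global")
  ps <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  tt <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  keep <- ps != "-"
  comp <- ps[keep] == tt[keep] & tt[keep] != "-"
  comp[tt[keep] == "-"] <- NA
  out <- rep(NA, n)
  out[seq_along(comp)] <- comp
  out
}

.windowIdentity <- function(ok, s, e) {
  v <- ok[s:e]
  v <- v[!is.na(v)]
  if (!length(v)) return(0)
  mean(v)
}

#' Classify the molecular mechanism of a curated InDel
#'
#' Applies both detectors and labels the call: unequal crossing over
#' (UCO) when a same-orientation template pair is found and the derived
#' single copy passes the chimera test; otherwise single-strand annealing
#' (SSA) when a junction microhomology motif is present; otherwise
#' unclassified. When both signatures are positive the template evidence
#' wins (microhomology can occur by chance within paralogous templates)
#' and the conflict is recorded.
#'
#' @param call One row of [svCalls()] as a list/data.frame row.
#' @param pair A [ChromosomePair-class].
#' @param kMin,searchWindow See [detectMicrohomology()].
#' @param templateMinIdentity,flankSearch See [detectUcoTemplate()].
#' @param window,step,minRun See [chimeraTest()].
#' @return list with `label` ("UCO", "SSA" or "unclassified"), `motif`,
#'   `templateA`, `templateB`, `crossover`, `conflict`.
#' @export
classifyMechanism <- function(call, pair, kMin = 3, searchWindow = 50,
                              templateMinIdentity = 0.9,
                              flankSearch = 5000, window = 200,
                              step = 50, minRun = 2) {
  if (call$carrier == "A") { cs <- .chr(pair@seqA); ds <- .chr(pair@seqB) }
  else { cs <- .chr(pair@seqB); ds <- .chr(pair@seqA) }
  w <- searchWindow
  cl <- .sub(cs, call$start - w, call$start + w - 1L)
  cr <- .sub(cs, call$end - w + 1L, call$end + w)
  dj <- .sub(ds, call$junction - w, call$junction + w - 1L)
  motif <- detectMicrohomology(
    cl, cr, dj, kMin = kMin, searchWindow = w,
    centerL = min(w, call$start - 1L), centerR = min(w, call$end),
    centerJ = min(w, call$junction - 1L))

  tmpl <- detectUcoTemplate(call, pair,
                            templateMinIdentity = templateMinIdentity,
                            flankSearch = flankSearch)
  uco <- FALSE
  crossover <- NA_real_
  if (!is.null(tmpl)) {
    if (call$carrier == "A") { cg <- pair@genesA; dg <- pair@genesB }
    else { cg <- pair@genesB; dg <- pair@genesA }
    ids <- cg$gene_id
    gA <- cg[match(tmpl$templateA, ids)]
    gB <- cg[match(tmpl$templateB, ids)]
    gD <- dg[match(tmpl$singleCopy, dg$gene_id)]
    ct <- chimeraTest(substr(ds, start(gD), end(gD)),
                      substr(cs, start(gA), end(gA)),
                      substr(cs, start(gB), end(gB)),
                      window = window, step = step, minRun = minRun)
    uco <- isTRUE(ct$isRecombinant)
    if (uco) crossover <- ct$crossover
  }
  label <- if (uco) "UCO" else if (!is.null(motif)) "SSA"
    else "unclassified"
  list(label = label,
       motif = if (is.null(motif)) NA_character_ else motif,
       templateA = if (uco) tmpl$templateA else NA_character_,
       templateB = if (uco) tmpl$templateB else NA_character_,
       crossover = crossover,
       conflict = uco && !is.null(motif))
}

#' Classify every validated call in an SvCallSet
#'
#' @param callset An [SvCallSet-class].
#' @param pair The [ChromosomePair-class] the calls were made on.
#' @param ... Passed to [classifyMechanism()].
#' @return The [SvCallSet-class] with `mechanism`, `motif`, `templateA`,
#'   `templateB` and `crossover` filled for validated and partial calls.
#' @export
classifyCallSet <- function(callset, pair, ...) {
  cc <- callset@calls
  for (i in seq_len(nrow(cc))) {
    if (cc$validity[i] == "rejected") next
    res <- classifyMechanism(cc[i, ], pair, ...)
    cc$mechanism[i] <- res$label
    cc$motif[i] <- res$motif
    cc$templateA[i] <- res$templateA
    cc$templateB[i] <- res$templateB
    cc$crossover[i] <- res$crossover
  }
  callset@calls <- cc
  callset
}
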