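#' Simulate an ancestral chromosome
#'
#' Generates the shared ancestor of a genotype pair: an i.i.d. random
#' nucleotide background (optionally salted with dinucleotide repeats),
#' non-overlapping gene models at a given density, and NLR paralog pairs
#' embedded in the same orientation at a recorded spacing and nucleotide
#' identity. The pairs serve as templates for unequal crossing over when
#' genotypes are derived.
#'
#' @param length Chromosome length in bp (>= 100 kb).
#' @param geneDensity Genes per Mb (total, including NLR pair members).
#' @param nlrPairSpec list with `count` (number of pairs) and `identity`
#'   (percent nucleotide identity within a pair, in \[90, 100\]).
#' @param pairSpacing Distance (bp) between the starts of the two members
#'   of a pair; this is also the size of the deletion an unequal crossover
#'   between them produces.
#' @param nlrLen Length (bp) of each NLR gene.
#' @param geneLenRange Range of generic gene lengths (bp).
#' @param repeatSalt Number of 400-bp dinucleotide repeat intervals to
#'   inject into intergenic space.
#' @param avoidPairPlacement Optional data.frame (`start`, `end`) of
#'   intervals the NLR paralog pairs must not touch (e.g. regions
#'   reserved for haploblocks, so unequal-crossover sites stay clear of
#'   their boundaries). Generic genes may still occupy them.
#' @param seed Integer seed; identical inputs and seed give byte-identical
#'   output.
#' @return An [AncestorModel-class].
#' @examples
#' anc <- simulateAncestor(2e5, geneDensity = 10,
#'                         nlrPairSpec = list(count = 1, identity = 97),
#'                         pairSpacing = 3e4, seed = 1)
#' anc
#' @export
simulateAncestor <- function(length, geneDensity = 10,
                             nlrPairSpec = list(count = 1, identity = 97),
                             pairSpacing = 5e4, nlrLen = 3000,
                             geneLenRange = c(1000, 3000),
                             repeatSalt = 0, avoidPairPlacement = NULL,
                             seed = 1) {
  length <- as.integer(length)
  stopifnot(length >= 1e5)
  npair <- nlrPairSpec$count
  if (npair > 0) {
    stopifnot(nlrPairSpec$identity >= 90, nlrPairSpec$identity <= 100)
  }
  .withSeed(seed, {
    ngenes <- round(length / 1e6 * geneDensity)
    ngeneric <- max(0L, ngenes - 2L * npair)
    # capacity check: each pair needs pairSpacing + nlrLen, generic genes
    # their own length, with breathing room between features
    need <- npair * (pairSpacing + nlrLen) +
      ngeneric * (max(geneLenRange) + 2000)
    if (need > 0.7 * length)
      stop("sizing error: chromosome too small to host requested genes")

    seq <- .randomSeq(length)
    occupied <- IRanges()
    avoid <- if (is.null(avoidPairPlacement)) IRanges() else
      IRanges(avoidPairPlacement$start, avoidPairPlacement$end)

    placeInterval <- function(w, alsoAvoid = IRanges()) {
      for (i in 1:200) {
        s <- sample.int(length - w - 2000L, 1) + 1000L
        cand <- IRanges(s, s + w - 1L)
        if (!any(IRanges::overlapsAny(cand + 500L, occupied)) &&
            !any(IRanges::overlapsAny(cand + 500L, alsoAvoid))) {
          occupied <<- c(occupied, cand)
          return(s)
        }
      }
      stop("sizing error: could not place features without overlap")
    }

    geneStart <- integer(); geneEnd <- integer()
    geneStrand <- character(); geneClass <- character()
    geneId <- character()
    pairs <- data.frame(geneA = character(), geneB = character(),
                        identity = numeric(), same_orientation = logical())

    for (p in seq_len(npair)) {
      span <- pairSpacing + nlrLen
      a1 <- placeInterval(span, alsoAvoid = avoid)
      a2 <- a1 + pairSpacing
      tmpl <- .randomSeq(nlrLen)
      copy <- .mutateToIdentity(tmpl, nlrPairSpec$identity / 100)
      substr(seq, a1, a1 + nlrLen - 1L) <- tmpl
      substr(seq, a2, a2 + nlrLen - 1L) <- copy
      idA <- sprintf("NLR%02da", p); idB <- sprintf("NLR%02db", p)
      st <- sample(c("+", "-"), 1)
      geneStart <- c(geneStart, a1, a2)
      geneEnd <- c(geneEnd, a1 + nlrLen - 1L, a2 + nlrLen - 1L)
      geneStrand <- c(geneStrand, st, st)
      geneClass <- c(geneClass, "NLR", "NLR")
      geneId <- c(geneId, idA, idB)
      pairs <- rbind(pairs, data.frame(
        geneA = idA, geneB = idB, identity = nlrPairSpec$identity,
        same_orientation = TRUE))
    }

    for (g in seq_len(ngeneric)) {
      w <- sample(seq(geneLenRange[1], geneLenRange[2]), 1)
      s <- placeInterval(w)
      geneStart <- c(geneStart, s)
      geneEnd <- c(geneEnd, s + w - 1L)
      geneStrand <- c(geneStrand, sample(c("+", "-"), 1))
      geneClass <- c(geneClass, "generic")
      geneId <- c(geneId, sprintf("G%04d", g))
    }

    reps <- IRanges()
    for (r in seq_len(repeatSalt)) {
      s <- placeInterval(400L)
      di <- paste(sample(.BASES, 2), collapse = "")
      substr(seq, s, s + 399L) <- strrep(di, 200)
      reps <- c(reps, IRanges(s, s + 399L))
    }

    genes <- GRanges(rep("chr", length(geneStart)),
                     IRanges(geneStart, geneEnd), strand = geneStrand)
    genes$gene_id <- geneId
    genes$class <- geneClass
    genes <- genes[order(start(genes))]
    new("AncestorModel", sequence = DNAString(seq), genes = genes,
        paralogPairs = pairs, repeats = reps)
  })
}

#' Plan planted InDels on an ancestor
#'
#' Chooses non-overlapping sites for SSA deletions, unequal-crossover
#' deletions (using the ancestor's embedded NLR paralog pairs) and decoy
#' assembly-gap InDels, avoiding gene models and haploblock intervals.
#'
#' @param ancestor An [AncestorModel-class].
#' @param nSSA,nDecoy Numbers of SSA and decoy-gap InDels.
#' @param nUCO Number of unequal-crossover InDels; must not exceed the
#'   number of paralog pairs in the ancestor.
#' @param sizeRange Size range (bp) for SSA/decoy deletions.
#' @param motifLen Microhomology motif length range for SSA.
#' @param carrier Genotype that keeps the sequence ("A" or "B"); may be a
#'   vector recycled over InDels.
#' @param haploblocks Optional data.frame (`start`, `end`) to avoid.
#' @param margin Minimum distance (bp) between planted features.
#' @param geneContainingSSA How many of the SSA deletions must fully
#'   contain at least one generic gene (those genes become truly unique
#'   to the carrier genotype).
#' @param seed Integer seed.
#' @return data.frame InDel specification consumed by [deriveGenotypes()].
#' @export
planIndels <- function(ancestor, nSSA = 1, nUCO = 1, nDecoy = 1,
                       sizeRange = c(2e4, 8e4), motifLen = c(3, 8),
                       carrier = "A", haploblocks = NULL,
                       margin = 1e4, geneContainingSSA = 0, seed = 1) {
  stopifnot(geneContainingSSA <= nSSA)
  stopifnot(nUCO <= nrow(ancestor@paralogPairs))
  L <- length(ancestor@sequence)
  .withSeed(seed, {
    forb <- ancestor@genes
    forbidden <- IRanges(start(forb) - 500L, end(forb) + 500L)
    if (!is.null(haploblocks) && nrow(haploblocks))
      forbidden <- c(forbidden,
                     IRanges(haploblocks$start - margin,
                             haploblocks$end + margin))
    spec <- data.frame(mechanism = character(), carrier = character(),
                       start = integer(), end = integer(),
                       motif = character(), pair = integer(),
                       crossover = integer())
    carrier <- rep(carrier, length.out = nSSA + nUCO + nDecoy)
    ci <- 0L
    # planted-feature exclusions (haploblocks + placed InDels), kept
    # separate from gene exclusions so gene-containing deletions can be
    # validated against them alone
    planted <- if (!is.null(haploblocks) && nrow(haploblocks))
      IRanges(haploblocks$start - margin, haploblocks$end + margin)
    else IRanges()

    # UCO sites are fixed by the paralog pairs
    ids <- ancestor@genes$gene_id
    for (u in seq_len(nUCO)) {
      ci <- ci + 1L
      pr <- ancestor@paralogPairs[u, ]
      gA <- ancestor@genes[match(pr$geneA, ids)]
      gB <- ancestor@genes[match(pr$geneB, ids)]
      tl <- width(gA)
      cx <- sample(seq(round(0.3 * tl), round(0.7 * tl)), 1)
      s <- start(gA) + cx
      e <- start(gB) + cx - 1L
      spec <- rbind(spec, data.frame(
        mechanism = "UCO", carrier = carrier[ci], start = s, end = e,
        motif = NA_character_, pair = u, crossover = cx))
      forbidden <- c(forbidden,
                     IRanges(start(gA) - margin, end(gB) + margin))
      planted <- c(planted,
                   IRanges(start(gA) - margin, end(gB) + margin))
    }

    place <- function(w) {
      for (i in 1:500) {
        s <- sample.int(L - w - 4e4, 1) + 2e4
        cand <- IRanges(s - margin, s + w - 1L + margin)
        if (!any(IRanges::overlapsAny(cand, forbidden))) {
          forbidden <<- c(forbidden, cand)
          planted <<- c(planted, cand)
          return(s)
        }
      }
      stop("specification error: could not place InDel without overlap")
    }

    # SSA deletions placed around a generic gene (gene fully contained)
    genericGenes <- ancestor@genes[ancestor@genes$class == "generic"]
    for (i in seq_len(geneContainingSSA)) {
      ci <- ci + 1L
      w <- sample(seq(sizeRange[1], sizeRange[2]), 1)
      placed <- FALSE
      for (gi in sample(seq_along(genericGenes))) {
        g <- genericGenes[gi]
        if (w < width(g) + 2000L) next
        pad <- sample.int(w - width(g) - 2000L, 1) + 1000L
        s <- start(g) - pad
        if (s < 2e4 || s + w - 1L > L - 2e4) next
        cand <- IRanges(s, s + w - 1L)
        # no partial gene overlap: every gene fully inside or outside
        gr <- IRanges::ranges(ancestor@genes)
        ovl <- gr[IRanges::overlapsAny(gr, cand)]
        if (any(start(ovl) < s | end(ovl) > s + w - 1L)) next
        # avoid other planted features and haploblocks (genes inside
        # the interval are intended)
        if (any(IRanges::overlapsAny(cand + margin, planted))) next
        k <- sample(seq(motifLen[1], motifLen[2]), 1)
        spec <- rbind(spec, data.frame(
          mechanism = "SSA", carrier = carrier[ci], start = s,
          end = s + w - 1L, motif = .randomSeq(k), pair = NA_integer_,
          crossover = NA_integer_))
        forbidden <- c(forbidden, cand + margin)
        planted <- c(planted, cand + margin)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("specification error: no gene-containing site available")
    }
    for (i in seq_len(nSSA - geneContainingSSA)) {
      ci <- ci + 1L
      w <- sample(seq(sizeRange[1], sizeRange[2]), 1)
      s <- place(w)
      k <- sample(seq(motifLen[1], motifLen[2]), 1)
      spec <- rbind(spec, data.frame(
        mechanism = "SSA", carrier = carrier[ci], start = s,
        end = s + w - 1L, motif = .randomSeq(k), pair = NA_integer_,
        crossover = NA_integer_))
    }
    for (i in seq_len(nDecoy)) {
      ci <- ci + 1L
      w <- sample(seq(sizeRange[1], sizeRange[2]), 1)
      s <- place(w)
      spec <- rbind(spec, data.frame(
        mechanism = "decoy_gap", carrier = carrier[ci], start = s,
        end = s + w - 1L, motif = NA_character_, pair = NA_integer_,
        crossover = NA_integer_))
    }
    spec
  })
}

#' Derive two genotypes from an ancestor
#'
#' Applies baseline SNPs (a Poisson process at `baselineSnpRate` per Mb,
#' elevated `fold`-times inside haploblock intervals), planted InDels with
#' their molecular signatures, and annotation drop-outs, returning the two
#' genotype sequences, their annotations, and a truth ledger.
#'
#' SNP alternate alleles are written into genotype B. InDel construction,
#' per mechanism:
#' \describe{
#'   \item{SSA}{the motif is written at both ends of the to-be-deleted
#'     interval (so the carrier keeps two copies flanking the segment);
#'     the other genotype loses the interval, keeping a single motif copy
#'     at the junction.}
#'   \item{UCO}{the deletion runs between the two members of a
#'     same-orientation paralog pair, from offset `crossover` in the first
#'     to the same offset in the second; the derived genotype keeps a
#'     single recombinant gene (5' of copy one, 3' of copy two).}
#'   \item{decoy_gap}{the segment is replaced in the derived assembly by a
#'     run of `gapRun` Ns (an unresolved assembly gap), creating an
#'     apparent InDel with Ns at both breakpoints.}
#' }
#'
#' @param ancestor An [AncestorModel-class].
#' @param baselineSnpRate SNPs per Mb outside haploblocks.
#' @param haploblockSpec data.frame with `start`, `end` (ancestor
#'   coordinates) and `fold` (density multiplier), or NULL.
#' @param indelSpec data.frame as produced by [planIndels()], or NULL.
#' @param dropoutFraction Fraction of genotype-B genes removed from B's
#'   annotation only (their sequence stays).
#' @param gapRun N-run length used for decoy gaps.
#' @param seed Integer seed.
#' @return A [ChromosomePair-class] with a filled [TruthLedger-class].
#' @export
deriveGenotypes <- function(ancestor, baselineSnpRate = 27,
                            haploblockSpec = NULL, indelSpec = NULL,
                            dropoutFraction = 0, gapRun = 100, seed = 1) {
  anc <- .chr(ancestor@sequence)
  L <- nchar(anc)
  hb <- if (is.null(haploblockSpec))
    data.frame(start = integer(), end = integer(), fold = numeric())
  else haploblockSpec
  ind <- if (is.null(indelSpec))
    data.frame(mechanism = character(), carrier = character(),
               start = integer(), end = integer(), motif = character(),
               pair = integer(), crossover = integer())
  else indelSpec

  # planted features must not overlap each other or haploblock boundaries
  if (nrow(ind)) {
    ir <- IRanges(ind$start, ind$end)
    if (length(IRanges::findOverlaps(ir, drop.self = TRUE,
                                     drop.redundant = TRUE)) > 0)
      stop("specification error: planted InDels overlap each other")
    if (nrow(hb)) {
      bounds <- IRanges(c(hb$start, hb$end), c(hb$start, hb$end))
      if (any(IRanges::overlapsAny(ir, bounds)))
        stop("specification error: InDel overlaps a haploblock boundary")
    }
  }
  if (nrow(hb)) {
    hr <- IRanges(hb$start, hb$end)
    if (length(IRanges::findOverlaps(hr, drop.self = TRUE,
                                     drop.redundant = TRUE)) > 0)
      stop("specification error: haploblock intervals overlap")
  }

  .withSeed(seed, {
    # 1. plant SSA motifs in the ancestor (inherited by both genotypes)
    for (i in which(ind$mechanism == "SSA")) {
      m <- ind$motif[i]; k <- nchar(m)
      s <- ind$start[i]; e <- ind$end[i]
      substr(anc, s - k, s - 1L) <- m
      substr(anc, e - k + 1L, e) <- m
    }

    # 2. SNPs: Poisson per segment, excluded near planted InDels
    excl <- IRanges()
    if (nrow(ind)) excl <- IRanges(ind$start - 60L, ind$end + 60L)
    segs <- data.frame(start = 1L, end = L, fold = 1)
    if (nrow(hb)) {
      hbr <- IRanges::reduce(IRanges(hb$start, hb$end))
      base <- IRanges::setdiff(IRanges(1L, L), IRanges(hb$start, hb$end))
      segs <- rbind(
        data.frame(start = start(base), end = end(base), fold = 1),
        data.frame(start = hb$start, end = hb$end, fold = hb$fold))
    }
    snpPos <- integer()
    for (i in seq_len(nrow(segs))) {
      w <- segs$end[i] - segs$start[i] + 1L
      lam <- w / 1e6 * baselineSnpRate * segs$fold[i]
      n <- stats::rpois(1, lam)
      if (n > 0)
        snpPos <- c(snpPos,
                    segs$start[i] - 1L + sample.int(w, min(n, w)))
    }
    snpPos <- sort(unique(snpPos))
    if (length(snpPos) && length(excl))
      snpPos <- snpPos[!IRanges::overlapsAny(
        IRanges(snpPos, snpPos), excl)]
    if (length(snpPos)) {
      ref <- substring(anc, snpPos, snpPos)
      keep <- ref %in% .BASES
      snpPos <- snpPos[keep]; ref <- ref[keep]
      alt <- vapply(ref, function(b) sample(setdiff(.BASES, b), 1), "")
    } else {
      ref <- character(); alt <- character()
    }

    # 3. per-genotype edit lists (the genotype NOT carrying the sequence
    # receives the deletion)
    mkEdits <- function(genotype) {
      rows <- which(ind$carrier != genotype)
      if (!length(rows))
        return(data.frame(start = integer(), end = integer(),
                          insert = character()))
      data.frame(
        start = ind$start[rows], end = ind$end[rows],
        insert = ifelse(ind$mechanism[rows] == "decoy_gap",
                        strrep("N", gapRun), ""))
    }
    editsA <- mkEdits("A")
    editsB <- mkEdits("B")

    seqA <- anc
    seqB <- anc
    if (length(snpPos)) {
      sv <- strsplit(seqB, "", fixed = TRUE)[[1]]
      sv[snpPos] <- alt
      seqB <- paste(sv, collapse = "")
    }
    seqA <- .applyEdits(seqA, editsA)
    seqB <- .applyEdits(seqB, editsB)

    # 4. annotations: lift ancestor genes through each genotype's edits
    genes <- ancestor@genes
    ids <- genes$gene_id
    recombIds <- character()
    lift <- function(edits, genotype) {
      gs <- .mapThroughEdits(start(genes), edits)
      ge <- .mapThroughEdits(end(genes), edits)
      keep <- !is.na(gs) & !is.na(ge)
      out <- GRanges(rep("chr", sum(keep)),
                     IRanges(gs[keep], ge[keep]),
                     strand = strand(genes)[keep])
      out$gene_id <- ids[keep]
      out$class <- genes$class[keep]
      # genes partially clipped by a deletion: drop (their model is gone)
      # then add the recombinant chimera for UCO deletions in this genotype
      for (i in which(ind$carrier != genotype &
                      ind$mechanism == "UCO")) {
        pr <- ancestor@paralogPairs[ind$pair[i], ]
        gA <- genes[match(pr$geneA, ids)]
        gB <- genes[match(pr$geneB, ids)]
        # drop clipped template halves if still present
        out <- out[!(out$gene_id %in% c(pr$geneA, pr$geneB))]
        a1 <- .mapThroughEdits(start(gA), edits)
        tl <- width(gA)
        rec <- GRanges("chr", IRanges(a1, a1 + tl - 1L),
                       strand = strand(gA))
        rec$gene_id <- paste0("rec_", pr$geneA, "_", pr$geneB)
        rec$class <- "NLR"
        recombIds <<- c(recombIds, rec$gene_id)
        out <- c(out, rec)
      }
      # drop genes that straddle a remaining deletion edge (clipped)
      wA <- width(out)
      wAnc <- width(genes)[match(out$gene_id, ids)]
      clipped <- !is.na(wAnc) & wA != wAnc
      out <- out[!clipped]
      sort(out)
    }
    genesA <- lift(editsA, "A")
    genesB <- lift(editsB, "B")

    # 5. annotation drop-outs from genotype B only (sequence untouched)
    dropped <- character()
    if (dropoutFraction > 0) {
      cand <- genesB$gene_id[genesB$class == "generic"]
      ndrop <- round(dropoutFraction * length(cand))
      if (ndrop > 0) {
        dropped <- sample(cand, ndrop)
        genesB <- genesB[!(genesB$gene_id %in% dropped)]
      }
    }

    # 6. truth ledger in final coordinates
    posA <- .mapThroughEdits(snpPos, editsA)
    posB <- .mapThroughEdits(snpPos, editsB)
    snps <- data.frame(pos = snpPos, posA = posA, posB = posB,
                       ref = unname(ref), alt = unname(alt))
    hbA <- hb
    if (nrow(hbA)) {
      hbA$start <- .mapThroughEdits(hb$start, editsA)
      hbA$end <- .mapThroughEdits(hb$end, editsA)
    }
    indels <- ind
    if (nrow(indels)) {
      carrierEdits <- list(A = editsA, B = editsB)
      n <- nrow(indels)
      indels$size <- indels$end - indels$start + 1L
      cs <- ce <- jx <- integer(n)
      for (i in seq_len(n)) {
        ced <- carrierEdits[[indels$carrier[i]]]
        ded <- carrierEdits[[setdiff(c("A", "B"), indels$carrier[i])]]
        cs[i] <- .mapThroughEdits(indels$start[i], ced)
        ce[i] <- .mapThroughEdits(indels$end[i], ced)
        jx[i] <- .mapThroughEdits(indels$end[i] + 1L, ded)
        if (indels$mechanism[i] == "decoy_gap")
          jx[i] <- jx[i] - gapRun  # junction at the N-run start
      }
      indels$start <- cs; indels$end <- ce; indels$junction <- jx
      indels$templateA <- NA_character_
      indels$templateB <- NA_character_
      uco <- which(indels$mechanism == "UCO")
      if (length(uco)) {
        indels$templateA[uco] <-
          ancestor@paralogPairs$geneA[indels$pair[uco]]
        indels$templateB[uco] <-
          ancestor@paralogPairs$geneB[indels$pair[uco]]
      }
    } else {
      indels <- data.frame(mechanism = character(), carrier = character(),
                           start = integer(), end = integer(),
                           motif = character(), pair = integer(),
                           crossover = integer(), size = integer(),
                           junction = integer(),
                           templateA = character(),
                           templateB = character())
    }
    ledger <- new("TruthLedger", snps = snps, haploblocks = hbA,
                  indels = indels, droppedGenes = dropped,
                  chimeras = data.frame(scaffold = character(),
                                        junction = integer()))
    new("ChromosomePair", seqA = DNAString(seqA), seqB = DNAString(seqB),
        genesA = genesA, genesB = genesB, truth = ledger)
  })
}

#' Fragment a genotype into a scaffold set
#'
#' Cuts a chromosome into scaffolds with sizes drawn from a gamma
#' distribution, shuffles and randomly reverse complements them, and
#' optionally joins distant pieces into chimeric scaffolds, recording
#' exact provenance. The pieces tile the source sequence with no loss.
#'
#' @param genotype Sequence (character or [Biostrings::DNAString]).
#' @param meanSize Mean scaffold size (bp).
#' @param cvSize Coefficient of variation of scaffold sizes.
#' @param nChimeras Number of chimeric scaffolds to create by joining two
#'   pieces that originate at least `chimeraDistance` apart.
#' @param chimeraDistance Minimum source distance (bp) between the parts
#'   of a chimera.
#' @param minChimeraPart Minimum size (bp) of each part of a chimera (so
#'   that segment sampling hits every part).
#' @param minSize Minimum scaffold size (bp).
#' @param seed Integer seed.
#' @return A [ScaffoldSet-class].
#' @export
fragmentIntoScaffolds <- function(genotype, meanSize = 1e5, cvSize = 0.5,
                                  nChimeras = 0, chimeraDistance = 1e6,
                                  minChimeraPart = 1.2e5, minSize = 2e3,
                                  seed = 1) {
  g <- .chr(genotype)
  L <- nchar(g)
  .withSeed(seed, {
    sizes <- integer()
    tot <- 0L
    shape <- 1 / cvSize^2
    while (tot < L) {
      s <- max(minSize, round(stats::rgamma(1, shape = shape,
                                            scale = meanSize / shape)))
      sizes <- c(sizes, as.integer(min(s, L - tot)))
      tot <- tot + sizes[length(sizes)]
    }
    if (nChimeras > length(sizes) / 2)
      stop("nChimeras must be at most half the scaffold count")
    ends <- cumsum(sizes)
    starts <- ends - sizes + 1L
    pieces <- data.frame(start = starts, end = ends)

    # choose chimera pairs: parts big enough and far apart
    big <- which(sizes >= minChimeraPart)
    pairUp <- list()
    used <- integer()
    for (ci in seq_len(nChimeras)) {
      cand <- setdiff(big, used)
      found <- FALSE
      for (a in sample(cand)) {
        bOk <- cand[abs(pieces$start[cand] - pieces$start[a]) >
                      chimeraDistance & cand != a]
        if (length(bOk)) {
          b <- if (length(bOk) == 1) bOk else sample(bOk, 1)
          pairUp[[ci]] <- c(a, b)
          used <- c(used, a, b)
          found <- TRUE
          break
        }
      }
      if (!found)
        stop("could not form requested chimeras; relax size constraints")
    }

    nPieces <- nrow(pieces)
    singles <- setdiff(seq_len(nPieces), used)
    scafSeq <- character()
    prov <- data.frame(scaffold = character(), part = integer(),
                       start = integer(), end = integer(),
                       orientation = character())
    chimJunctions <- data.frame(scaffold = character(),
                                junction = integer())
    addScaf <- function(idx, id) {
      parts <- character(length(idx))
      for (j in seq_along(idx)) {
        p <- idx[j]
        ss <- substr(g, pieces$start[p], pieces$end[p])
        ori <- sample(c("+", "-"), 1)
        if (ori == "-") ss <- .revcomp(ss)
        parts[j] <- ss
        prov <<- rbind(prov, data.frame(
          scaffold = id, part = j, start = pieces$start[p],
          end = pieces$end[p], orientation = ori))
      }
      if (length(idx) > 1)
        chimJunctions <<- rbind(chimJunctions, data.frame(
          scaffold = id,
          junction = cumsum(nchar(parts))[-length(parts)]))
      paste(parts, collapse = "")
    }
    order <- sample(c(lapply(singles, identity), pairUp))
    ids <- sprintf("scaffold_%03d", seq_along(order))
    scafSeq <- vapply(seq_along(order),
                      function(i) addScaf(order[[i]], ids[i]), "")
    seqs <- DNAStringSet(scafSeq)
    names(seqs) <- ids
    ss <- new("ScaffoldSet", sequences = seqs, provenance = prov)
    attr(ss, "chimeras") <- chimJunctions
    ss
  })
}
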