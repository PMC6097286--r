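# Gene-content comparison: one-way hits, RBH, unique-gene curation,
# collinearity, NLR clustering and CNV regions.

#' Extract gene sequences from a chromosome
#'
#' The genomic span of each gene model, reverse complemented for
#' minus-strand genes.
#'
#' @param seq Chromosome sequence.
#' @param genes [GenomicRanges::GRanges] with `gene_id` metadata.
#' @return Named character vector of gene sequences.
#' @export
geneSequences <- function(seq, genes) {
  s <- .chr(seq)
  out <- vapply(seq_along(genes), function(i) {
    g <- substr(s, start(genes)[i], end(genes)[i])
    if (as.character(strand(genes)[i]) == "-") g <- .revcomp(g)
    g
  }, "")
  names(out) <- genes$gene_id
  out
}

#' One-way best hits between two gene sets
#'
#' For every gene of the query set, its best alignment hit in the target
#' set (or none). The score cutoff stands in for a BLAST E-value cutoff
#' and is calibrated so that unrelated random sequences essentially never
#' hit.
#'
#' @param queryGenes,targetGenes Named character vectors of gene
#'   sequences (see [geneSequences()]).
#' @param scoreCutoff Minimum alignment score (identical columns) for a
#'   hit.
#' @param k Seed word size.
#' @return data.frame with one row per query gene: `gene`, `hit` (NA for
#'   no hit), `score`, `identity`.
#' @export
oneWayHits <- function(queryGenes, targetGenes, scoreCutoff = 100,
                       k = 15) {
  out <- data.frame(gene = names(queryGenes), hit = NA_character_,
                    score = NA_real_, identity = NA_real_,
                    stringsAsFactors = FALSE)
  if (!length(queryGenes) || !length(targetGenes)) return(out)
  # pre-screen against the concatenated target set (N separators block
  # cross-boundary words); only candidates sharing a seed are aligned
  sep <- strrep("N", k)
  cat_t <- paste(vapply(targetGenes, .chr, ""), collapse = sep)
  bounds <- cumsum(nchar(targetGenes) + k)
  starts <- c(1, utils::head(bounds, -1) + 1)
  for (i in seq_along(queryGenes)) {
    q <- .chr(queryGenes[[i]])
    cand <- integer()
    for (qq in c(q, .revcomp(q))) {
      m <- .kmerMatchesCpp(qq, cat_t, as.integer(k), 50L)
      if (nrow(m))
        cand <- c(cand, findInterval(m[, "tstart"], starts))
    }
    cand <- sort(unique(cand))
    bestScore <- -Inf; bestHit <- NA_character_; bestId <- NA_real_
    for (j in cand) {
      al <- seedExtendAlign(q, targetGenes[[j]], k = k,
                            minLen = k, minIdentity = 0.5)
      if (!nrow(al)) next
      sc <- al$score[1]
      if (sc > bestScore ||
          (sc == bestScore && !is.na(bestHit) &&
           names(targetGenes)[j] < bestHit)) {
        bestScore <- sc
        bestHit <- names(targetGenes)[j]
        bestId <- al$identity[1]
      }
    }
    if (bestScore >= scoreCutoff) {
      out$hit[i] <- bestHit
      out$score[i] <- bestScore
      out$identity[i] <- bestId
    }
  }
  out
}

#' Reciprocal best hits
#'
#' Pairs of genes that are each other's best hit; a symmetric,
#' one-to-one matching (paralog groups collapse to at most one pair).
#'
#' @param hitsAB One-way hit map A to B (see [oneWayHits()]).
#' @param hitsBA One-way hit map B to A.
#' @return data.frame with `geneA`, `geneB`.
#' @export
reciprocalBestHits <- function(hitsAB, hitsBA) {
  ab <- hitsAB[!is.na(hitsAB$hit), , drop = FALSE]
  ba <- hitsBA[!is.na(hitsBA$hit), , drop = FALSE]
  back <- ba$hit[match(ab$hit, ba$gene)]
  keep <- !is.na(back) & back == ab$gene
  out <- data.frame(geneA = ab$gene[keep], geneB = ab$hit[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Curate putatively unique genes against the other pseudomolecule
#'
#' Genes with no hit among the other genotype's annotated genes are
#' aligned to that genotype's full pseudomolecule: a spanning hit
#' (identity at least `identityFloor` over at least `coverage` of the
#' gene length) rescues the gene as annotation-missed; the rest are
#' truly unique.
#'
#' @param noHitGenes Named character vector of gene sequences.
#' @param otherPm The other genotype's pseudomolecule sequence.
#' @param identityFloor Minimum identity of the spanning hit.
#' @param coverage Minimum fraction of the gene length covered.
#' @param k Seed word size.
#' @return list with `rescued` and `trulyUnique` (character vectors of
#'   gene ids).
#' @export
curateUnique <- function(noHitGenes, otherPm, identityFloor = 0.9,
                         coverage = 0.8, k = 15) {
  pm <- if (is(otherPm, "Pseudomolecule")) .chr(otherPm@sequence)
        else .chr(otherPm)
  rescued <- character(); unique <- character()
  for (id in names(noHitGenes)) {
    g <- noHitGenes[[id]]
    al <- seedExtendAlign(g, pm, k = k, minLen = k,
                          minIdentity = identityFloor)
    ok <- nrow(al) > 0 &&
      any(al$identity >= identityFloor &
            (al$qend - al$qstart + 1) >= coverage * nchar(g))
    if (ok) rescued <- c(rescued, id) else unique <- c(unique, id)
  }
  list(rescued = rescued, trulyUnique = unique)
}

#' Non-collinear genes from RBH pair orders
#'
#' A reciprocal-best-hit pair is collinear when it lies on the longest
#' common subsequence of the two gene orders (equivalently, the
#' weight-maximal increasing run of partner ranks); genes off that
#' backbone are non-collinear. Genes on scaffolds carrying fewer than
#' `minGenesPerScaffold` genes are excluded from the analysis, since a
#' single-gene scaffold's placement carries no independent order
#' information.
#'
#' @param rbh RBH pairs ([reciprocalBestHits()]).
#' @param orderA,orderB Character vectors of gene ids in chromosomal
#'   order for each genotype.
#' @param scaffoldOfB Optional named character vector mapping genotype-B
#'   gene ids to their scaffold of origin.
#' @param minGenesPerScaffold Scaffolds with fewer genes are excluded.
#' @return data.frame with `geneA`, `geneB` for each non-collinear pair.
#' @export
collinearityTest <- function(rbh, orderA, orderB, scaffoldOfB = NULL,
                             minGenesPerScaffold = 2) {
  if (!is.null(scaffoldOfB)) {
    tab <- table(scaffoldOfB)
    small <- names(tab)[tab < minGenesPerScaffold]
    excl <- names(scaffoldOfB)[scaffoldOfB %in% small]
    rbh <- rbh[!(rbh$geneB %in% excl), , drop = FALSE]
  }
  rbh <- rbh[rbh$geneA %in% orderA & rbh$geneB %in% orderB, ,
             drop = FALSE]
  if (nrow(rbh) < 2)
    return(data.frame(geneA = character(), geneB = character()))
  rbh <- rbh[order(match(rbh$geneA, orderA)), , drop = FALSE]
  ranks <- match(rbh$geneB, orderB)
  lis <- .longestIncreasingRun(ranks)
  out <- rbh[-lis, , drop = FALSE]
  rownames(out) <- NULL
  out[, c("geneA", "geneB")]
}

# indices of a longest strictly increasing subsequence (leftmost on ties)
.longestIncreasingRun <- function(x) {
  n <- length(x)
  dp <- integer(n); prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    dp[i] <- 1L
    for (j in seq_len(i - 1L)) {
      if (x[j] < x[i] && dp[j] + 1L > dp[i]) {
        dp[i] <- dp[j] + 1L
        prev[i] <- j
      }
    }
  }
  i <- which.max(dp)
  keep <- integer()
  while (!is.na(i)) { keep <- c(i, keep); i <- prev[i] }
  keep
}

#' Cluster NLR genes by genomic distance
#'
#' Single-linkage clustering of NLR gene positions: consecutive NLRs at
#' most `maxGap` apart join a cluster; clusters of two or more genes are
#' reported.
#'
#' @param nlrGenes [GenomicRanges::GRanges] of NLR genes (with
#'   `gene_id`).
#' @param maxGap Maximum gap (bp) between consecutive cluster members.
#' @return list with `clusters` (data.frame `cluster`, `start`, `end`,
#'   `size`, `members`), `fractionClustered`, `largestCluster`,
#'   `totalNlrs`.
#' @export
clusterNlrs <- function(nlrGenes, maxGap = 2e5) {
  n <- length(nlrGenes)
  empty <- data.frame(cluster = integer(), start = integer(),
                      end = integer(), size = integer(),
                      members = character())
  if (n == 0)
    return(list(clusters = empty, fractionClustered = 0,
                largestCluster = 0L, totalNlrs = 0L))
  o <- order(start(nlrGenes))
  g <- nlrGenes[o]
  newc <- c(TRUE, start(g)[-1] - end(g)[-n] > maxGap)
  cid <- cumsum(newc)
  rows <- lapply(split(seq_len(n), cid), function(ix) {
    data.frame(cluster = cid[ix[1]], start = min(start(g)[ix]),
               end = max(end(g)[ix]), size = length(ix),
               members = paste(g$gene_id[ix], collapse = ","))
  })
  cl <- do.call(rbind, rows)
  cl <- cl[cl$size >= 2, , drop = FALSE]
  rownames(cl) <- NULL
  clustered <- sum(cl$size)
  list(clusters = cl,
       fractionClustered = clustered / n,
       largestCluster = if (nrow(cl)) max(cl$size) else 0L,
       totalNlrs = n)
}

#' Detect NLR copy-number-variant regions between genotypes
#'
#' Clusters are matched across genotypes via their flanking
#' reciprocal-best-hit anchor genes: the nearest non-NLR RBH gene on each
#' side of a cluster brackets an interval in both genotypes; differing
#' NLR counts inside the bracketed intervals define a CNV region.
#'
#' @param genesA,genesB [GenomicRanges::GRanges] annotations (with
#'   `gene_id`, `class`).
#' @param clustersA Cluster table for genotype A ([clusterNlrs()]
#'   `$clusters`), used to seed candidate regions.
#' @param rbh RBH pairs.
#' @param flankSearch Maximum distance (bp) from cluster edge to anchor.
#' @return data.frame with `startA`, `endA`, `startB`, `endB`, `countA`,
#'   `countB`, `anchorLeft`, `anchorRight` (genotype-A anchor ids);
#'   unanchorable clusters are reported with NA interval on B.
#' @export
detectCnvRegions <- function(genesA, genesB, clustersA, rbh,
                             flankSearch = 5e5) {
  out <- data.frame(startA = integer(), endA = integer(),
                    startB = integer(), endB = integer(),
                    countA = integer(), countB = integer(),
                    anchorLeft = character(), anchorRight = character())
  if (!nrow(clustersA)) return(out)
  anchA <- genesA[genesA$class != "NLR" & genesA$gene_id %in% rbh$geneA]
  for (i in seq_len(nrow(clustersA))) {
    cs <- clustersA$start[i]; ce <- clustersA$end[i]
    lf <- anchA[end(anchA) < cs & end(anchA) >= cs - flankSearch]
    rt <- anchA[start(anchA) > ce & start(anchA) <= ce + flankSearch]
    if (!length(lf) || !length(rt)) {
      out <- rbind(out, data.frame(
        startA = cs, endA = ce, startB = NA_integer_,
        endB = NA_integer_,
        countA = clustersA$size[i], countB = NA_integer_,
        anchorLeft = NA_character_, anchorRight = NA_character_))
      next
    }
    la <- lf[which.max(end(lf))]
    ra <- rt[which.min(start(rt))]
    laB <- rbh$geneB[match(la$gene_id, rbh$geneA)]
    raB <- rbh$geneB[match(ra$gene_id, rbh$geneA)]
    bL <- genesB[match(laB, genesB$gene_id)]
    bR <- genesB[match(raB, genesB$gene_id)]
    bs <- min(end(bL), end(bR)) + 1L
    be <- max(start(bL), start(bR)) - 1L
    inA <- genesA$class == "NLR" & start(genesA) > end(la) &
      end(genesA) < start(ra)
    inB <- genesB$class == "NLR" & start(genesB) >= bs &
      end(genesB) <= be
    cA <- sum(inA); cB <- sum(inB)
    if (cA != cB)
      out <- rbind(out, data.frame(
        startA = end(la) + 1L, endA = start(ra) - 1L,
        startB = bs, endB = be, countA = cA, countB = cB,
        anchorLeft = la$gene_id, anchorRight = ra$gene_id))
  }
  rownames(out) <- NULL
  out
}

#' Full gene-content comparison of a chromosome pair
#'
#' Runs one-way hits in both directions, reciprocal best hits,
#' unique-gene curation against the opposite pseudomolecule, and the
#' collinearity test, returning a [GeneComparison-class].
#'
#' @param pair A [ChromosomePair-class].
#' @param scoreCutoff,k See [oneWayHits()].
#' @param identityFloor,coverage See [curateUnique()].
#' @param scaffoldOfB,minGenesPerScaffold See [collinearityTest()].
#' @return A [GeneComparison-class].
#' @export
compareGenes <- function(pair, scoreCutoff = 100, k = 15,
                         identityFloor = 0.9, coverage = 0.8,
                         scaffoldOfB = NULL, minGenesPerScaffold = 2) {
  gsA <- geneSequences(pair@seqA, pair@genesA)
  gsB <- geneSequences(pair@seqB, pair@genesB)
  hAB <- oneWayHits(gsA, gsB, scoreCutoff = scoreCutoff, k = k)
  hBA <- oneWayHits(gsB, gsA, scoreCutoff = scoreCutoff, k = k)
  rbh <- reciprocalBestHits(hAB, hBA)
  puA <- hAB$gene[is.na(hAB$hit)]
  puB <- hBA$gene[is.na(hBA$hit)]
  cuA <- curateUnique(gsA[puA], pair@seqB, identityFloor = identityFloor,
                      coverage = coverage, k = k)
  cuB <- curateUnique(gsB[puB], pair@seqA, identityFloor = identityFloor,
                      coverage = coverage, k = k)
  nc <- collinearityTest(rbh,
                         pair@genesA$gene_id[order(start(pair@genesA))],
                         pair@genesB$gene_id[order(start(pair@genesB))],
                         scaffoldOfB = scaffoldOfB,
                         minGenesPerScaffold = minGenesPerScaffold)
  new("GeneComparison", hitsAB = hAB, hitsBA = hBA, rbh = rbh,
      putativeUniqueA = puA, putativeUniqueB = puB,
      rescuedA = cuA$rescued, rescuedB = cuB$rescued,
      trulyUniqueA = cuA$trulyUnique, trulyUniqueB = cuB$trulyUnique,
      nonCollinear = nc)
}
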