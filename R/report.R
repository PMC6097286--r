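# Pipeline orchestration, truth-ledger evaluation and summary arithmetic.

#' Evaluate calls against the truth ledger
#'
#' Matches calls to planted features (reciprocal overlap of at least 50%
#' or both boundaries within `tolerance`) and computes precision, recall
#' and boundary error per feature class, plus derived percentages.
#'
#' @param pair The simulated [ChromosomePair-class] (carries the truth).
#' @param callset [SvCallSet-class] of curated InDel calls, or NULL.
#' @param haploblocks data.frame of called haploblocks (genotype-A
#'   coordinates), or NULL.
#' @param geneCmp [GeneComparison-class], or NULL.
#' @param tolerance Boundary tolerance in bp.
#' @return list of class `EvaluationSummary`: per-class data.frame
#'   `metrics` (`class`, `nTruth`, `nCalled`, `nMatched`, `precision`,
#'   `recall`, `boundaryError`), `haploblockJaccard`, and
#'   `percentages`.
#' @export
evaluateAgainstTruth <- function(pair, callset = NULL,
                                 haploblocks = NULL, geneCmp = NULL,
                                 tolerance = 100) {
  tl <- pair@truth
  if (nrow(tl@indels) == 0 && nrow(tl@haploblocks) == 0 &&
      !length(tl@droppedGenes)) {
    message("evaluateAgainstTruth: empty truth ledger; skipped")
    return(invisible(NULL))
  }
  metrics <- list()
  addRow <- function(class, nTruth, nCalled, nMatched, be = NA_real_) {
    metrics[[class]] <<- data.frame(
      class = class, nTruth = nTruth, nCalled = nCalled,
      nMatched = nMatched,
      precision = if (nCalled > 0) nMatched / nCalled else NA_real_,
      recall = if (nTruth > 0) nMatched / nTruth else NA_real_,
      boundaryError = be)
  }

  matchIv <- function(ts, te, cs, ce) {
    ov <- pmax(0, pmin(te, ce) - pmax(ts, cs) + 1)
    recip <- ov >= 0.5 * (te - ts + 1) & ov >= 0.5 * (ce - cs + 1)
    nearBounds <- abs(ts - cs) <= tolerance & abs(te - ce) <= tolerance
    recip | nearBounds
  }

  if (!is.null(callset)) {
    truthReal <- tl@indels[tl@indels$mechanism != "decoy_gap", ,
                           drop = FALSE]
    called <- svCalls(callset)
    called <- called[called$validity %in% c("validated", "partial"), ,
                     drop = FALSE]
    matchedT <- logical(nrow(truthReal))
    matchedC <- logical(nrow(called))
    mechOk <- 0L
    be <- numeric()
    for (i in seq_len(nrow(truthReal))) {
      for (j in seq_len(nrow(called))) {
        if (truthReal$carrier[i] != called$carrier[j]) next
        if (matchIv(truthReal$start[i], truthReal$end[i],
                    called$start[j], called$end[j])) {
          matchedT[i] <- TRUE
          matchedC[j] <- TRUE
          be <- c(be, abs(truthReal$start[i] - called$start[j]))
          if (!is.na(called$mechanism[j]) &&
              called$mechanism[j] == truthReal$mechanism[i])
            mechOk <- mechOk + 1L
        }
      }
    }
    addRow("indels", nrow(truthReal), nrow(called), sum(matchedC),
           if (length(be)) mean(be) else NA_real_)
    addRow("mechanisms", sum(matchedT), sum(matchedT), mechOk)
    # decoy rejection
    decoys <- tl@indels[tl@indels$mechanism == "decoy_gap", ,
                        drop = FALSE]
    rejected <- svCalls(callset)
    rejected <- rejected[rejected$validity == "rejected", , drop = FALSE]
    nRej <- 0L
    for (i in seq_len(nrow(decoys))) {
      hit <- FALSE
      for (j in seq_len(nrow(rejected))) {
        if (decoys$carrier[i] == rejected$carrier[j] &&
            matchIv(decoys$start[i], decoys$end[i],
                    rejected$start[j], rejected$end[j]))
          hit <- TRUE
      }
      if (hit) nRej <- nRej + 1L
    }
    addRow("decoys_rejected", nrow(decoys), nrow(rejected), nRej)
  }

  jac <- NA_real_
  if (!is.null(haploblocks) && nrow(tl@haploblocks)) {
    th <- tl@haploblocks
    matchedT <- logical(nrow(th)); matchedC <- logical(nrow(haploblocks))
    jj <- numeric()
    be <- numeric()
    for (i in seq_len(nrow(th))) {
      for (j in seq_len(nrow(haploblocks))) {
        ov <- max(0, min(th$end[i], haploblocks$end[j]) -
                    max(th$start[i], haploblocks$start[j]) + 1)
        un <- max(th$end[i], haploblocks$end[j]) -
          min(th$start[i], haploblocks$start[j]) + 1
        if (ov / un > 0) {
          if (ov >= 0.5 * (th$end[i] - th$start[i] + 1)) {
            matchedT[i] <- TRUE; matchedC[j] <- TRUE
            jj <- c(jj, ov / un)
            be <- c(be, abs(th$start[i] - haploblocks$start[j]),
                    abs(th$end[i] - haploblocks$end[j]))
          }
        }
      }
    }
    addRow("haploblocks", nrow(th), nrow(haploblocks), sum(matchedC),
           if (length(be)) mean(be) else NA_real_)
    jac <- if (length(jj)) mean(jj) else 0
  }

  if (!is.null(geneCmp)) {
    dropped <- tl@droppedGenes
    addRow("dropout_rescue", length(dropped),
           length(geneCmp@rescuedA),
           length(intersect(geneCmp@rescuedA, dropped)))
    # genes truly unique to A: annotated on A, inside a deletion carried
    # by A (i.e. absent from B sequence)
    delA <- tl@indels[tl@indels$carrier == "A" &
                        tl@indels$mechanism != "decoy_gap", ,
                      drop = FALSE]
    gA <- pair@genesA
    expUnique <- character()
    for (i in seq_len(nrow(delA))) {
      inDel <- start(gA) >= delA$start[i] & end(gA) <= delA$end[i]
      expUnique <- c(expUnique, gA$gene_id[inDel])
    }
    addRow("truly_unique", length(expUnique),
           length(geneCmp@trulyUniqueA),
           length(intersect(geneCmp@trulyUniqueA, expUnique)))
  }

  out <- list(metrics = do.call(rbind, metrics),
              haploblockJaccard = jac)
  rownames(out$metrics) <- NULL
  class(out) <- "EvaluationSummary"
  out
}

#' @export
print.EvaluationSummary <- function(x, ...) {
  cat("EvaluationSummary\n")
  print(x$metrics, row.names = FALSE)
  if (!is.na(x$haploblockJaccard))
    cat("mean haploblock Jaccard:", round(x$haploblockJaccard, 3), "\n")
  invisible(x)
}

#' Percentages from integer counts, at reported precision
#'
#' Each percentage is `100 * numerator / denominator`, rounded to one
#' decimal place, or two decimal places for values below 1.
#'
#' @param numerators,denominators Integer vectors (recycled names from
#'   `numerators` are kept).
#' @return Named numeric vector of percentages.
#' @examples
#' summaryPercentages(c(unique = 26), c(6018))    # 0.43
#' summaryPercentages(c(clustered = 62), c(161))  # 38.5
#' @export
summaryPercentages <- function(numerators, denominators) {
  if (any(denominators == 0)) stop("undefined input: zero denominator")
  p <- 100 * numerators / denominators
  out <- ifelse(p < 1, round(p, 2), round(p, 1))
  names(out) <- names(numerators)
  out
}

#' Run the full synthetic two-genotype comparison pipeline
#'
#' Simulates an ancestor and a derived genotype pair with planted InDels,
#' haploblocks and annotation drop-outs, then runs InDel calling and
#' curation, mechanism classification, SNP/haploblock analysis and gene
#' comparison, and evaluates everything against the truth ledger. One
#' structured log line per stage reports input/output counts.
#'
#' @param chromLen Chromosome length (bp).
#' @param seed Master seed for all stochastic steps.
#' @param geneDensity Genes per Mb.
#' @param nSSA,nUCO,nDecoy Planted InDel counts.
#' @param indelSizeRange SSA/decoy deletion size range (bp).
#' @param baselineSnpRate Baseline SNP density (SNPs/Mb).
#' @param haploblockSpec data.frame (`start`, `end`, `fold`) or NULL for
#'   a default of two planted blocks at fold 100.
#' @param dropoutFraction Annotation drop-out fraction.
#' @param minIndelSize Minimum InDel size called.
#' @param densityWindow,densityStep Haploblock density window/step (bp).
#' @param foldThreshold Haploblock call threshold (fold over median).
#' @param refineWindow Haploblock boundary refinement window (bp).
#' @param quiet Suppress stage logging.
#' @return list with `pair`, `callset`, `snps`, `track`, `haploblocks`,
#'   `genes`, `evaluation`.
#' @export
runPipeline <- function(chromLen = 5e6, seed = 1, geneDensity = 10,
                        nSSA = 1, nUCO = 1, nDecoy = 1,
                        indelSizeRange = c(2e4, 8e4),
                        baselineSnpRate = 27, haploblockSpec = NULL,
                        dropoutFraction = 0.05, minIndelSize = 1e4,
                        densityWindow = 2.5e5,
                        densityStep = densityWindow / 5,
                        foldThreshold = 10,
                        refineWindow = 5000, quiet = FALSE) {
  log <- function(...) if (!quiet) message("[svduet] ", ...)
  if (is.null(haploblockSpec)) {
    haploblockSpec <- data.frame(
      start = round(c(0.1, 0.62) * chromLen),
      end = round(c(0.2, 0.74) * chromLen),
      fold = 100)
  }
  anc <- simulateAncestor(chromLen, geneDensity = geneDensity,
                          nlrPairSpec = list(count = max(1, nUCO),
                                             identity = 97),
                          pairSpacing = mean(indelSizeRange),
                          avoidPairPlacement = data.frame(
                            start = haploblockSpec$start - 2e4,
                            end = haploblockSpec$end + 2e4),
                          seed = seed)
  log("ancestor: ", chromLen, " bp, ", length(anc@genes), " genes")
  ind <- planIndels(anc, nSSA = nSSA, nUCO = nUCO, nDecoy = nDecoy,
                    sizeRange = indelSizeRange,
                    haploblocks = haploblockSpec,
                    geneContainingSSA = min(1, nSSA), seed = seed + 1)
  pair <- deriveGenotypes(anc, baselineSnpRate = baselineSnpRate,
                          haploblockSpec = haploblockSpec,
                          indelSpec = ind,
                          dropoutFraction = dropoutFraction,
                          seed = seed + 2)
  log("genotypes: A ", length(pair@seqA), " bp / B ",
      length(pair@seqB), " bp, ", nrow(pair@truth@snps), " SNPs, ",
      nrow(pair@truth@indels), " planted InDels")

  chain <- .collinearChain(.chr(pair@seqA), .chr(pair@seqB))
  callset <- callLargeIndels(pair@seqA, pair@seqB,
                             minIndelSize = minIndelSize, chain = chain)
  log("svcall: ", length(callset), " candidates, ",
      sum(svCalls(callset)$validity == "validated"), " validated, ",
      sum(svCalls(callset)$validity == "rejected"),
      " rejected by the N rule")
  callset <- classifyCallSet(callset, pair)
  log("mechanism: ",
      paste(svCalls(callset)$mechanism[
        svCalls(callset)$validity != "rejected"], collapse = ", "))

  snps <- callSnps(pair@seqA, pair@seqB, chain = chain)
  track <- densityTrack(snps, length(pair@seqA), w = densityWindow,
                        s = densityStep)
  hb <- segmentHaploblocks(track, foldThreshold = foldThreshold)
  if (nrow(hb)) {
    for (i in seq_len(nrow(hb))) {
      r <- refineBlockBreakpoints(hb[i, ], pair@seqA, pair@seqB,
                                  refineWindow = refineWindow,
                                  searchSpan = densityWindow +
                                    densityStep, chain = chain)
      hb$start[i] <- r$start
      hb$end[i] <- r$end
    }
  }
  log("haploblock: ", nrow(snps), " SNPs, ", nrow(hb),
      " blocks called")

  genes <- compareGenes(pair)
  log("genes: ", nrow(genes@rbh), " RBH pairs, ",
      length(genes@rescuedA), " rescued, ",
      length(genes@trulyUniqueA), " truly unique (A)")

  ev <- evaluateAgainstTruth(pair, callset = callset,
                             haploblocks = hb, geneCmp = genes)
  list(pair = pair, callset = callset, snps = snps, track = track,
       haploblocks = hb, genes = genes, evaluation = ev)
}
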