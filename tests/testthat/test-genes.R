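# Gene-content comparison: hits, RBH, curation, collinearity, NLR
# clusters and CNV regions.

makeGeneSet <- function(n, len = 1200, seed = 1) {
  set.seed(seed)
  g <- vapply(seq_len(n), function(i) randomDna(len), "")
  names(g) <- sprintf("g%02d", seq_len(n))
  g
}

test_that("identical gene sets hit themselves and form full RBH", {
  gs <- makeGeneSet(8, seed = 111)
  h <- oneWayHits(gs, gs)
  expect_identical(h$hit, h$gene)
  rbh <- reciprocalBestHits(h, h)
  expect_equal(nrow(rbh), 8L)
  expect_identical(rbh$geneA, rbh$geneB)
})

test_that("novel genes produce no hits; diverged paralogs still hit", {
  gsA <- makeGeneSet(10, seed = 112)
  gsB <- gsA[1:5]
  h <- oneWayHits(gsA, gsB)
  expect_equal(sum(is.na(h$hit)), 5L)
  expect_identical(h$gene[is.na(h$hit)], names(gsA)[6:10])
  # a 95%-identical paralog is found above the cutoff
  p <- gsA[[1]]
  v <- strsplit(p, "")[[1]]
  pos <- sample(length(v), round(0.05 * length(v)))
  for (i in pos) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  gsB2 <- c(gsB, para = paste(v, collapse = ""))
  h1 <- oneWayHits(gsA["g01"], gsB2["para"])
  expect_equal(h1$hit, "para")
  expect_gt(h1$identity, 0.9)
})

test_that("random sequences essentially never hit (cutoff calibration)", {
  set.seed(113)
  q <- vapply(1:60, function(i) randomDna(1000), "")
  names(q) <- paste0("q", 1:60)
  t <- vapply(1:60, function(i) randomDna(1000), "")
  names(t) <- paste0("t", 1:60)
  h <- oneWayHits(q, t)  # 3600 random pairs
  expect_equal(sum(!is.na(h$hit)), 0L)
})

test_that("RBH is one-to-one and transpose-symmetric", {
  gsA <- makeGeneSet(12, seed = 114)
  # duplicate one gene in A: only one copy may enter an RBH pair
  gsA2 <- c(gsA, g01b = gsA[["g01"]])
  gsB <- gsA
  hAB <- oneWayHits(gsA2, gsB)
  hBA <- oneWayHits(gsB, gsA2)
  rbh <- reciprocalBestHits(hAB, hBA)
  expect_lte(sum(rbh$geneA %in% c("g01", "g01b")), 1L)
  expect_false(anyDuplicated(rbh$geneA) > 0)
  expect_false(anyDuplicated(rbh$geneB) > 0)
  # symmetry against the transposed computation
  rbh2 <- reciprocalBestHits(hBA, hAB)
  flip <- data.frame(geneA = rbh2$geneB, geneB = rbh2$geneA)
  expect_setequal(paste(rbh$geneA, rbh$geneB),
                  paste(flip$geneA, flip$geneB))
})

test_that("curation rescues annotation-missed genes and keeps
          deletion-resident genes unique", {
  set.seed(115)
  geneSeqs <- makeGeneSet(4, seed = 115)
  pm <- paste0(randomDna(5000), geneSeqs[[1]], randomDna(5000),
               geneSeqs[[2]], randomDna(5000))
  cu <- curateUnique(geneSeqs, pm)
  expect_setequal(cu$rescued, c("g01", "g02"))
  expect_setequal(cu$trulyUnique, c("g03", "g04"))
  cu0 <- curateUnique(geneSeqs[0], pm)
  expect_length(cu0$rescued, 0L)
  expect_length(cu0$trulyUnique, 0L)
})

test_that("collinearity flags a transposed gene via the LCS backbone", {
  ids <- sprintf("g%02d", 1:30)
  rbh <- data.frame(geneA = ids, geneB = ids)
  orderA <- ids
  # move g05 twenty positions away in B
  orderB <- ids[-5]
  orderB <- append(orderB, "g05", after = 24)
  nc <- collinearityTest(rbh, orderA, orderB)
  expect_equal(nc$geneA, "g05")
  # identical orders: nothing flagged
  expect_equal(nrow(collinearityTest(rbh, orderA, orderA)), 0L)
  # brute-force LCS oracle agrees on the flagged count
  lcsLen <- function(x, y) {
    m <- matrix(0L, length(x) + 1, length(y) + 1)
    for (i in seq_along(x)) for (j in seq_along(y))
      m[i + 1, j + 1] <- if (x[i] == y[j]) m[i, j] + 1L
        else max(m[i, j + 1], m[i + 1, j])
    m[length(x) + 1, length(y) + 1]
  }
  expect_equal(nrow(nc), length(ids) - lcsLen(orderA, orderB))
})

test_that("one-gene scaffolds are excluded from the collinearity test", {
  ids <- sprintf("g%02d", 1:10)
  rbh <- data.frame(geneA = ids, geneB = ids)
  orderB <- c(ids[-2], ids[2])       # g02 moved to the end
  scaff <- setNames(c("s1", "s2", rep("s3", 8)), ids)  # g02 alone on s2
  nc <- collinearityTest(rbh, ids, orderB, scaffoldOfB = scaff)
  expect_false("g02" %in% nc$geneB)
  # without the scaffold rule the same gene is flagged
  nc2 <- collinearityTest(rbh, ids, orderB)
  expect_true("g02" %in% nc2$geneB)
})

test_that("NLR clustering matches the printed arithmetic and is
          monotone in max_gap", {
  set.seed(116)
  # positions: a cluster of 3, a cluster of 2, three singletons
  starts <- c(1e5, 1.5e5, 2.0e5, 1e6, 1.05e6, 3e6, 5e6, 8e6)
  gr <- GenomicRanges::GRanges("chr",
          IRanges::IRanges(starts, starts + 3000))
  gr$gene_id <- sprintf("nlr%d", seq_along(starts))
  cl <- clusterNlrs(gr, maxGap = 2e5)
  expect_equal(nrow(cl$clusters), 2L)
  expect_equal(sort(cl$clusters$size), c(2L, 3L))
  expect_equal(cl$fractionClustered, 5 / 8)
  expect_equal(cl$largestCluster, 3L)
  # no clustering when genes are far apart
  cl0 <- clusterNlrs(gr, maxGap = 1e4)
  expect_equal(nrow(cl0$clusters), 0L)
  expect_equal(cl0$fractionClustered, 0)
  # limit case: one cluster containing all
  clAll <- clusterNlrs(gr, maxGap = 1e7)
  expect_equal(nrow(clAll$clusters), 1L)
  expect_equal(clAll$clusters$size, 8L)
  # monotone non-decreasing clustered fraction
  fr <- vapply(c(1e4, 5e4, 1e5, 5e5, 1e6, 1e7),
               function(g) clusterNlrs(gr, maxGap = g)$fractionClustered,
               0)
  expect_true(all(diff(fr) >= 0))
})

test_that("CNV regions are matched via flanking RBH anchors", {
  mkGenes <- function(starts, classes, ids) {
    gr <- GenomicRanges::GRanges("chr",
            IRanges::IRanges(starts, starts + 2000))
    gr$gene_id <- ids
    gr$class <- classes
    gr
  }
  # A: anchor L, 5 NLRs, anchor R; B: same anchors, 2 NLRs
  gA <- mkGenes(c(1e5, 2e5, 2.2e5, 2.4e5, 2.6e5, 2.8e5, 4e5),
                c("generic", rep("NLR", 5), "generic"),
                c("aL", paste0("nA", 1:5), "aR"))
  gB <- mkGenes(c(1e5, 2e5, 2.2e5, 3e5),
                c("generic", "NLR", "NLR", "generic"),
                c("bL", "nB1", "nB2", "bR"))
  rbh <- data.frame(geneA = c("aL", "aR"), geneB = c("bL", "bR"))
  clA <- clusterNlrs(gA[gA$class == "NLR"], maxGap = 1e5)$clusters
  cnv <- detectCnvRegions(gA, gB, clA, rbh)
  expect_equal(nrow(cnv), 1L)
  expect_equal(cnv$countA, 5L)
  expect_equal(cnv$countB, 2L)
  expect_equal(cnv$anchorLeft, "aL")
  # equal counts: no region reported
  gB2 <- mkGenes(c(1e5, 2e5, 2.2e5, 2.4e5, 2.6e5, 2.8e5, 4e5),
                 c("generic", rep("NLR", 5), "generic"),
                 c("bL", paste0("nB", 1:5), "bR"))
  expect_equal(nrow(detectCnvRegions(gA, gB2, clA, rbh)), 0L)
  # zero NLRs on one side still forms a region
  gB3 <- mkGenes(c(1e5, 3e5), c("generic", "generic"), c("bL", "bR"))
  cnv3 <- detectCnvRegions(gA, gB3, clA, rbh)
  expect_equal(cnv3$countB, 0L)
  # unanchorable cluster reported unmatched
  rbh0 <- data.frame(geneA = character(), geneB = character())
  un <- detectCnvRegions(gA, gB, clA, rbh0)
  expect_true(is.na(un$startB[1]))
})

test_that("drop-outs are rescued and deletion genes truly unique on
          simulated pairs", {
  for (seed in c(121, 122)) {
    anc <- simulateAncestor(1.5e6, geneDensity = 20,
                            nlrPairSpec = list(count = 1, identity = 97),
                            pairSpacing = 2e4, seed = seed)
    ind <- planIndels(anc, nSSA = 1, nUCO = 0, nDecoy = 0,
                      sizeRange = c(1.5e4, 2.5e4), margin = 5e3,
                      geneContainingSSA = 1, seed = seed + 1)
    pair <- deriveGenotypes(anc, baselineSnpRate = 0, indelSpec = ind,
                            dropoutFraction = 0.1, seed = seed + 2)
    tl <- truth(pair)
    cmp <- compareGenes(pair)
    # every drop-out rescued (annotation-missed, sequence intact)
    expect_setequal(cmp@rescuedA, tl@droppedGenes)
    # exactly the deletion-resident genes are truly unique
    delGenes <- genesA(pair)$gene_id[
      start(genesA(pair)) >= tl@indels$start[1] &
        end(genesA(pair)) <= tl@indels$end[1]]
    expect_gte(length(delGenes), 1L)
    expect_setequal(cmp@trulyUniqueA, delGenes)
    expect_length(intersect(cmp@rescuedA, cmp@trulyUniqueA), 0L)
  }
})
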