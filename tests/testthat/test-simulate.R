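# Synthetic-data generator: ancestor, derived genotypes, scaffolding.

test_that("ancestor simulation honours gene density and pair identity", {
  anc <- simulateAncestor(1e6, geneDensity = 10,
                          nlrPairSpec = list(count = 1, identity = 97),
                          pairSpacing = 3e4, seed = 1)
  expect_equal(length(anc@genes), 10L)
  expect_equal(sum(anc@genes$class == "NLR"), 2L)
  pp <- anc@paralogPairs
  expect_equal(nrow(pp), 1L)
  ids <- anc@genes$gene_id
  gA <- anc@genes[match(pp$geneA, ids)]
  gB <- anc@genes[match(pp$geneB, ids)]
  expect_equal(as.character(strand(gA)), as.character(strand(gB)))
  # independent global-alignment oracle for the emitted pair identity
  sA <- substr(as.character(anc@sequence), start(gA), end(gA))
  sB <- substr(as.character(anc@sequence), start(gB), end(gB))
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(sA),
                                      Biostrings::DNAString(sB),
                                      type = "global")
  expect_lt(abs(Biostrings::pid(al) - 97), 0.5)
})

test_that("zero gene density gives an empty gene list", {
  anc <- simulateAncestor(1e5, geneDensity = 0,
                          nlrPairSpec = list(count = 0), seed = 1)
  expect_equal(length(anc@genes), 0L)
})

test_that("simulation is deterministic for a fixed seed", {
  a1 <- simulateAncestor(1.5e5, seed = 7)
  a2 <- simulateAncestor(1.5e5, seed = 7)
  expect_identical(as.character(a1@sequence), as.character(a2@sequence))
  expect_identical(start(a1@genes), start(a2@genes))
  a3 <- simulateAncestor(1.5e5, seed = 8)
  expect_false(identical(as.character(a1@sequence),
                         as.character(a3@sequence)))
})

test_that("a chromosome too small for its genes raises a sizing error", {
  expect_error(simulateAncestor(1e5, geneDensity = 400, seed = 1),
               "sizing error")
})

test_that("zero divergence reproduces the ancestor exactly", {
  anc <- simulateAncestor(1.2e5, geneDensity = 5,
                          nlrPairSpec = list(count = 0), seed = 2)
  pair <- deriveGenotypes(anc, baselineSnpRate = 0, seed = 3)
  expect_identical(as.character(pair@seqA), as.character(anc@sequence))
  expect_identical(as.character(pair@seqB), as.character(anc@sequence))
  expect_equal(nrow(truth(pair)@snps), 0L)
})

test_that("planted SNPs are exactly the observed differences", {
  anc <- simulateAncestor(5e5, geneDensity = 0,
                          nlrPairSpec = list(count = 0), seed = 4)
  pair <- deriveGenotypes(anc, baselineSnpRate = 100, seed = 5)
  tl <- truth(pair)
  a <- strsplit(as.character(pair@seqA), "")[[1]]
  b <- strsplit(as.character(pair@seqB), "")[[1]]
  diffs <- which(a != b)
  expect_identical(diffs, tl@snps$pos)
  expect_identical(a[diffs], tl@snps$ref)
  expect_identical(b[diffs], tl@snps$alt)
})

test_that("realized SNP counts stay inside the Poisson 99% band", {
  # 30 SNPs/Mb on 10 Mb: central 99% interval of Poisson(300)
  lo <- qpois(0.005, 300); hi <- qpois(0.995, 300)
  anc <- simulateAncestor(2e6, geneDensity = 0,
                          nlrPairSpec = list(count = 0), seed = 6)
  n <- 0
  for (s in 1:5) {  # 5 x 2 Mb = 10 Mb at 30 SNPs/Mb
    p <- deriveGenotypes(anc, baselineSnpRate = 30, seed = s)
    n <- n + nrow(truth(p)@snps)
  }
  expect_gte(n, lo)
  expect_lte(n, hi)
})

test_that("SSA deletions carry the motif twice in the carrier and once
          at the derived junction", {
  anc <- simulateAncestor(3e5, geneDensity = 0,
                          nlrPairSpec = list(count = 0), seed = 7)
  spec <- data.frame(mechanism = "SSA", carrier = "A", start = 150001,
                     end = 180000, motif = "CGA", pair = NA,
                     crossover = NA)
  pair <- deriveGenotypes(anc, baselineSnpRate = 0, indelSpec = spec,
                          seed = 8)
  a <- as.character(pair@seqA); b <- as.character(pair@seqB)
  expect_equal(nchar(a) - nchar(b), 30000L)
  # carrier: motif immediately left of the interval and at its end
  expect_equal(substr(a, 149998, 150000), "CGA")
  expect_equal(substr(a, 179998, 180000), "CGA")
  # derived: single copy at the junction
  jx <- truth(pair)@indels$junction[1]
  expect_equal(substr(b, jx - 3, jx - 1), "CGA")
  # derived equals carrier with the interval spliced out
  expect_identical(b, paste0(substr(a, 1, 150000),
                             substr(a, 180001, nchar(a))))
})

test_that("UCO deletions produce a recombinant single copy", {
  anc <- simulateAncestor(3e5, geneDensity = 4,
                          nlrPairSpec = list(count = 1, identity = 96),
                          pairSpacing = 4e4, seed = 9)
  ind <- planIndels(anc, nSSA = 0, nUCO = 1, nDecoy = 0, seed = 10)
  pair <- deriveGenotypes(anc, baselineSnpRate = 0, indelSpec = ind,
                          seed = 11)
  tl <- truth(pair)
  expect_equal(nchar(as.character(pair@seqA)) -
                 nchar(as.character(pair@seqB)), tl@indels$size[1])
  # derived annotation holds one recombinant NLR instead of the pair
  recs <- grep("^rec_", pair@genesB$gene_id, value = TRUE)
  expect_length(recs, 1L)
  expect_false(any(c("NLR01a", "NLR01b") %in% pair@genesB$gene_id))
  # the recombinant is 5' of copy one + 3' of copy two
  ids <- anc@genes$gene_id
  gA <- anc@genes[match("NLR01a", ids)]
  gB <- anc@genes[match("NLR01b", ids)]
  ancSeq <- as.character(anc@sequence)
  cx <- tl@indels$crossover[1]
  gR <- pair@genesB[pair@genesB$gene_id == recs]
  recSeq <- substr(as.character(pair@seqB), start(gR), end(gR))
  expected <- paste0(substr(ancSeq, start(gA), start(gA) + cx - 1),
                     substr(ancSeq, start(gB) + cx, end(gB)))
  expect_identical(recSeq, expected)
})

test_that("decoy gaps leave N runs at an apparent InDel junction", {
  anc <- simulateAncestor(3e5, geneDensity = 0,
                          nlrPairSpec = list(count = 0), seed = 12)
  spec <- data.frame(mechanism = "decoy_gap", carrier = "A",
                     start = 100001, end = 140000, motif = NA,
                     pair = NA, crossover = NA)
  pair <- deriveGenotypes(anc, baselineSnpRate = 0, indelSpec = spec,
                          gapRun = 100, seed = 13)
  b <- as.character(pair@seqB)
  jx <- truth(pair)@indels$junction[1]
  expect_equal(substr(b, jx, jx + 99), strrep("N", 100))
  expect_equal(nchar(b), 3e5 - 40000 + 100)
})

test_that("overlapping planted features raise a specification error", {
  anc <- simulateAncestor(3e5, geneDensity = 0,
                          nlrPairSpec = list(count = 0), seed = 14)
  spec <- data.frame(mechanism = c("SSA", "SSA"), carrier = "A",
                     start = c(1e5, 1.2e5), end = c(1.3e5, 1.5e5),
                     motif = "CGA", pair = NA, crossover = NA)
  expect_error(deriveGenotypes(anc, indelSpec = spec, seed = 1),
               "specification error")
  hb <- data.frame(start = 1.25e5, end = 2e5, fold = 10)
  expect_error(deriveGenotypes(anc, indelSpec = spec[1, ],
                               haploblockSpec = hb, seed = 1),
               "specification error")
})

test_that("annotation drop-outs remove genes from one GFF only", {
  anc <- simulateAncestor(1e6, geneDensity = 20,
                          nlrPairSpec = list(count = 0), seed = 15)
  pair <- deriveGenotypes(anc, baselineSnpRate = 0,
                          dropoutFraction = 0.2, seed = 16)
  tl <- truth(pair)
  expect_equal(length(tl@droppedGenes), 4L)
  expect_false(any(tl@droppedGenes %in% pair@genesB$gene_id))
  expect_true(all(tl@droppedGenes %in% pair@genesA$gene_id))
  # sequence untouched
  expect_identical(as.character(pair@seqA), as.character(pair@seqB))
})

test_that("fragmentation tiles the genotype without loss", {
  g <- randomDna(2e6, seed = 17)
  ss <- fragmentIntoScaffolds(g, meanSize = 1e5, nChimeras = 0,
                              seed = 18)
  pv <- provenance(ss)
  # every scaffold one provenance interval
  expect_equal(max(table(pv$scaffold)), 1L)
  # intervals tile the source exactly
  pv <- pv[order(pv$start), ]
  expect_equal(pv$start[1], 1L)
  expect_equal(pv$end[nrow(pv)], 2e6)
  expect_true(all(pv$start[-1] == pv$end[-nrow(pv)] + 1L))
  # conservation: scaffold lengths sum to the genotype length
  expect_equal(sum(Biostrings::width(scaffoldSeqs(ss))), 2e6)
  # provenance reproduces each scaffold sequence
  for (i in sample(nrow(pv), 5)) {
    s <- substr(g, pv$start[i], pv$end[i])
    if (pv$orientation[i] == "-") s <- revcompChr(s)
    expect_identical(as.character(scaffoldSeqs(ss)[[pv$scaffold[i]]]), s)
  }
})

test_that("requested chimeras join distant pieces", {
  g <- randomDna(3e6, seed = 19)
  ss <- fragmentIntoScaffolds(g, meanSize = 1.5e5, nChimeras = 2,
                              chimeraDistance = 1e6, seed = 20)
  pv <- provenance(ss)
  tab <- table(pv$scaffold)
  chim <- names(tab)[tab == 2]
  expect_length(chim, 2L)
  for (cc in chim) {
    parts <- pv[pv$scaffold == cc, ]
    expect_gt(abs(parts$start[1] - parts$start[2]), 1e6)
  }
})
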