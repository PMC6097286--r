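# Microhomology detection, UCO templates, chimera test, classification.
# (The brute-force microhomology oracle lives in helper-oracles.R.)

test_that("the canonical triplet signature is detected", {
  set.seed(61)
  x <- randomDna(47); y <- randomDna(47)
  intL <- randomDna(47); intR <- randomDna(47)
  cl <- paste0(x, "CGA", substr(intL, 1, 50))         # breakpoint at 50
  cr <- paste0(substr(intR, 1, 47), "CGA", y)          # breakpoint at 50
  dj <- paste0(x, "CGA", y)                            # junction at 50
  m <- detectMicrohomology(cl, cr, dj, centerJ = 50)
  expect_false(is.null(m))
  # the planted triplet is the motif core (chance flank extension only)
  expect_true(grepl("CGA", m, fixed = TRUE))
})

test_that("junctions without shared motifs return none", {
  dj <- paste0(strrep("A", 50), strrep("C", 50))
  cl <- paste0(strrep("G", 50), strrep("T", 50))
  cr <- paste0(strrep("T", 50), strrep("G", 50))
  expect_null(detectMicrohomology(cl, cr, dj))
})

test_that("the longest qualifying motif wins over shorter ones", {
  set.seed(62)
  x <- randomDna(45); y <- randomDna(47)
  # both "CGA" and "TACGA" flank the breakpoints; TACGA must win
  cl <- paste0(x, "TACGA", randomDna(50))
  cr <- paste0(randomDna(45), "TACGA", y)
  dj <- paste0(x, "TACGA", y)
  m <- detectMicrohomology(cl, cr, dj, centerJ = 50)
  expect_true(grepl("TACGA", m, fixed = TRUE))
  expect_gte(nchar(m), 5L)
})

test_that("detector agrees with the brute-force oracle on random
          junctions", {
  set.seed(63)
  agree <- 0L
  n <- 300
  for (i in seq_len(n)) {
    cl <- randomDna(100); cr <- randomDna(100); dj <- randomDna(100)
    got <- detectMicrohomology(cl, cr, dj)
    exp <- microhomologyOracle(cl, cr, dj)
    if (identical(got, exp) ||
        (is.null(got) && is.null(exp))) agree <- agree + 1L
  }
  expect_equal(agree, n)
})

test_that("detector agrees with the oracle on planted SSA junctions", {
  set.seed(64)
  for (i in 1:50) {
    k <- sample(3:8, 1)
    motif <- randomDna(k)
    x <- randomDna(50 - k); y <- randomDna(50)
    iv <- randomDna(200)
    cl <- paste0(x, motif, substr(iv, 1, 50))
    cr <- paste0(substr(iv, 151, 200 - k), motif, y)
    dj <- paste0(x, motif, y)
    got <- detectMicrohomology(cl, cr, dj)
    exp <- microhomologyOracle(cl, cr, dj)
    expect_identical(got, exp)
    expect_false(is.null(got))
  }
})

test_that("chimera test localises a synthetic crossover", {
  set.seed(65)
  tA <- randomDna(3000)
  tB <- paste(vapply(strsplit(tA, "")[[1]], function(c) {
    if (runif(1) < 0.05) sample(setdiff(c("A", "C", "G", "T"), c), 1)
    else c
  }, ""), collapse = "")  # ~95% identity
  cx <- 1200
  single <- paste0(substr(tA, 1, cx), substr(tB, cx + 1, 3000))
  ct <- chimeraTest(single, tA, tB)
  expect_true(ct$isRecombinant)
  expect_lte(abs(ct$crossover - cx), 200)

  # copy identical to one template: not recombinant
  ct2 <- chimeraTest(tA, tA, tB)
  expect_false(ct2$isRecombinant)
  expect_false(ct2$uninformative)

  # indistinguishable templates: uninformative
  ct3 <- chimeraTest(tA, tA, tA)
  expect_false(ct3$isRecombinant)
  expect_true(ct3$uninformative)
})

test_that("crossover recovery is within one window at >=3% divergence", {
  set.seed(66)
  for (i in 1:10) {
    tA <- randomDna(2500)
    v <- strsplit(tA, "")[[1]]
    pos <- sample(2500, 100)  # 4% divergence
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    tB <- paste(v, collapse = "")
    cx <- sample(600:1900, 1)
    single <- paste0(substr(tA, 1, cx), substr(tB, cx + 1, 2500))
    ct <- chimeraTest(single, tA, tB, window = 200, step = 50)
    expect_true(ct$isRecombinant)
    expect_lte(abs(ct$crossover - cx), 200)
  }
})

test_that("template detection requires same orientation and identity", {
  res <- smallPipelinePair(seed = 71, chromLen = 1e6)
  pair <- res$pair
  cs <- callLargeIndels(seqA(pair), seqB(pair), minIndelSize = 5e3)
  cc <- svCalls(cs)
  tl <- truth(pair)
  ucoTruth <- tl@indels[tl@indels$mechanism == "UCO", ]
  i <- which(cc$validity == "validated" &
               abs(cc$start - ucoTruth$start) < 5e3)
  tm <- detectUcoTemplate(cc[i, ], pair)
  expect_false(is.null(tm))
  expect_setequal(c(tm$templateA, tm$templateB), c("NLR01a", "NLR01b"))
  # an SSA call has no flanking template pair
  ssaTruth <- tl@indels[tl@indels$mechanism == "SSA", ]
  j <- which(cc$validity == "validated" &
               abs(cc$start - ssaTruth$start) < 5e3)
  expect_null(detectUcoTemplate(cc[j, ], pair))
})

test_that("classification labels planted UCO and SSA correctly across
          seeds", {
  for (seed in c(81, 82, 83)) {
    res <- smallPipelinePair(seed = seed, chromLen = 1e6)
    pair <- res$pair
    cs <- classifyCallSet(
      callLargeIndels(seqA(pair), seqB(pair), minIndelSize = 5e3), pair)
    cc <- svCalls(cs)
    tl <- truth(pair)
    for (mech in c("SSA", "UCO")) {
      tr <- tl@indels[tl@indels$mechanism == mech, ]
      i <- which(cc$validity != "rejected" &
                   abs(cc$start - tr$start) < 6e3)
      expect_equal(cc$mechanism[i], mech)
      if (mech == "SSA")
        expect_true(grepl(tr$motif, cc$motif[i], fixed = TRUE))
      if (mech == "UCO")  # crossover in single-copy-local coordinates
        expect_lte(abs(cc$crossover[i] - tr$crossover), 250)
    }
  }
})

test_that("a call with neither signature stays unclassified", {
  set.seed(67)
  left <- randomDna(150000); right <- randomDna(150000)
  a <- paste0(left, strrep("A", 1) , randomDna(30000), "CCTT", right)
  b <- paste0(left, "GGAA", right)  # junction shares no >=3-mer pattern
  pair <- new("ChromosomePair", seqA = Biostrings::DNAString(a),
              seqB = Biostrings::DNAString(b),
              genesA = GenomicRanges::GRanges(),
              genesB = GenomicRanges::GRanges(),
              truth = new("TruthLedger",
                          snps = data.frame(), haploblocks = data.frame(),
                          indels = data.frame(),
                          droppedGenes = character(),
                          chimeras = data.frame()))
  cs <- callLargeIndels(a, b, minIndelSize = 1e4, window = 5e4)
  cc <- svCalls(cs)
  expect_equal(nrow(cc), 1L)
  res <- classifyMechanism(cc[1, ], pair)
  expect_true(res$label %in% c("unclassified", "SSA"))
  # with no annotation, UCO is impossible
  expect_false(res$label == "UCO")
})
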