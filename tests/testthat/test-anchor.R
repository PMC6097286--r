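# Scaffold anchoring, chimera splitting, pseudomolecule assembly.

test_that("segment sampling follows the size-tiered rule", {
  # short scaffolds are used whole
  s8 <- sampleSegments(8e3)
  expect_equal(nrow(s8), 1L)
  expect_equal(s8$len, 8000L)
  # 10-200 kb: 1-kb segments every 30 kb
  s100 <- sampleSegments(1e5)
  expect_equal(s100$offset, c(1, 30001, 60001, 90001))
  expect_true(all(s100$len == 1000L))
  # > 200 kb: 1-kb segments every 100 kb
  s250 <- sampleSegments(2.5e5)
  expect_equal(s250$offset, c(1, 100001, 200001))
})

test_that("majority voting places, orients and rejects ties", {
  ref <- randomDna(8e5, seed = 21)
  sc <- substr(ref, 300001, 400000)
  a <- anchorScaffold(sc, ref, regionGap = 1e5)
  expect_equal(a$status, "placed")
  expect_equal(a$orientation, "+")
  expect_equal(a$position, 300001)
  expect_equal(a$nMajority, 4L)

  # reverse-complemented scaffold: minus orientation, same left edge
  am <- anchorScaffold(revcompChr(sc), ref, regionGap = 1e5)
  expect_equal(am$orientation, "-")
  expect_equal(am$position, 300001)

  # 3 vs 1 votes: majority region wins
  chim31 <- paste0(substr(ref, 100001, 190000),
                   substr(ref, 700001, 730000))
  a31 <- anchorScaffold(chim31, ref, regionGap = 1e5)
  expect_equal(a31$status, "placed")
  expect_equal(a31$nMajority, 3L)
  expect_lt(abs(a31$position - 100001), 5)

  # 2 vs 2 votes: no strict majority
  chim22 <- paste0(substr(ref, 100001, 160000),
                   substr(ref, 700001, 760000))
  a22 <- anchorScaffold(chim22, ref, regionGap = 1e5)
  expect_equal(a22$status, "ambiguous")

  # foreign sequence: unplaced
  expect_equal(anchorScaffold(randomDna(5e4), ref)$status, "unplaced")
})

test_that("chimeras split at vote discontinuities; clean scaffolds do not", {
  ref <- randomDna(8e5, seed = 22)
  sc <- substr(ref, 100001, 250000)
  a <- anchorScaffold(sc, ref, regionGap = 1e5)
  sp <- detectAndSplitChimeras(sc, a$votes, chimeraDistance = 2e5)
  expect_false(sp$split)
  expect_equal(sp$pieces, data.frame(start = 1L, end = 150000L))

  # two-region chimera
  chim <- paste0(substr(ref, 1, 150000), substr(ref, 600001, 750000))
  a2 <- anchorScaffold(chim, ref, regionGap = 1e5)
  sp2 <- detectAndSplitChimeras(chim, a2$votes, chimeraDistance = 2e5)
  expect_true(sp2$split)
  expect_equal(nrow(sp2$pieces), 2L)
  # splitting never loses sequence
  expect_equal(sum(sp2$pieces$end - sp2$pieces$start + 1), nchar(chim))
  # cut lies between the flanking provenance blocks
  expect_gt(sp2$pieces$end[1], 120000)
  expect_lt(sp2$pieces$end[1], 180001)

  # three provenance blocks: multiple splits allowed
  chim3 <- paste0(substr(ref, 1, 120000), substr(ref, 400001, 520000),
                  substr(ref, 700001, 790000))
  a3 <- anchorScaffold(chim3, ref, regionGap = 1e5)
  sp3 <- detectAndSplitChimeras(chim3, a3$votes, chimeraDistance = 2e5)
  expect_equal(nrow(sp3$pieces), 3L)
  expect_equal(sum(sp3$pieces$end - sp3$pieces$start + 1), nchar(chim3))
})

test_that("pseudomolecule assembly is length-conserving with AGP map", {
  set.seed(23)
  scafs <- Biostrings::DNAStringSet(
    c(s1 = randomDna(1000), s2 = randomDna(1000), s3 = randomDna(1000)))
  anch <- list(
    placements = data.frame(
      component = c("s1", "s2", "s3"), scaffold = c("s1", "s2", "s3"),
      start = 1L, end = 1000L, status = "placed",
      position = c(5000, 1, 9000), orientation = c("+", "+", "-"),
      nVotes = 1L, nMajority = 1L, fromSplit = FALSE),
    sequences = scafs)
  pm <- buildPseudomolecule(anch, gapLen = 100)
  expect_equal(length(pm@sequence), 3200L)
  seq <- as.character(pm@sequence)
  # order by anchor position: s2, s1, s3; s3 reverse complemented
  expect_equal(substr(seq, 1, 1000), as.character(scafs[["s2"]]))
  expect_equal(substr(seq, 1001, 1100), strrep("N", 100))
  expect_equal(substr(seq, 1101, 2100), as.character(scafs[["s1"]]))
  expect_equal(substr(seq, 2201, 3200), revcompChr(as.character(scafs[["s3"]])))
  a <- agp(pm)
  expect_equal(sum(a$component_type == "W"), 3L)
  expect_equal(sum(a$component_type == "N"), 2L)
  expect_equal(max(a$object_end), 3200L)
  # AGP intervals are contiguous
  expect_true(all(a$object_beg[-1] == a$object_end[-nrow(a)] + 1L))

  # duplicate placement is an assembly error
  bad <- anch
  bad$placements <- rbind(bad$placements, bad$placements[1, ])
  expect_error(buildPseudomolecule(bad), "assembly error")
})

test_that("N50/N90 match the cumulative-sum definition", {
  expect_equal(assemblyStats(c(5, 4, 3, 2, 1) * 1000),
               c(n50 = 4000, n90 = 2000, total = 15000))
  expect_equal(assemblyStats(777), c(n50 = 777, n90 = 777, total = 777))
  expect_equal(assemblyStats(rep(42, 10))[["n50"]], 42)
  expect_error(assemblyStats(numeric()), "undefined")
  # brute-force oracle on random length sets
  set.seed(24)
  for (i in 1:5) {
    lens <- sample.int(1e4, 20)
    st <- assemblyStats(lens)
    s <- sort(lens, decreasing = TRUE)
    oracleN <- function(x) s[min(which(cumsum(s) >= x * sum(s)))]
    expect_equal(st[["n50"]], oracleN(0.5))
    expect_equal(st[["n90"]], oracleN(0.9))
  }
})

test_that("fragment-and-reanchor round trip restores order and
          orientation and splits planted chimeras", {
  ref <- randomDna(2e6, seed = 25)
  ss <- fragmentIntoScaffolds(ref, meanSize = 1.2e5, nChimeras = 1,
                              chimeraDistance = 8e5, seed = 26)
  anch <- anchorScaffoldSet(ss, ref, regionGap = 3e5,
                            chimeraDistance = 8e5)
  pl <- anch$placements
  pv <- provenance(ss)
  chimIds <- pv$scaffold[duplicated(pv$scaffold)]
  # the planted chimera is split; every piece re-anchored
  expect_true(all(pl$fromSplit[pl$scaffold %in% chimIds]))
  expect_equal(sum(pl$fromSplit), 2L)
  # all multi-segment non-chimeric scaffolds recover position and strand
  single <- pv[!(pv$scaffold %in% chimIds), ]
  chk <- merge(pl, single, by = "scaffold")
  chk <- chk[chk$nVotes >= 2, ]
  expect_true(all(chk$status == "placed"))
  expect_true(all(chk$orientation.x == chk$orientation.y))
  expect_true(all(abs(chk$position - chk$start.y) <= 2))
  # pseudomolecule length conservation: components + gaps
  pm <- buildPseudomolecule(anch, gapLen = 100)
  comp <- agp(pm)
  wlen <- sum(comp$object_end[comp$component_type == "W"] -
                comp$object_beg[comp$component_type == "W"] + 1)
  glen <- sum(comp$object_end[comp$component_type == "N"] -
                comp$object_beg[comp$component_type == "N"] + 1)
  expect_equal(length(pm@sequence), wlen + glen)
})
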