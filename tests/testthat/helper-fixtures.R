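# Shared fixtures: small sequences and simulated pairs built in code.

randomDna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcompChr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Hamming identity oracle for equal-length strings (independent of the
# package's C++ helpers)
hammingIdentityOracle <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  stopifnot(length(va) == length(vb))
  mean(va == vb)
}

# brute-force maximal-exact-match oracle on short sequences: all maximal
# runs of agreement >= minLen between every offset pair, forward strand
maximalMatchOracle <- function(a, b, minLen) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  na <- length(va); nb <- length(vb)
  out <- list()
  for (d in (-(na - 1)):(nb - 1)) {
    i <- max(1, 1 - d); j <- i + d
    runLen <- 0
    while (i <= na && j <= nb) {
      if (va[i] == vb[j]) {
        runLen <- runLen + 1
      } else {
        if (runLen >= minLen)
          out[[length(out) + 1]] <- c(i - runLen, j - runLen, runLen)
        runLen <- 0
      }
      i <- i + 1; j <- j + 1
    }
    if (runLen >= minLen)
      out[[length(out) + 1]] <- c(i - runLen, j - runLen, runLen)
  }
  if (!length(out))
    return(data.frame(x = integer(), y = integer(), length = integer()))
  m <- do.call(rbind, out)
  df <- data.frame(x = m[, 1], y = m[, 2], length = m[, 3])
  df[order(df$x, df$y), ]
}

# a small simulated pair with one planted feature of each kind
smallPipelinePair <- function(seed = 1, chromLen = 1e6,
                              baselineSnpRate = 0, dropout = 0) {
  anc <- simulateAncestor(chromLen, geneDensity = 10,
                         nlrPairSpec = list(count = 1, identity = 97),
                         pairSpacing = 3e4, seed = seed)
  ind <- planIndels(anc, nSSA = 1, nUCO = 1, nDecoy = 1,
                    sizeRange = c(1.5e4, 3e4), margin = 5e3,
                    seed = seed + 1)
  pair <- deriveGenotypes(anc, baselineSnpRate = baselineSnpRate,
                          indelSpec = ind, dropoutFraction = dropout,
                          seed = seed + 2)
  list(ancestor = anc, indels = ind, pair = pair)
}
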