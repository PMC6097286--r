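# Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")

# coerce DNAString / DNAStringSet element / character to character scalar
.chr <- function(x) {
  if (is.character(x)) return(x)
  as.character(x)
}

.dna <- function(x) {
  if (is(x, "DNAString")) return(x)
  Biostrings::DNAString(x)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(.chr(x))))
}

# run code under a local RNG state seeded deterministically
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# random nucleotide string of length n
.randomSeq <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

# copy of seq with substitutions so that pairwise identity ~= identity
# (fraction in [0,1]); substitutions drawn uniformly among the 3 other bases
.mutateToIdentity <- function(seq, identity) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  nmut <- round((1 - identity) * n)
  if (nmut > 0) {
    pos <- sample.int(n, nmut)
    for (p in pos) {
      v[p] <- sample(setdiff(.BASES, v[p]), 1)
    }
  }
  paste(v, collapse = "")
}

# substring with 1-based closed coordinates, clamped to sequence bounds
.sub <- function(s, start, end) {
  n <- nchar(s)
  substr(s, max(1L, as.integer(start)), min(n, as.integer(end)))
}

# Hamming identity of two equal-length strings
.hammingIdentity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0) return(NA_real_)
  mm <- length(.mismatchOffsetsCpp(a, b, 1L, 1L, nchar(a)))
  1 - mm / nchar(a)
}

# N-gap runs of a sequence as a data.frame(start, end); cached-free, cheap
.nRuns <- function(s) {
  m <- .nRunsCpp(.chr(s))
  data.frame(start = m[, 1], end = m[, 2])
}

# is there a non-ACGT run overlapping [start, end]?
.hasNIn <- function(nruns, start, end) {
  if (nrow(nruns) == 0) return(FALSE)
  any(nruns$start <= end & nruns$end >= start)
}

# apply a set of edits to a sequence. edits: data.frame(start, end, insert)
# deleting [start, end] (0-width deletion when end < start) and inserting
# `insert` in its place. Applied right-to-left so coordinates stay valid.
.applyEdits <- function(seq, edits) {
  if (nrow(edits) == 0) return(seq)
  edits <- edits[order(edits$start, decreasing = TRUE), , drop = FALSE]
  if (any(duplicated(edits$start)))
    stop("overlapping edits")
  for (i in seq_len(nrow(edits))) {
    s <- edits$start[i]; e <- edits$end[i]
    seq <- paste0(substr(seq, 1, s - 1), edits$insert[i],
                  substr(seq, e + 1, nchar(seq)))
  }
  seq
}

# map ancestor coordinates through a set of edits (same layout as
# .applyEdits) to derived coordinates; positions inside deleted intervals
# map to NA
.mapThroughEdits <- function(pos, edits) {
  if (nrow(edits) == 0 || length(pos) == 0) return(pos)
  out <- pos
  for (i in seq_len(nrow(edits))) {
    s <- edits$start[i]; e <- edits$end[i]
    dlen <- max(0L, e - s + 1L)
    ilen <- nchar(edits$insert[i])
    inside <- !is.na(pos) & pos >= s & pos <= e
    after <- !is.na(pos) & pos > e
    out[inside] <- NA_integer_
    out[after] <- out[after] - dlen + ilen
  }
  out
}
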