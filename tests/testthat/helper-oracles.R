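# Brute-force oracles shared by unit and acceptance tests.

# Microhomology oracle: enumerate every candidate motif (all lengths >=
# kMin at every admissible pair of end offsets; the candidate at each
# offset pair is the maximal common suffix) under the documented
# qualifying rule, applying the same selection order as the detector.
microhomologyOracle <- function(cl, cr, dj, kMin = 3, w = 50, tol = 10,
                                centerL = w, centerR = w, centerJ = w) {
  best <- NULL; bestDist <- Inf
  for (eL in seq_len(nchar(cl))) {
    if (abs(eL - centerL) > tol) next
    for (eR in seq_len(nchar(cr))) {
      if (abs(eR - centerR) > tol) next
      kmax <- min(eL, eR, w)
      if (kmax < kMin) next
      for (k in kmax:kMin) {
        mL <- substr(cl, eL - k + 1, eL)
        if (mL != substr(cr, eR - k + 1, eR)) next
        occ <- gregexpr(mL, dj, fixed = TRUE)[[1]]
        if (occ[1] == -1) break
        ends <- occ + k - 1
        nearby <- ends[ends >= centerJ - tol & ends <= centerJ + tol + k]
        if (!length(nearby)) break
        e <- nearby[which.min(abs(nearby - centerJ - k))]
        if (any(ends == e - k) || any(ends == e + k)) break
        dist <- abs(eL - centerL) + abs(eR - centerR) +
          abs(e - centerJ - k)
        if (is.null(best) || k > nchar(best) ||
            (k == nchar(best) &&
             (dist < bestDist || (dist == bestDist && mL < best)))) {
          best <- mL; bestDist <- dist
        }
        break  # the maximal common suffix was already tested
      }
    }
  }
  best
}
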