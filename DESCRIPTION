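Package: svduet
Title: Two-Genotype Chromosome Comparison for Large Structural Variants,
    Haploblocks and Gene Content
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares two chromosome-scale assemblies of closely related
    genotypes the way high-quality plant pseudomolecules are compared by
    hand: scaffolds are anchored to a reference by segment sampling and
    majority vote (with chimera splitting) to build a gap-joined
    pseudomolecule, large InDels are detected from windowed dot plots and
    curated with an assembly-gap (N) filter, breakpoints are classified
    into unequal crossing over or single-strand-annealing double-strand
    break repair from their molecular signatures, SNP-density haploblocks
    are segmented and their boundaries refined, and gene content is
    compared via reciprocal best hits with annotation-dropout rescue,
    collinearity, NLR clustering and copy-number-variant regions. A
    synthetic chromosome-pair simulator with a machine-readable truth
    ledger supports end-to-end validation of every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    IRanges,
    GenomicRanges,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
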