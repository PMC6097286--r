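#' @import methods
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#' @useDynLib svduet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setOldClass("data.frame")

#' Ancestor chromosome model
#'
#' A simulated ancestral chromosome: its sequence, gene models (generic and
#' NLR), the NLR paralog pairs embedded as templates for unequal crossing
#' over, and any repeat-salted intervals.
#'
#' @slot sequence A [Biostrings::DNAString] with the ancestral sequence.
#' @slot genes A [GenomicRanges::GRanges] with metadata columns `gene_id`
#'   and `class` (`"generic"` or `"NLR"`).
#' @slot paralogPairs A data.frame with columns `geneA`, `geneB`,
#'   `identity` (percent) and `same_orientation`.
#' @slot repeats An [IRanges::IRanges] of dinucleotide-salted intervals.
#' @exportClass AncestorModel
setClass("AncestorModel",
  representation(
    sequence = "DNAString",
    genes = "GRanges",
    paralogPairs = "data.frame",
    repeats = "IRanges"
  )
)

setValidity("AncestorModel", function(object) {
  msg <- character()
  L <- length(object@sequence)
  g <- object@genes
  if (length(g) && (any(start(g) < 1) || any(end(g) > L)))
    msg <- c(msg, "gene intervals must lie within sequence bounds")
  pp <- object@paralogPairs
  if (nrow(pp)) {
    if (any(pp$identity < 90 | pp$identity > 100))
      msg <- c(msg, "paralog pair identity must be in [90, 100]")
    ids <- g$gene_id
    same <- pp$same_orientation
    for (i in which(same)) {
      sa <- as.character(strand(g[match(pp$geneA[i], ids)]))
      sb <- as.character(strand(g[match(pp$geneB[i], ids)]))
      if (!identical(sa, sb))
        msg <- c(msg, "same_orientation paralog pairs must share strand")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Truth ledger of planted features
#'
#' Machine-readable ground truth for a simulated chromosome pair: every
#' planted SNP, haploblock, InDel (with mechanism label and signature
#' evidence), annotation drop-out and chimeric scaffold junction.
#'
#' @slot snps data.frame: `pos` (ancestor), `posA`, `posB`, `ref`, `alt`.
#' @slot haploblocks data.frame: `start`, `end` (genotype-A coordinates),
#'   `fold`.
#' @slot indels data.frame: `carrier` ("A"/"B"), `start`, `end` (1-based
#'   closed, carrier coordinates), `size`, `mechanism` ("SSA", "UCO" or
#'   "decoy_gap"), `motif`, `templateA`, `templateB`, `crossover`,
#'   `junction` (derived-genotype coordinate of the junction).
#' @slot droppedGenes character vector of gene ids removed from one
#'   annotation while their sequence stays intact.
#' @slot chimeras data.frame: `scaffold`, `junction` (offset within the
#'   scaffold).
#' @exportClass TruthLedger
setClass("TruthLedger",
  representation(
    snps = "data.frame",
    haploblocks = "data.frame",
    indels = "data.frame",
    droppedGenes = "character",
    chimeras = "data.frame"
  )
)

#' A pair of derived genotype chromosomes
#'
#' Two chromosome sequences derived from a common ancestor, their gene
#' annotations, and (for simulated pairs) the truth ledger of planted
#' features.
#'
#' @slot seqA,seqB [Biostrings::DNAString] chromosome sequences.
#' @slot genesA,genesB [GenomicRanges::GRanges] gene annotations with
#'   metadata columns `gene_id` and `class`.
#' @slot truth A [TruthLedger-class] (empty for real data).
#' @exportClass ChromosomePair
setClass("ChromosomePair",
  representation(
    seqA = "DNAString",
    seqB = "DNAString",
    genesA = "GRanges",
    genesB = "GRanges",
    truth = "TruthLedger"
  )
)

#' A fragmented scaffold set with provenance
#'
#' Scaffolds cut from a genotype sequence, possibly shuffled, reverse
#' complemented and joined into chimeras, with the exact source interval(s)
#' of every scaffold recorded.
#'
#' @slot sequences A [Biostrings::DNAStringSet], one entry per scaffold.
#' @slot provenance data.frame: `scaffold`, `part` (1, 2, ... within a
#'   scaffold), `start`, `end` (source coordinates), `orientation`
#'   ("+"/"-").
#' @exportClass ScaffoldSet
setClass("ScaffoldSet",
  representation(
    sequences = "DNAStringSet",
    provenance = "data.frame"
  )
)

setValidity("ScaffoldSet", function(object) {
  pv <- object@provenance
  if (!all(pv$scaffold %in% names(object@sequences)))
    return("provenance rows must reference existing scaffolds")
  TRUE
})

#' A gap-joined pseudomolecule
#'
#' The product of anchoring scaffolds to a reference: ordered, oriented
#' scaffolds concatenated with fixed-length N gaps, plus the AGP map,
#' per-scaffold placement report and assembly statistics.
#'
#' @slot sequence [Biostrings::DNAString] pseudomolecule sequence.
#' @slot agp data.frame in AGP v2.1 column layout.
#' @slot placements data.frame placement report (one row per scaffold).
#' @slot stats list with `n50`, `n90`, `total`, `anchoredFraction`.
#' @exportClass Pseudomolecule
setClass("Pseudomolecule",
  representation(
    sequence = "DNAString",
    agp = "data.frame",
    placements = "data.frame",
    stats = "list"
  )
)

#' A set of large-InDel calls
#'
#' Candidate and curated InDel calls between two pseudomolecules. One row
#' per call with refined breakpoints (carrier coordinates), junction
#' coordinate on the derived genotype, N-filter status, validity and the
#' mechanism label once classified.
#'
#' @slot calls data.frame with columns `id`, `carrier`, `start`, `end`,
#'   `size`, `junction`, `junctionGap` (width of unaligned derived
#'   sequence at the junction; positive for assembly gaps), `ambiguity`,
#'   `n_status`, `validity`, `mechanism`, `motif`, `templateA`,
#'   `templateB`, `crossover`.
#' @slot params list of caller parameters.
#' @exportClass SvCallSet
setClass("SvCallSet",
  representation(calls = "data.frame", params = "list")
)

#' Gene-content comparison between two genotypes
#'
#' One-way best-hit maps, reciprocal best hits, putatively unique genes and
#' their curation (rescued on the other pseudomolecule vs truly unique),
#' plus the non-collinear gene list.
#'
#' @slot hitsAB,hitsBA data.frame one-way best-hit maps (`gene`, `hit`,
#'   `score`, `identity`).
#' @slot rbh data.frame reciprocal best-hit pairs (`geneA`, `geneB`).
#' @slot putativeUniqueA,putativeUniqueB character vectors of no-hit genes.
#' @slot rescuedA,rescuedB character vectors of genes rescued on the other
#'   pseudomolecule.
#' @slot trulyUniqueA,trulyUniqueB character vectors.
#' @slot nonCollinear data.frame (`geneA`, `geneB`) flagged RBH pairs.
#' @exportClass GeneComparison
setClass("GeneComparison",
  representation(
    hitsAB = "data.frame", hitsBA = "data.frame", rbh = "data.frame",
    putativeUniqueA = "character", putativeUniqueB = "character",
    rescuedA = "character", rescuedB = "character",
    trulyUniqueA = "character", trulyUniqueB = "character",
    nonCollinear = "data.frame"
  )
)

setValidity("GeneComparison", function(object) {
  msg <- character()
  if (length(intersect(object@rescuedA, object@trulyUniqueA)) ||
      length(intersect(object@rescuedB, object@trulyUniqueB)))
    msg <- c(msg, "rescued and truly-unique sets must be disjoint")
  if (nrow(object@rbh)) {
    if (anyDuplicated(object@rbh$geneA) || anyDuplicated(object@rbh$geneB))
      msg <- c(msg, "RBH pairs must form a one-to-one matching")
  }
  if (length(msg)) msg else TRUE
})
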