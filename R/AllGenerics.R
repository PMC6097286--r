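# Accessor generics and show methods for the core containers.

#' @rdname accessors
#' @param x An svduet object.
#' @export
setGeneric("seqA", function(x) standardGeneric("seqA"))
#' @rdname accessors
#' @export
setGeneric("seqB", function(x) standardGeneric("seqB"))
#' @rdname accessors
#' @export
setGeneric("genesA", function(x) standardGeneric("genesA"))
#' @rdname accessors
#' @export
setGeneric("genesB", function(x) standardGeneric("genesB"))
#' @rdname accessors
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))
#' @rdname accessors
#' @export
setGeneric("svCalls", function(x) standardGeneric("svCalls"))
#' @rdname accessors
#' @export
setGeneric("scaffoldSeqs", function(x) standardGeneric("scaffoldSeqs"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("pmSequence", function(x) standardGeneric("pmSequence"))
#' @rdname accessors
#' @export
setGeneric("agp", function(x) standardGeneric("agp"))
#' @rdname accessors
#' @export
setGeneric("placements", function(x) standardGeneric("placements"))
#' @rdname accessors
#' @export
setGeneric("assemblySummary", function(x) standardGeneric("assemblySummary"))
#' @rdname accessors
#' @export
setGeneric("rbhPairs", function(x) standardGeneric("rbhPairs"))

#' Accessors for svduet containers
#'
#' Getter functions for the slots of [ChromosomePair-class],
#' [AncestorModel-class], [ScaffoldSet-class], [Pseudomolecule-class],
#' [SvCallSet-class] and [GeneComparison-class] objects.
#'
#' @name accessors
#' @return The slot contents.
NULL

#' @rdname accessors
#' @export
setMethod("seqA", "ChromosomePair", function(x) x@seqA)
#' @rdname accessors
#' @export
setMethod("seqB", "ChromosomePair", function(x) x@seqB)
#' @rdname accessors
#' @export
setMethod("genesA", "ChromosomePair", function(x) x@genesA)
#' @rdname accessors
#' @export
setMethod("genesB", "ChromosomePair", function(x) x@genesB)
#' @rdname accessors
#' @export
setMethod("truth", "ChromosomePair", function(x) x@truth)
#' @rdname accessors
#' @export
setMethod("svCalls", "SvCallSet", function(x) x@calls)
#' @rdname accessors
#' @export
setMethod("scaffoldSeqs", "ScaffoldSet", function(x) x@sequences)
#' @rdname accessors
#' @export
setMethod("provenance", "ScaffoldSet", function(x) x@provenance)
#' @rdname accessors
#' @export
setMethod("pmSequence", "Pseudomolecule", function(x) x@sequence)
#' @rdname accessors
#' @export
setMethod("agp", "Pseudomolecule", function(x) x@agp)
#' @rdname accessors
#' @export
setMethod("placements", "Pseudomolecule", function(x) x@placements)
#' @rdname accessors
#' @export
setMethod("assemblySummary", "Pseudomolecule", function(x) x@stats)
#' @rdname accessors
#' @export
setMethod("rbhPairs", "GeneComparison", function(x) x@rbh)

#' @rdname accessors
#' @export
setMethod("length", "ScaffoldSet", function(x) length(x@sequences))
#' @rdname accessors
#' @export
setMethod("length", "SvCallSet", function(x) nrow(x@calls))

setMethod("show", "AncestorModel", function(object) {
  cat("AncestorModel:", length(object@sequence), "bp,",
      length(object@genes), "genes (",
      sum(object@genes$class == "NLR"), "NLR ),",
      nrow(object@paralogPairs), "paralog pair(s)\n")
})

setMethod("show", "TruthLedger", function(object) {
  cat("TruthLedger:", nrow(object@snps), "SNPs,",
      nrow(object@haploblocks), "haploblocks,",
      nrow(object@indels), "InDels,",
      length(object@droppedGenes), "dropped genes,",
      nrow(object@chimeras), "chimeras\n")
})

setMethod("show", "ChromosomePair", function(object) {
  cat("ChromosomePair\n",
      " genotype A:", length(object@seqA), "bp,",
      length(object@genesA), "genes\n",
      " genotype B:", length(object@seqB), "bp,",
      length(object@genesB), "genes\n")
  show(object@truth)
})

setMethod("show", "ScaffoldSet", function(object) {
  w <- Biostrings::width(object@sequences)
  nchim <- sum(table(object@provenance$scaffold) > 1)
  cat("ScaffoldSet:", length(w), "scaffolds, total", sum(as.numeric(w)),
      "bp,", nchim, "chimeric\n")
})

setMethod("show", "Pseudomolecule", function(object) {
  s <- object@stats
  cat("Pseudomolecule:", length(object@sequence), "bp,",
      sum(object@agp$component_type == "W"), "components\n",
      " N50:", s$n50, " N90:", s$n90,
      " anchored fraction:", round(s$anchoredFraction, 3), "\n")
})

setMethod("show", "SvCallSet", function(object) {
  cc <- object@calls
  cat("SvCallSet:", nrow(cc), "call(s)\n")
  if (nrow(cc))
    print(table(validity = cc$validity, mechanism = cc$mechanism))
})

setMethod("show", "GeneComparison", function(object) {
  cat("GeneComparison\n",
      " one-way hits A->B:", sum(!is.na(object@hitsAB$hit)), "/",
      nrow(object@hitsAB), "\n",
      " one-way hits B->A:", sum(!is.na(object@hitsBA$hit)), "/",
      nrow(object@hitsBA), "\n",
      " RBH pairs:", nrow(object@rbh), "\n",
      " truly unique:", length(object@trulyUniqueA), "(A),",
      length(object@trulyUniqueB), "(B)\n")
})
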