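# Readers/writers for the standard interchange formats.

#' Write sequences to FASTA
#'
#' @param seqs Named list/character vector of sequences, a
#'   [Biostrings::DNAStringSet], or a single sequence.
#' @param path Output path.
#' @export
writeFasta <- function(seqs, path) {
  if (is(seqs, "DNAStringSet")) {
    Biostrings::writeXStringSet(seqs, path)
    return(invisible(path))
  }
  if (is(seqs, "DNAString")) seqs <- stats::setNames(.chr(seqs), "seq")
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  ss <- Biostrings::DNAStringSet(unlist(lapply(seqs, .chr)))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write gene models to GFF3
#'
#' @param genes [GenomicRanges::GRanges] with `gene_id` (and optionally
#'   `class`) metadata columns.
#' @param path Output path.
#' @param seqname Sequence name for column 1.
#' @export
writeGff3 <- function(genes, path, seqname = "chr") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_along(genes)) {
    attrs <- sprintf("ID=%s", genes$gene_id[i])
    if (!is.null(genes$class))
      attrs <- paste0(attrs, ";gene_class=", genes$class[i])
    writeLines(sprintf("%s\tsvduet\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       seqname, start(genes)[i], end(genes)[i],
                       as.character(strand(genes)[i]), attrs), con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path Path to a GFF3 file with `gene` features carrying `ID`
#'   (and optionally `gene_class`) attributes.
#' @return [GenomicRanges::GRanges] with `gene_id` and `class`.
#' @export
readGff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  f <- f[vapply(f, length, 0L) >= 9]
  f <- f[vapply(f, function(x) x[3] == "gene", TRUE)]
  if (!length(f)) return(GRanges())
  getAttr <- function(attr, key) {
    m <- regmatches(attr, regexec(paste0(key, "=([^;]+)"), attr))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }
  gr <- GRanges(
    vapply(f, `[`, "", 1),
    IRanges(as.integer(vapply(f, `[`, "", 4)),
            as.integer(vapply(f, `[`, "", 5))),
    strand = vapply(f, `[`, "", 7))
  gr$gene_id <- vapply(f, function(x) getAttr(x[9], "ID"), "")
  cls <- vapply(f, function(x) getAttr(x[9], "gene_class"), "")
  gr$class <- ifelse(is.na(cls), "generic", cls)
  gr
}

#' Write an AGP v2.1 map
#'
#' @param pm A [Pseudomolecule-class].
#' @param path Output path.
#' @export
writeAgp <- function(pm, path) {
  a <- pm@agp
  rows <- vapply(seq_len(nrow(a)), function(i) {
    if (a$component_type[i] == "W")
      paste(a$object[i], a$object_beg[i], a$object_end[i],
            a$part_number[i], "W", a$component_id[i],
            a$component_beg[i], a$component_end[i], a$orientation[i],
            sep = "\t")
    else
      paste(a$object[i], a$object_beg[i], a$object_end[i],
            a$part_number[i], "N", a$component_id[i], "scaffold",
            "yes", "na", sep = "\t")
  }, "")
  writeLines(c("##agp-version\t2.1", rows), path)
  invisible(path)
}

#' Write SNPs as a VCF-like TSV
#'
#' Columns CHROM, POS (1-based), REF, ALT.
#'
#' @param snps data.frame from [callSnps()].
#' @param path Output path.
#' @param seqname CHROM value.
#' @export
writeSnpTsv <- function(snps, path, seqname = "chr") {
  df <- data.frame(CHROM = seqname, POS = snps$pos, REF = snps$ref,
                   ALT = snps$alt)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write intervals as BED
#'
#' @param df data.frame with `start`, `end` (1-based closed; converted
#'   to BED's 0-based half-open), plus an optional `name` column.
#' @param path Output path.
#' @param seqname Chromosome name.
#' @export
writeBed <- function(df, path, seqname = "chr") {
  name <- if (!is.null(df$name)) df$name else
    if (!is.null(df$id)) df$id else "."
  out <- data.frame(chrom = seqname, start = df$start - 1L,
                    end = df$end, name = name)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a truth ledger to JSON
#'
#' @param ledger A [TruthLedger-class].
#' @param path Output path.
#' @export
writeTruthLedger <- function(ledger, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write truth ledgers")
  jsonlite::write_json(
    list(snps = ledger@snps, haploblocks = ledger@haploblocks,
         indels = ledger@indels, droppedGenes = ledger@droppedGenes,
         chimeras = ledger@chimeras),
    path, dataframe = "rows", na = "null", auto_unbox = TRUE)
  invisible(path)
}
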