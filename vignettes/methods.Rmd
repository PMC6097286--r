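---
title: "Comparing two chromosome assemblies: methods and design notes"
author: "svduet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing two chromosome assemblies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svduet)
```

## The problem

When two high-quality chromosome-scale assemblies of closely related
genotypes (for example two bread-wheat cultivars) are compared, the
naive output of automated comparison — apparent large insertions and
deletions, genotype-specific genes — is dominated by artefacts:
scaffolds placed wrongly or joined across assembly gaps mimic
megabase-scale InDels, and genes missed by one annotation pipeline
masquerade as presence/absence variation. The curation logic that
separates real structural variation from artefact is simple but easy to
get wrong; `svduet` packages it as tested, reusable functions, together
with a simulator that plants ground truth so every step can be validated
end to end.

The pipeline mirrors how such comparisons are done by hand:

1. **Anchoring** — scaffolds are placed on a reference chromosome by
   segment sampling and majority vote, chimeric scaffolds are split, and
   a gap-joined pseudomolecule with an AGP map is produced.
2. **InDel detection** — the two pseudomolecules are compared in
   windows; jumps of the dot-plot main diagonal beyond a size threshold
   become candidates, breakpoints are refined to base resolution, and
   candidates with assembly-gap Ns at both breakpoints are rejected as
   false positives.
3. **Mechanism classification** — validated InDels are tested for the
   two molecular signatures observed at large deletion breakpoints:
   a same-orientation high-identity paralog pair whose derived single
   copy is a recombinant chimera (unequal crossing over, UCO), or a
   short direct repeat present twice in the carrier and once at the
   derived junction (single-strand-annealing DSB repair, SSA).
4. **Haploblocks** — substitution SNPs are called from the collinear
   alignment backbone, sliding-window densities are computed, runs of
   windows far above the chromosome-wide median are merged into
   haploblocks, and their boundaries are refined on the local identity
   transition.
5. **Gene content** — one-way best hits, reciprocal best hits (RBH),
   curation of putatively unique genes against the opposite
   pseudomolecule, rank-based collinearity, NLR clustering and
   copy-number-variant regions bracketed by RBH anchors.

## The alignment engine

All sequence comparison is done by one engine: exact k-mer seeds
(2-bit-encoded, both strands) merged along diagonals into maximal exact
matches, chained within a diagonal band, and scored by Hamming identity
over the chained span. Words occurring more often than `maxOcc`
(default 50) in either sequence are skipped, so high-copy repeats do not
flood the seed table — the analogue of excluding the repeat-rich
centromere from a whole-chromosome comparison. Defaults are word size
15 for anchoring and gene comparison (sensitive, short queries) and 25
or 31 for dot plots and whole-chromosome backbones (specific, long
targets). An adapter (`readAlignmentTable()`) ingests tabular output of
an external nucleotide BLAST, with the conventional E-value cut-off of
1e-10, so real aligner runs can be substituted where desired.

The genome-wide *collinear backbone* is the weight-maximal co-monotone
chain of diagonal-merged matches, computed per window to bound memory.
Runs of constant diagonal offset are the one-to-one collinear blocks;
offset jumps of at least the minimum InDel size are the SV candidates.
Because the backbone is shared by the SV caller, the SNP caller and the
haploblock refiner, all three see the same coordinate correspondence.

## Coordinates

All coordinates are 1-based closed throughout the package — the native
convention of R, `IRanges` and `Biostrings` — so GFF3 and AGP output
require no conversion; only BED output converts to 0-based half-open.

## Breakpoint refinement and its ambiguity

A candidate InDel is bracketed by exact-match anchors on both sides.
Refinement bisects 40-bp identity probes toward the junction (consistency
threshold 0.75, far above the ~0.25 identity of unrelated sequence) and
then scans at base level for the point where mismatches become dense
(8 mismatches within 16 bp), which tolerates isolated SNPs near the
junction. The deleted interval is reported at the *leftmost* position
consistent with the flanking similarity; the width of the consistent
range is recorded as `ambiguity`. This is not a nuisance quantity: for
an SSA deletion the ambiguity *is* the microhomology length, and for a
UCO deletion it is the template length, because the flanks can anneal
anywhere within the repeated sequence. The apparent size — the diagonal
offset difference — is exact regardless of placement, which is why the
simulator-recovery tests demand exact size but tolerate placement shifts
up to the recorded ambiguity.

The **N filter** mirrors manual curation: Ns "exactly at the
breakpoints on both sides" mark a false positive. Operationally, the
unaligned derived-junction interval (`junctionGap`, positive when
unalignable sequence such as an assembly gap sits between the flank
matches) and the two carrier breakpoints are searched for N runs within
`nWindow` (default 100 bp, the refinement-scale reading of "exactly
at"); Ns on both sides reject the call, Ns on one side keep it flagged
as partial.

## Mechanism signatures

`detectMicrohomology()` searches the maximal common suffix of the two
carrier breakpoint contexts over end offsets within ±10 bp of the
refined breakpoints (the refinement tolerance), and requires the motif
at the derived junction without an immediately tandem-adjacent second
copy (two adjacent copies would mean both repeats were retained, i.e.
no annealing-mediated loss). The minimum motif length is 3 — the
canonical observed signature is a nucleotide triplet — and the selection
is longest first, then closest to the breakpoints, then lexicographic,
making the detector deterministic and directly comparable to a
brute-force enumeration oracle.

`detectUcoTemplate()` requires what unequal crossing over requires:
a same-orientation, ≥90%-identity gene pair at the carrier breakpoints
and a single homologous copy spanning the derived junction (located up
to the breakpoint ambiguity, since within-template placement is
inherently ambiguous). `chimeraTest()` then computes per-window (200 bp,
step 50) identity of the single copy to each template and calls the copy
recombinant when a prefix run favours one template and the suffix run
the other (minimum 2 windows each, identity difference ≥0.01 to count);
the crossover is the midpoint between the last and first discriminating
windows, accurate to about one window when templates diverge ≥3%.
Classification is UCO if template and chimera test agree, else SSA if a
motif is found, else unclassified; on dual evidence UCO wins, because
short motifs occur by chance within paralogous templates (at ±10 bp and
length 3 the chance rate is appreciable), while a same-orientation
paralog pair with a recombinant single copy essentially cannot arise by
chance. Mechanisms the package carries no evidence model for
(TE-mediated events, replication errors) surface as "unclassified" —
expected behaviour, not failure.

## Haploblock segmentation

SNP calling is assembly-against-assembly: substitution columns inside
constant-offset collinear blocks, excluding columns within
`nExclusion` (10 bp) of N runs or block edges. This replaces
read-mapping variant calling; it preserves exactly the signal the
downstream analysis consumes (per-window substitution density) while
keeping the pipeline self-contained. Density windows overlap (step =
width/5 by default; only the width is fixed by convention at 2.5 Mb on
a full-size chromosome), so a merged run of qualifying windows
overshoots each true boundary by up to one window width — which is why
boundary refinement exists. The call threshold of 10× the chromosome
median sits two orders of magnitude of headroom below the observed
haploblock contrast (~27 vs 2500–4500 SNPs/Mb; the simulator takes the
fold as a parameter rather than fixing one value, since reported
contrasts range from 35-fold summaries to ~100-fold window ratios).

Refinement is a change-point fit rather than a first-crossing scan:
5-kb windows across the search span are classified against the midpoint
of the inside/outside mean identities, and the boundary maximising the
number of correctly classified windows on both sides wins. This is
robust to single noisy windows (at baseline 30 SNPs/Mb and fold 100, a
5-kb window's identity is separated from the midpoint by roughly 2
standard deviations, so isolated misclassifications do occur).
Windows with identity below 0.5 carry no boundary information — they
are unalignable, e.g. genotype-specific sequence inside a deletion —
and are excluded.

## Gene-content curation

Gene "sequence" is the genomic span of the model (annotation pipelines,
not transcript structure, are the object of comparison here). The
internal aligner's score cut-off (100 identical columns) plays the role
of the E-value cut-off: two unrelated 1-kb sequences share a seed word
with probability ~10⁻³ and essentially never produce a scoring chain,
which the test suite verifies empirically on thousands of random pairs.
Putatively unique genes (no hit among the other genotype's annotated
genes) are re-aligned to the other *pseudomolecule*; a spanning hit at
≥90% identity over ≥80% of the gene rescues it as annotation-missed.
Collinearity uses the longest-increasing-subsequence backbone of RBH
partner ranks — a gene is non-collinear when it is off every maximal
common subsequence of the two orders — with genes on scaffolds carrying
fewer than two genes excluded, since a single-gene scaffold's placement
was itself derived from the reference and carries no independent order
information. NLR clusters are single-linkage chains with inter-gene
gaps ≤200 kb (no published definition of "cluster" exists for these
data; 200 kb reproduces multi-gene clusters at observed NLR densities
without merging across anchor genes), and CNV regions are cluster pairs
bracketed by the same flanking RBH anchors with unequal NLR counts.

## The simulator and what it does not emulate

The generator builds an ancestor chromosome (i.i.d. uniform background —
only local self-similarity matters to the detectors — with optional
dinucleotide salting, gene models, same-orientation NLR paralog pairs at
96–98% identity) and derives two genotypes. SNPs are a Poisson process:
~27 SNPs/Mb baseline, elevated by a configurable fold inside haploblock
intervals (2500–4500 SNPs/Mb at fold ~100). Planted deletions carry
their mechanism signature noiselessly: SSA deletions write the motif at
both ends of the interval before deleting it from the derived genotype;
UCO deletions run between the members of a paralog pair and leave a
single recombinant copy; decoy InDels replace a segment with a short N
run in one assembly — the realisation of "identical sequence, but an
assembly gap", which surfaces as an apparent InDel with Ns at both
breakpoints and must be rejected by the N filter. Annotation drop-outs
remove genes from one annotation while leaving the sequence intact.
Scaffold sets tile the genotype exactly (no inter-scaffold loss),
shuffled and randomly reverse-complemented, with chimeras joining pieces
at least a configurable distance apart; chimera parts are kept ≥120 kb
so that the segment-sampling rule lands at least one segment in every
part.

Passing on this synthetic data shows that the *logic* of detection,
curation and classification is correct under the stated conditions. It
does not show robustness to what the simulator omits: realistic
transposon landscapes and nested repeats, polyploid homoeologous
copies, small indels inside alignments, sequencing error, or
recombination-map structure. The repeat-masking and ambiguity machinery
exist precisely because real data have these properties, but their
effectiveness there is not certified by these tests.

## Problem sizes and defaults

The package's own validation runs at desk scale, chosen as the smallest
sizes at which every rule keeps its meaning: 5-Mb chromosome pairs with
window = length/10 and a 10-kb InDel threshold (the same 1:65 scaling
as 10-Mb windows and a 100-kb threshold on a 651-Mb chromosome;
thresholds scale linearly with chromosome length), ~50-scaffold
assemblies with two chimeras for the anchoring round trip, 3-Mb
chromosomes with 150-kb density windows for haploblock recovery, and
1–1.5-Mb chromosomes for mechanism and gene-curation sweeps over 20
seeds each. A full 5-Mb pipeline run takes roughly half a minute on one
CPU.

Other notable defaults: anchoring votes are one per segment regardless
of score (the plainest reading of majority-of-hits), vote regions are
single-linkage clusters of hit positions with a gap parameter rather
than fixed bins (no boundary artefacts), inter-scaffold gaps are 100 N,
the chimera split point is the midpoint between the flanking segment
hits, and ambiguous or unplaced scaffolds are excluded from the
pseudomolecule but retained in the placement report.

## Worked example

```{r example, eval = FALSE}
res <- runPipeline(chromLen = 5e6, seed = 1)
res$evaluation
svCalls(res$callset)
```

`runPipeline()` simulates a pair, runs every stage and evaluates
against the truth ledger; the `EvaluationSummary` prints per-class
precision/recall and the mean haploblock Jaccard index. The README
shows the printed output of this exact call.

## Known limitations

* Inversions are visible as strand-flipped blocks in dot plots but are
  not curated as first-class SV calls.
* Breakpoints inside long tandem or dispersed repeats are reported at
  the leftmost consistent position; the ambiguity field must be
  consulted before interpreting breakpoint coordinates.
* The SSA detector will occasionally find a chance triplet at a
  junction whose true mechanism left no signature; such calls are
  labelled SSA rather than unclassified. UCO priority prevents the
  reverse error on genuine crossover events.
* Gene comparison uses one representative (genomic-span) sequence per
  gene; splice variants are not modelled.
* Pseudogene status is carried as metadata only; no frameshift/stop
  scanning is performed.
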