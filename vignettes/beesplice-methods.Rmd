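---
title: "Detecting and quantifying alternative splicing with beesplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying alternative splicing with beesplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beesplice)
```

## Overview

`beesplice` characterizes alternative splicing (AS) in a compact
invertebrate genome — the design point is the honey bee, whose exons
average about 320 bp and introns about 1,390 bp — from three inputs that
any junction-aware RNA-seq aligner can produce: a gene annotation (GFF3),
a table of splice-junction calls with confidence scores and supporting
read counts, and a per-base coverage track (bedGraph).  From these it

* refines the gene models with novel exons and intergenic multi-exon
  transcripts inferred from "transcribed islands",
* detects four AS classes — intron retention (IR), cassette exons (CE),
  alternative exon boundaries (AEB: alternative donor or acceptor sites),
  and alternative terminal exons (ATE: alternative first/last exons) —
* quantifies each event with inclusion and splicing ratios,
* scores splice-site strength with a maximum-entropy motif model, and
* relates CpG observed/expected depletion (a methylation proxy) and
  bisulfite methylation calls to the quantified ratios.

All internal coordinates are 0-based half-open; GFF3's 1-based closed
convention is converted only at the I/O boundary.

## Detection rules and their thresholds

**Junction filtering.** Junction calls must score *strictly* above 0.5 to
be used; calls from independent runs are clustered by summing support and
keeping the maximum score.  Retained junctions are partitioned by whether
both, one, or neither splice site exactly matches an annotated exon
boundary on the same strand.

**Cassette exons.** A fully known junction joining non-adjacent exon
boundaries of one transcript marks every annotated exon strictly between
them as a cassette exon.  Its inclusion ratio is
$\frac{(N(b{\sim}p)+N(q{\sim}c))/2}{(N(b{\sim}p)+N(q{\sim}c))/2+N(b{\sim}c)}$,
with $N$ the junction read support, $b$/$c$ the flanking boundaries and
$p$/$q$ the exon.  Missing junctions contribute support 0 (so the ratio
can reach the extremes 0 and 1); an event with all three supports zero is
kept but flagged `NA`.

**Intron retention.** An annotated intron is retained when (i) *every*
intronic base exceeds 5x depth and (ii) the inclusion ratio
$2\,\mathrm{Cov}(p,q)/(\mathrm{Cov}(a,p)+\mathrm{Cov}(q,d))$ is at least
three times the genome-wide baseline intron inclusion ratio, which
defaults to 0.017.  The ratio is deliberately unclamped (it can exceed 1
when the intron is deeper than its flanks).  The baseline is exposed as a
configuration constant because on other data it should be recomputed from
all annotated introns.

**Alternative exon boundaries.** A half-known junction displaced by
strictly less than 200 bp from an annotated boundary, staying within the
flanked exon, is an alternative donor or acceptor; which of the two is
decided in transcription orientation (the intron-start side is the donor
on `+` and the acceptor on `-`).  The displacement bound is interpreted
as an absolute two-sided window, and the boundary value 200 is rejected.
The splicing ratio is minor/major junction support ($\min/\max$, 1 on
ties, `NA` when both are zero); the inclusion ratio of the boundary
region is the support of the region-retaining junction over the summed
support.  Ties in major/minor assignment break toward the annotated site.

**Alternative terminal exons.** Only terminal-exon pairs that splice into
the *same* constitutive site are called (a first-exon pair must share its
downstream acceptor, a last-exon pair its upstream donor).  Their
splicing ratio reuses the minor/major formula on the two junctions into
the shared site.

## Gene-model augmentation

Transcribed islands are maximal runs of coverage at or above 5x, at least
50 bp long after merging gaps of at most 10 bp, that do not overlap any
annotated exon.  These three parameters are deliberately conservative
defaults, exposed in the configuration: the island concept constrains
only where novel exons may be placed, and the junction-side boundary of
every novel exon is exact by construction while the island-side boundary
is only accurate to the gap parameter.  Two augmentation routes exist: a
half-known junction whose novel end lands in an island creates a novel
exon attached to the gene owning the known side, and a both-novel
junction bridging two islands in intergenic space (no overlap with any
annotated gene span, either strand) creates a novel two-exon gene.  Novel
transcripts require at least two exons; single islands are never emitted
as transcripts.  Augmentation never modifies annotated features and is
idempotent, and novel features are written to GFF3 with source
`beesplice` so they remain distinguishable.  When a junction record
carries strand `.`, the strand is inferred from the GT/AG orientation of
its terminal dinucleotides.

## Splice-site strength

Site strength is the log2 odds of the motif window under a
maximum-entropy model of true sites versus a 0th-order genome background.
Window geometry follows the common convention for such models: donors
span 3 exonic + 6 intronic bases (9 nt), acceptors 20 intronic + 3 exonic
bases (23 nt); both are configuration options.  The model is fitted by
iterative proportional scaling subject to position marginals
(`constraint_order = 1`) or position plus adjacent-pairwise marginals
(`constraint_order = 2`, the default).  Because the constraint graph is a
chain, normalization and model marginals are computed exactly by forward–
backward dynamic programming, so the 23-mer acceptor never requires
enumerating $4^{23}$ motifs, and two limits hold exactly: the first-order
solution coincides with the independence (PWM) model, and adding
constraints can only increase training-set likelihood.  Convergence is
declared when fitted and empirical marginals agree within 1e-4
(configurable).  Training sites default to the windows of all unique
annotated introns of the supplied annotation; we train on the data at
hand rather than importing published human parameter tables, since
invertebrate site composition differs and the comparisons we make are
internal to one genome.

For figures-style comparisons, cassette exons contribute their own
acceptor and donor scores per inclusion-ratio bin; retained introns
contribute the average of their two flanking site scores; AEB/ATE events
contribute the difference between the major and minor variant's score per
splicing-ratio bin.  Extreme occupied bins are compared with a two-sided
Mann–Whitney test: exact by full enumeration (midranks for ties) up to a
combined n of 20, normal approximation with tie correction beyond.  No
multiple-testing correction is applied to these descriptive p-values;
this mirrors how such figure-level comparisons are usually reported and
is stated here prominently.

## CpG and methylation

CpG(o/e) is $P_{CpG}/(P_C \cdot P_G)$ with overlapping dinucleotide
counting over the $L-1$ windows of a region and base frequencies over its
$L$ bases; the counting convention (denominator $L-1$) is ours, chosen
for exactness on short regions, and the score is computed on the plus
strand since CpG is its own reverse complement.  The relative CpG score
of an AEB event is the absolute difference between the o/e of the exon
built with each boundary variant.  A region is "methylated" when at
least one covered CpG in it has a methylated read count above zero,
"unmethylated" when it has covered CpGs and none is methylated; the
minimum coverage for "covered" defaults to a single read and is
configurable.  These rules make the classification monotone: adding a
methylated call can never demote a region.

## The synthetic-data generator

The generator is first-class, tested code that defines the study
conditions.  It lays out three-exon genes with alternating strands on one
contig (exon lengths ~N(320, 80) bp, intron lengths ~N(1390, 300) bp,
clipped to leave room for planted features), writes canonical GT/AG
dinucleotides at every intron boundary, plants a configured number of
events of each kind with target ratios drawn from a nine-point grid on
[0.1, 0.9], and emits the complete input file set plus a truth table.
Read support is binomial at the configured depth (default 100x), so
recomputed ratios converge to the targets as depth grows; intronic
background noise is Poisson at 0.017x of exon depth, mirroring the
genome-wide baseline inclusion ratio, and practically never clears the
strict 5x IR floor.  Planted retained introns get uniform coverage at
`ratio * depth`, so their recomputed inclusion ratio is exact.

Optional couplings make the figure-style analyses reproducible by
design: `couple_strength = "planted"` samples site motifs from
consensus-biased pools whose bias follows the planted ratio (stronger
sites for high-inclusion cassette exons, weaker for high-inclusion
retained introns, and a graded major-weak/minor-strong assignment as the
splicing ratio rises); `couple_methylation = "planted"` couples CpG
density of the event region to the planted ratio and depletes CpGs in
retained introns.  Under coupling, boundary displacements are drawn from
60–150 bp so the two competing motif windows and the boundary region do
not overlap; otherwise they follow the 3/4/5 bp pool that dominates real
displacement spectra.  Exons are independently flagged "methylated"
(default 50%), which depletes their CpGs to 25% and emits bisulfite
records with nonzero methylated counts.

What the generator does *not* emulate: read-level sequencing error,
mappability artifacts, overlapping genes, isoform-level coverage
heterogeneity along exons, and junction-score miscalibration.  Passing
tests therefore demonstrate correctness of the detection rules and
formulas under the stated statistical structure, not robustness to every
artifact of real libraries.

## Numerical choices and degenerate inputs

* Ratio comparisons against thresholds use a 1e-9 guard where the
  threshold itself is a float product (3 x 0.017), so a ratio of exactly
  0.051 passes.
* Zero-support and zero-denominator metrics are `NA`, never silently 0,
  and the events are retained.
* Duplicate junctions merge by summed support and maximum score; the
  maximum (not the mean) is kept so one confident observation is not
  diluted by replicates.
* Empty inputs (no junctions, empty annotation, zero coverage) flow
  through every operation and produce empty results, not errors;
  mismatched chromosome namespaces are an error naming the offenders.
* All writers emit deterministically ordered, fixed-notation text, so a
  fixed seed reproduces every output byte-for-byte.

## Problem sizes

The bundled tests run the full pipeline on genomes of 15–60 genes and the
statistical analyses on 130–420 genes with 100–360 planted events per
coupling scenario; these sizes were chosen so binomial noise at 100x
depth is small relative to the planted effects while the whole suite
stays quick on a laptop.  Detection quality is also probed at 1000x depth,
where recomputed ratios match planted ratios within 0.02 on average.

## Limitations

* CE detection is restricted to annotated internal exons; novel cassette
  exons arise only after augmentation has added them.
* The pipeline quantifies events descriptively; it does not model
  read-length-normalized percent-spliced-in, isoform abundance, or
  differential splicing between conditions.
* Orthology is consumed from a user table, never computed.
* The IR baseline default (0.017) is a literature-scale constant for the
  honey bee; other genomes should recompute it.
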