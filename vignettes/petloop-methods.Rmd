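---
title: "petloop: models and methods for ChIA-PET chromatin interaction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{petloop: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petloop)
```

## The problem

ChIA-PET (chromatin interaction analysis by paired-end tag sequencing)
captures pairs of genomic loci that were in spatial contact and bound by a
chromatin mark of interest -- typically H3K4me3 at active promoters and
H3K27ac at active enhancers. Each sequenced read pair (a PET) marks two loci;
clusters of PET ends form interaction anchors, and anchor pairs supported by
many linking PETs are candidate chromatin loops. petloop implements the full
desk-side analysis for such data: from mapped PETs in BEDPE to
high-confidence loops, promoter/enhancer annotation, expression integration,
two-tissue comparison, and chromatin interaction networks (ChINs). A
deterministic synthetic-data generator with a ground-truth manifest makes
every stage testable without any sequencing data.

All coordinates are 0-based half-open, the native convention of the
BED/BEDPE inputs; GFF3 gene models are converted on read. All overlap
predicates in the package mean ">= 1 bp overlap" under that convention.

## PET processing

Replicates are pooled and exact duplicates (identical coordinates of both
ends after canonical ordering) are collapsed, with the multiplicity retained.
The genomic span of a PET is the distance between its two end midpoints
(integer floor); midpoints make the span invariant to read length, which the
raw inner-edge distance is not. Same-chromosome PETs with span strictly below
10 kb are classified as self-ligation products -- a single fragment
circularizing on itself -- and removed before loop calling; a span of exactly
10,000 bp is kept. Different-chromosome PETs are kept aside as
inter-chromosomal candidates.

A deliberately minimal window-Poisson peak caller
(`call_pet_peaks_simple()`) is included so synthetic end-to-end runs need no
external binary: fixed windows, per-window PET-end counts tested against a
genome-wide mean Poisson rate, adjacent significant windows merged. It is not
a substitute workflow for real data, where MACS peaks are supplied through
`read_peaks()`.

## The interaction significance model

Candidate interactions are all peak pairs linked by at least one PET (a PET
links A and B when its two end midpoints fall in A and B, A != B; peaks of a
mark are merged to be non-overlapping first). Significance uses a
hypergeometric urn: given `nTot` PETs in the candidate-generating population,
of which `nA` end in anchor A, the probability of seeing at least `x` of the
`nB` anchor-B PET ends also landing in A is

    P[X >= x],  X ~ Hypergeometric(nTot, nA, nB).

Three operational choices deserve note, each configurable or documented:

* **Population.** `nTot` counts PETs whose both ends are peak-assigned --
  the population from which candidates arise. This keeps the urn
  self-consistent: every draw in the model corresponds to a PET that could
  have produced a candidate.
* **Per-anchor counts.** `nA` and `nB` count PET *ends* in the anchor within
  that population (a PET with both ends in A contributes 2 to `nA`).
* **Tail.** One-sided upper tail, computed by log-space summation of PMF
  terms for numerical stability; `P[X >= 0] = 1` by construction.

p-values are adjusted with the Benjamini-Hochberg step-up genome-wide across
all candidates of a run (per mark, per tissue), and interactions with at
least 3 linking PETs and FDR < 0.01 are reported as high-confidence. The
model is deliberately distance-free; the background distance decay present in
real (and simulated) data is what the count threshold and the FDR control are
tested against. Mark-specific interaction sets from the same tissue are then
unioned, treating two records as the same event when both anchor pairs
overlap by >= 1 bp -- the same matching rule used everywhere in the package
(mark merging, tissue comparison, network conservation), so there is exactly
one notion of "the same loop".

Inter-chromosomal candidates are scored identically (`pet_class = "inter"`)
but reported separately and never enter distance-based stages.

## Anchor annotation

A peak is proximal (P) when its interval overlaps the window
`[TSS - 2000, TSS + 2000)` of at least one gene, otherwise distal (D). The
overlap is between the peak interval and the TSS window -- not a midpoint
distance -- which makes the proximal rule the exact complement of the distal
regulatory region (DR) definition: an H3K27ac peak at least 2 kb from every
TSS. Interactions inherit their class from the anchors (P-P, P-D, D-D).

DRs receive exactly one genomic-location label with precedence
geneBody > downstream2kb (strand-aware 2 kb past the TTS) > TE > intergenic.
The precedence among overlapping categories is a design choice of this
package (the categories genuinely overlap and no canonical order exists);
it is exposed so users can reorder by calling the predicates themselves.

Interaction distances are anchor-midpoint distances, consistent with PET
spans. Distance histograms use half-open bins whose default interior edges
are 10 kb / 50 kb / 100 kb / 1 Mb over the implicit support [0, Inf), so bin
masses always sum to the number of interactions. Connectivity statistics
(distal partners per promoter and vice versa) count distinct partner anchors
of P-D interactions. "Skipped genes" of a P-D loop are genes whose TSS lies
strictly between the anchor midpoints with a TSS window clear of both
anchors; "typically expressed" means mean FPKM >= 1, the same threshold as
the activity call.

## Expression integration

A gene is active when its mean FPKM over the sample panel is >= 1. Tissue
specificity uses Shannon entropy over the N-sample panel: with relative
expression p_t = w_t / sum(w),

    H = sum_t -p_t log2(p_t),   0 <= H <= log2(N),

low H meaning tissue-restricted, H near log2(N) constitutive. Genes with an
all-zero profile have no defined distribution and are excluded with a
warning.

Co-expression of P-P-connected promoter pairs is tested against
distance-preserving controls: each eligible interaction (both anchors
overlapping exactly one gene promoter, two different genes) is shifted along
its chromosome by a uniform random offset 100 times; a shifted loop is kept
as a control when both anchors again land on promoter windows of two
different genes and both carry peak signal at least the 25th percentile of
signals at real interacting anchors. The percentile rule is this package's
reproducible operationalization of "similar mark level" -- the qualitative
filter is otherwise not computable -- and the quantile is a parameter.
Observed and control Pearson correlations are compared with a two-sided
Welch t test; Welch because nothing guarantees equal variances between the
two sets. Under a null with no planted co-expression the test rejects at
close to its nominal level (the suite calibrates this over 500 simulated
expression panels).

The entropy-by-context analysis groups genes by their relation to distal
anchors: interacting with a genic D (D overlapping any gene body),
interacting with an intergenic D, carrying a D inside the gene's own body
(regardless of interactions), and a control group of genes with promoter
mark signal but no intergenic-D interaction. Groups are deliberately not
exclusive; a gene contributes to every group whose definition it meets.

## Two-tissue comparison

Tissue-specific expressed genes follow a stringent rule: mean FPKM exactly 0
in one tissue's samples and >= 2 in the other's. The strict zero is kept as
stated -- quantification noise would motivate a tolerance, but the rule is
implemented as written and the threshold is a parameter. An interaction is
tissue-specific when no interaction of the other tissue matches it under the
both-anchor overlap rule; matched interactions are common, and the
specific/common split partitions each tissue's set exactly. Class enrichment
among specific vs common interactions uses 2x2 Fisher exact tests (the
natural exact test at these counts). Promoter interaction strength per gene
counts intra-chromosomal PETs with at least one end midpoint in the promoter
window, once per PET.

## Chromatin interaction networks

Anchors are nodes, interactions are edges; components are extracted with
igraph and components with at least 3 interactions are reported as ChINs.
Cross-tissue conservation of P-P components is measured as the fraction of a
component's P-P edges matched anywhere in the other tissue, conserved when
above 0.65. Edges are the unit because the component-size rule itself counts
interactions; a node-based alternative (fraction of component nodes
overlapped by the other tissue's P-P anchors) is exposed as
`method = "nodes"`. Term enrichment per component is the generic
hypergeometric upper tail over a flat gene-to-term map with BH correction
across terms -- no ontology propagation, by design, so any annotation source
can be used.

## The synthetic-data generator

The generator emulates the features of promoter-centred ChIA-PET data that
the pipeline's decisions depend on, with a reference configuration used
throughout the test suite (chosen once as a realistic desk-scale study):

* genome: 2 chromosomes x 20 Mb, 300 genes (>= 12 kb apart, log-normal
  lengths), one proximal peak per TSS and 300 distal peaks >= 2 kb from all
  TSS, placed in gene bodies, downstream windows, TEs and intergenic space;
  2 kb anchors (the scale of observed distal regulatory elements);
* loops: 200 planted peak pairs at midpoint distance >= 10 kb in a
  0.60/0.35/0.05 P-P/P-D/D-D mix, Poisson(10) PETs per loop. Poisson was
  chosen over negative binomial for analytic tractability; the loop-count
  mean is the single knob that controls recovery difficulty;
* background: 50,000 PETs, of which 30% self-ligation (spans uniform in
  [100, 9999]), 10% inter-chromosomal, and the rest anchored at a random
  peak with the partner end at distance d ~ d^-1 truncated to
  [1 kb, 10 Mb]. The power-law decay is a modeling choice for
  stress-testing: the significance model itself is distance-free, so a
  distance-skewed background is exactly what could fool it;
* expression: 78 samples shaped as 53 + 25; log-normal baselines; planted
  co-expressed pairs share a latent factor whose loading is solved in closed
  form so the expected Pearson correlation of the log-normal values equals
  the target rho (default 0.6); tissue-specific genes are exactly 0 in one
  sample group and >= 2 in mean in the other; constitutive genes (those
  hosting a distal peak in their body) get near-uniform profiles; genes
  interacting with intergenic D get restricted profiles over a small noise
  floor. These planted contrasts are what the entropy-by-context and
  co-expression analyses are validated against. Where one gene would play
  several roles, a documented precedence applies (tissue-specific >
  co-expressed > constitutive > restricted > intermediate) and the manifest
  records which co-expressed pairs were actually realized.

Every stage draws from a stream derived deterministically from the master
seed, so (configuration, seed) reproduces all outputs byte-identically.

What the generator does *not* emulate -- and hence what passing tests do not
show about real data: mappability and alignment artifacts, linker chimeras,
PET-count overdispersion beyond Poisson, peak-width heterogeneity, chromatin
domain structure beyond a single power-law decay, and real gene-density
landscapes. Results on synthetic data validate the statistical machinery and
the bookkeeping, not biological discovery.

## Numerical and degenerate-input choices

* Hypergeometric tails are computed by log-sum-exp over log PMF terms; the
  suite checks exact agreement (1e-12) with combinatorial enumeration for
  all populations up to 30 and with the distribution function elsewhere.
* Midpoints use integer floor division; distances are exact integers.
* After peak merging, a PET end falling in several peaks cannot occur; the
  assignment uses the first (only) overlap.
* Empty inputs (no PETs, no peak-assigned PETs, no eligible promoter pairs,
  empty BED files) return empty results with a warning rather than erroring,
  so pipelines degrade gracefully; genuinely invalid inputs (negative
  coordinates, malformed lines, out-of-range p-values, overlapping sample
  groups) error with the offending record named.
* BH ties and order: the step-up is order-invariant and idempotent on its
  output scale; adjusted values are clipped at 1.

## Problem sizes used by the suite

The test suite runs the reference scenario over seeds 1-10 for loop
recovery (recall >= 0.90 at empirical FDR <= 0.05 under the >= 3 PETs /
FDR < 0.01 rule), a 500-gene all-P-P scenario for the co-expression power
and null calibration (500 expression panels), and smaller genomes
(5-15 Mb) for construction and round-trip properties. These sizes were
chosen so the full suite exercises every stage end to end in a few minutes
on a laptop while keeping planted-structure recovery statistically
meaningful.

## Known limitations

* The hypergeometric model ignores genomic distance; on strongly
  distance-decayed backgrounds short-range candidate pairs are the main
  source of false positives, which is why the empirical-FDR property is part
  of the acceptance suite rather than assumed.
* The strict FPKM = 0 rule for tissue-specific genes is noise-intolerant by
  construction.
* Term enrichment treats annotations as a flat map; hierarchical ontologies
  should be flattened (or propagated) upstream.
* The conservation metric for P-P components is one of several defensible
  choices; both implemented metrics are reported per component so the
  threshold can be re-examined.
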