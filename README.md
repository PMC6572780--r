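# petloop

Chromatin interaction calling, annotation and network analysis for ChIA-PET
data, with a fully deterministic synthetic-data generator for end-to-end
validation.

## What it is for

ChIA-PET enriches proximity-ligation read pairs (paired-end tags, PETs) for a
chromatin mark — typically H3K4me3 at active promoters and H3K27ac at active
enhancers — so that each read pair is evidence that two mark-bound loci were
in spatial contact. petloop takes mapped PETs (BEDPE), peak calls (BED) and
gene models (GFF3) and produces the analyses a regulatory-genomics study
builds on them:

* **PET processing** — replicate pooling, deduplication, and removal of
  self-ligation PETs (genomic span < 10 kb, midpoint-to-midpoint).
* **Interaction calling** — for each peak pair linked by PETs, the
  hypergeometric upper tail `P[X ≥ x]`, `X ~ Hypergeom(nTot, nA, nB)`, with
  `x` the linking PETs, `nA`/`nB` the per-anchor PET ends, and `nTot` the
  PETs whose both ends are peak-assigned; Benjamini–Hochberg correction
  across candidates; high confidence means ≥ 3 PETs and FDR < 0.01.
* **Anchor annotation** — proximal (P) anchors overlap a TSS ± 2 kb window,
  the rest are distal (D); distal regulatory regions (DRs) are H3K27ac peaks
  ≥ 2 kb from every TSS; interactions are classed P–P / P–D / D–D; distance
  histograms, promoter–enhancer connectivity and skipped-gene reports.
* **Expression integration** — activity calls (FPKM ≥ 1), Shannon-entropy
  tissue specificity `H = Σ −p_t log2 p_t` over an expression panel, and
  co-expression of P–P-connected promoter pairs against distance-preserving
  shifted controls (Welch t test).
* **Two-tissue comparison** — tissue-specific expressed genes (FPKM exactly
  0 vs ≥ 2), tissue-specific vs common interactions (both-anchor ≥ 1 bp
  overlap matching), class enrichment by Fisher exact test.
* **Networks** — chromatin interaction network (ChIN) components with ≥ 3
  interactions, degree and span statistics, cross-tissue conservation of
  P–P components, and hypergeometric term enrichment per component.
* **Synthetic data** — a seeded generator planting loops, co-expressed
  pairs, tissue-specific and constitutive genes in a distance-decay PET
  background, with a ground-truth manifest, so the whole pipeline is
  testable at desk scale.

## Worked example

```r
library(petloop)

cfg <- sim_config(seed = 1)          # reference scenario: 2 x 20 Mb, 300 genes,
sim <- simulate_dataset(cfg)         # 200 planted loops, 50,000 background PETs

pets <- classify_pets(pool_and_dedup(list(sim$pets)))
pets
#> PET set: 52041 unique PETs
#>   total         52042
#>   unique        52041
#>   selfLigation  22614
#>   intra         24467
#>   inter         4960

calls <- call_interactions(pets, sim$genome$peaks)
ann   <- annotate_peaks(sim$genome$peaks, sim$genome$genes)
calls <- classify_interactions(calls, ann)
nrow(calls)                          # 206 high-confidence interactions
table(calls$class)                   # DD 12   PD 74   PP 120
median(interaction_distance(calls))  # 292,198 bp

ct <- coexpression_test(calls, ann, sim$genome$genes, sim$expr,
                        sim$genome$peaks, sim$genome$chrom_sizes, seed = 1)
ct
#> P-P promoter co-expression vs shifted controls
#>   observed pairs: 120 (mean r = 0.367)
#>   control pairs:  11 (mean r = 0.132)
#>   Welch t = 2.908, two-sided p = 0.0121

chins <- build_chins(calls, annotations = ann)
chins
#> ChIN set: 13 components with >= 3 interactions
```

All 200 planted loops are among the 206 calls (recall 1.0, six
false-positive background pairs, empirical FDR 0.029), their P–P/P–D/D–D
labels match the manifest exactly, promoter pairs connected by P–P loops are
measurably co-expressed relative to shifted controls, and the anchors weave
into 13 ChINs whose largest has 11 interactions over 12 anchors and 8 genes.

## Documentation

The methods vignette (`vignettes/petloop-methods.Rmd`) describes the
statistical model and its assumptions, every tunable threshold with its
default and rationale, what the synthetic generator does and does not
emulate, and the package's numerical and design choices.
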