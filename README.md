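# epiloop

Integrative 3D-epigenomic analysis of condition-specific transcription.

`epiloop` is an R/Bioconductor-style package for asking why a gene is
transcribed in one cell state and silent in another, by joining the data
layers that surround RNAPII- and CTCF-mediated chromatin loops
(ChIA-PET-style peaks and loops): two-state expression tables, histone-mark
peaks and signal (H3K4me1, H3K4me3, H3K27ac, H3K27me3), CTCF/RNAPII
binding, per-CpG bisulfite methylation, and non-coding variants with
linkage-disequilibrium structure.  It is aimed at regulatory-genomics
analysts who have processed peak/loop/methylation calls in standard text
formats (BED, BEDPE, bedGraph, TSV) and want a tested, scriptable pipeline
from those files to linked biological calls.

## What it computes

* **Condition-specific genes** — threshold calls on
  `log2((mean_A + c)/(mean_B + c))` with a 4-fold default
  (|log2FC| ≥ 2) and a 1 TPM expression floor; plus expression breadth
  across a multi-cell panel.
* **Interaction domains** (RAID for RNAPII, CCD for CTCF) — connected
  components of anchor-overlapping loops, with single-gene (SG) vs
  multi-gene (MG) classification by TSS content.
* **Enhancer chromatin states** — active (H3K4me1+H3K27ac), intermediate
  (H3K4me1 only), poised (H3K4me1+H3K27me3) — and **promoter strength**,
  log2(H3K4me3/H3K4me1) at the TSS, negative = enhancer-like (Ep).
* **The E-P network** — loop anchors annotated P/Ep/E, edges typed by
  anchor pair, per-gene connected-enhancer counts, and the expression
  effect of 1 / 2 / ≥3 connected enhancers (Wilcoxon rank-sum).
* **Co-transcription** — Pearson correlation of promoter-promoter-linked
  gene pairs across an expression panel (fraction with r > 0.25) against
  a degree-preserving rewired null with an add-one empirical p-value.
* **Enrichment statistics** — hypergeometric SNP enrichment of
  LD-expanded (r² ≥ 0.8) variant sets in enhancer classes, two-proportion
  z ranking of TF occupancy, two-sample KS for binding breadth, and a PWM
  scanner for motif placement.
* **Differential CTCF binding** — MA classification
  (M = log2 intensity ratio, |M| ≥ 1) of merged promoter-proximal CTCF
  sites, binding breadth across a cell panel, and the methylation of CTCF
  peak footprints (~500 bp) and motif windows (219 bp): coverage-weighted
  beta means and Fisher+BH differential methylated cytosine (DMC) calls.
* **A/B compartments** — leading eigenvector of the observed/expected
  correlation matrix of a binned contact map, oriented so A is the
  gene-dense class, with per-gene compartment-switch calls.

A fully synthetic two-state data generator (`generateDataset()`) plants
all of this structure — specific genes with a 16-fold expression ratio,
E-P loops, co-expressed P-P pairs, methylation-coupled CTCF sites, LD
blocks, compartments — with machine-readable truth tables, so the entire
pipeline is testable end to end without any external download.

## Worked example

```r
library(epiloop)

ds <- generateDataset(synthConfig(seed = 42))
b  <- ds$bundle

# 1. condition-specific genes
de <- callSpecificGenes(b$expr, b$states, "A", "B")
table(de$call)
#>    a_specific    b_specific low_expressed        shared
#>            50            50            25            75

# 2. loops -> interaction domains
dom <- clusterDomains(b$loops$A$RNAPII)
head(dom$domains, 3)
#> GRanges object with 3 ranges and 3 metadata columns:
#>       seqnames        ranges strand |   domain_id      factor   n_loops
#>   [1]     chr1  49847-253864      * |    RAID_001      RNAPII         5
#>   [2]     chr1 349626-518252      * |    RAID_002      RNAPII         3
#>   [3]     chr1 650616-853837      * |    RAID_003      RNAPII         5

# 3. enhancers, promoter strength, E-P network
loops <- b$loops$A$RNAPII
enh <- defineEnhancers(b$peaks$A$H3K4me1, b$peaks$A$H3K27ac,
                       b$peaks$A$H3K27me3, b$genes, loops)
stg <- promoterStrength(b$genes, b$signal$A$H3K4me3, b$signal$A$H3K4me1)
a1  <- annotateAnchors(anchorOne(loops), b$genes, stg, enh)
a2  <- annotateAnchors(anchorTwo(loops), b$genes, stg, enh)
net <- buildEPNetwork(loops, a1, a2)
net
#> EPNetwork: 148 nodes, 108 edges
#>   edge types: E-Ep=22 E-P=76 Ep-P=4 P-P=6

# 4. co-transcription of P-P pairs vs the rewired null
pairs <- extractPPPairs(net)
pairPearson(pairs, b$panel)$fractionCorrelated
#> [1] 1
rn <- rewiredNull(pairs, b$panel, nPerm = 1000, seed = 42)
c(observed = rn$observedMean, null = mean(rn$null), p = rn$p.value)
#>  observed mean r = 0.992, null mean r = -0.038, empirical p = 0.000999

# 5. differential CTCF binding and motif methylation
spec <- ds$truth$specificGenes
diff <- differentialBinding(b$peaks$A$CTCF, b$peaks$B$CTCF,
                            b$genes[spec$gene_id])
table(S4Vectors::mcols(diff)$call)
#> up_a up_b
#>   50   50
tru    <- ds$truth$ctcfSites
motifs <- bedToGRanges(tru$chrom, tru$motif_start, tru$motif_end)
mA     <- methylationInRegions(b$methylation$A, motifs, "motif_219bp")
compareRegionMethylation(mA[tru$call == "up_a", ], mA[tru$call != "up_a", ])
#> motif beta, bound 0.10 vs unbound 0.90, rank-sum p = 6.76e-18
```

Reading of the numbers: the caller recovers the 50+50 planted specific
genes; RNAPII loops cluster into multi-loop domains spanning the planted
regulatory territories; the state-A network contains one E/Ep link per
planted enhancer; the ten planted promoter-promoter pairs are perfectly
co-expressed while rewired pairings are uncorrelated (the add-one
estimator bottoms out at 1/1001 for 1000 permutations); and CTCF sites
bound in state A are hypomethylated at their motif windows (beta 0.10)
exactly where the unbound state is hypermethylated (0.90).

File-based workflows use `writeBundle()` to emit the synthetic data in
the standard formats, `bundleRunConfig()` + `runPipeline()` to drive all
stages from one config (YAML/JSON or list) with a JSON run report, and
`inst/scripts/epiloop.R` as a shell front-end
(`Rscript epiloop.R synth|validate|run-all ...`).

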