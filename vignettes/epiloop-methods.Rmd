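---
title: "Methods: integrative loop-resolved epigenomics with epiloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative loop-resolved epigenomics with epiloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

`epiloop` implements an integrative 3D-epigenomic analysis that asks why a
gene transcribes in one cell state and not in another.  It joins five data
layers around RNAPII- and CTCF-mediated chromatin loops (as produced by
ChIA-PET-style assays): expression tables for two cell states, histone-mark
peaks and signal (H3K4me1, H3K4me3, H3K27ac, H3K27me3), CTCF and RNAPII
binding, per-CpG bisulfite methylation counts, and non-coding variant
tables with linkage-disequilibrium (LD) structure.  The output is a set of
linked calls: condition-specific genes, the interaction domains and
enhancer-promoter (E-P) networks that contain them, promoter-proximal
differential CTCF binding, and the CpG methylation changes at CTCF motifs
that accompany it.

All coordinates are held internally as `GRanges` (1-based, closed); every
file format is the 0-based half-open BED dialect, converted exactly at
read/write.  The dialect is declared, never guessed: a 1-based input file
is the caller's error, not a heuristic's.

## Stage-by-stage model

**Condition-specific genes.** The caller is deliberately a transparent
threshold rule, not a fitted model: with per-state means $\bar a,\bar b$
and pseudocount $c = 0.1$,
$\mathrm{log2fc} = \log_2\frac{\bar a + c}{\bar b + c}$, and a gene is
A-specific iff $\mathrm{log2fc} \ge 2$ (a 4-fold change) and
$\bar a \ge 1$ TPM.  Genes below 1 TPM in both states are `low_expressed`;
the remainder are `shared`.  The 4-fold default reads the conventional
"±4-fold change" convention; the threshold is a parameter because the
alternative reading (|log2FC| ≥ 4) exists.  No distributional test is
fitted: abundances arrive already normalised (TPM/RPKM) and replicate
structure is not assumed.

**Expression breadth.** Across a panel of cell types, breadth is the
fraction of cells with abundance ≥ 1; a gene with breadth ≤ 0.2 is labelled
cell-specific.  The 0.2 cutoff is a declared default (exposed as
`breadthMax`), chosen so that a gene expressed in a handful of related cell
types still counts as narrow on panels of 20-100 cells.

**Interaction domains (RAID/CCD).** A domain is a connected component of
the graph whose nodes are loops and whose edges join loops with anchors
closer than `mergeGap` bp (strict overlap at the default 0).  This is the
simplest operational definition consistent with "a cluster of connected
loops"; published domain callers differ in details that their supplements
rarely state, so the definition here is declared and parameterised rather
than reverse-engineered.  Gene-domain membership is decided by the TSS, not
the gene body, because every promoter-centred quantity in the pipeline is
TSS-anchored.  The clustering is order-invariant and partitions the loop
set; both properties are tested.

**Enhancers and promoter strength.** The enhancer universe is H3K4me1
peaks outside all TSS windows (±2 kb) that touch at least one RNAPII loop
anchor — the anchor requirement operationalises "enhancers engaged in
RNAPII-mediated interactions" (overlap with RNAPII peaks instead is
available via `requireAnchor = FALSE`).  Chromatin state is
H3K4me1+H3K27ac = active, H3K4me1 only = intermediate,
H3K4me1+H3K27me3 = poised; a region with all three marks is poised
(repression dominates), keeping the rule total.  Promoter strength is
$\log_2\frac{\mathrm{H3K4me3} + \varepsilon}{\mathrm{H3K4me1} + \varepsilon}$
over the TSS window with $\varepsilon = 0.1$; negative means
enhancer-like (Ep), non-negative strong.  The tie at exactly 0 goes to
strong: the boundary must belong somewhere, the published rule defines
only the two open half-lines, and with $\varepsilon$-smoothing the
boundary carries no mass in practice.

**The E-P network.** Each loop anchor is annotated `P`, `Ep`, `E`, or
`none`; promoter identity takes precedence over enhancer overlap (the Ep
concept presumes promoter identity dominates), and an anchor spanning two
TSS windows takes the nearer TSS with a logged ambiguity.  Edges are typed
by their anchor pair; multiple loops supporting one pair collapse into one
edge with a support count.  A gene's connected-enhancer count includes
enhancer-like promoters of partner genes, so the 1 / 2 / ≥3 stratification
of expression by enhancer count (compared by rank-sum test) sees the same
enhancer definition the counts do.

**Co-transcription.** Promoter-promoter pairs (including Ep-P, the
default, since an enhancer-like promoter is still a promoter) are
correlated across the expression panel with Pearson r; the headline number
is the fraction of pairs with r > 0.25.  Significance comes from a
degree-preserving rewired null: each permutation rematches the multiset of
paired genes uniformly at random, rejecting self-pairs and observed pairs,
so every gene keeps its pairing multiplicity.  "Randomly rewired" alone
does not determine a null; degree preservation is the stricter choice and
an unconstrained mode is available behind `mode = "free"`.  The empirical
p-value uses the add-one estimator $(1 + \#\{null \ge obs\})/(n_{perm}+1)$
and therefore never returns 0.

**Differential CTCF binding.** Sites are merged A∪B peak footprints
restricted to the TSS windows of the genes of interest.  Per state the
site intensity is the maximum overlapping peak intensity (summit height is
the conventional MA input; sum and mean are available), and
$M = \log_2\frac{a+\varepsilon}{b+\varepsilon}$,
$A = \tfrac12\log_2\left((a+\varepsilon)(b+\varepsilon)\right)$ with calls at
$|M| \ge 1$ (2-fold; no published threshold exists, so it is a parameter).
Binding breadth across a cell panel is the number of panel cell types
whose peaks overlap the site, compared between site groups by the
two-sample KS test.

**Methylation.** Region methylation is the coverage-weighted mean beta
$\sum m_i / \sum t_i$ over CpGs with coverage ≥ 5, reported at CTCF peak
footprints (~500 bp) and motif windows (219 bp — treated as a width
parameter; canonical CTCF position weight matrices are ~19 bp and the
provenance of the wider figure is not stated in the source material).
Differentially methylated cytosines (DMCs) are called per shared position
with Fisher's exact test on the methylated/unmethylated count table,
Benjamini-Hochberg correction across all tested positions, and gates
q ≤ 0.05 and |Δβ| ≥ 0.25.  This Fisher+BH+delta procedure is a declared
substitute for an unnamed published caller.  No smoothing across
neighbouring CpGs is applied: the analysis operates at single-cytosine
resolution.

**Compartments.** A/B compartments come from the sign of the leading
eigenvector of the observed/expected correlation matrix of a binned
contact map, with orientation fixed so the A label has the higher mean
gene density (the standard sign-fixing rule).  Bins with a zero contact
marginal are NA.  A near-identity correlation matrix (leading eigenvalue
fraction below $2/m$ for $m$ bins) is flagged as structureless.

**Statistical kernels.** The rank-sum test enumerates the exact U null
distribution when the combined sample size is ≤ 12 (exact under ties,
where the usual exact algorithms are unavailable) and otherwise uses the
normal approximation with tie and continuity corrections.  The
two-proportion z uses the pooled variance without continuity correction,
so $z^2$ equals the uncorrected chi-square.  The hypergeometric tail,
Fisher's exact test, KS test and BH correction call the standard R
routines; the test suite still checks each against exhaustive enumeration
(or a brute-force ECDF supremum) on small instances, so the contract is
verified, not assumed.  SNP enrichment counts at the element level — an
element either contains a variant or not — because base-pair-level
counting lets element length dominate the statistic.  The hypergeometric
universe is the element set; whether the published analysis used an
element or SNP universe is not determinable from the text, so the
element reading is the default and documented as such.  Kernels return
raw p-values; BH is applied at the reporting layer when more than 10
simultaneous tests are emitted.

## The synthetic data generator

`generateDataset()` emulates the study's structure with planted ground
truth; its defaults are the package's reference conditions and are not
adjusted per analysis:

* 200 genes on 2 chromosomes, in disjoint ~150 kb territories occupying
  the proximal ~62% of each chromosome; the gene-free tail is the planted
  B compartment, which also makes gene density a valid orientation signal.
* 50 genes specific to each state with a 16-fold planted expression ratio
  before noise; multiplicative log-normal noise with sd 0.25 in log2
  units (the standard abundance noise model; ratios stay interpretable,
  and at this sd the realised replicate-mean ratio stays above half the
  planted fold).
* 1-3 enhancers per specific gene (probabilities 0.35/0.35/0.30), 15-52 kb
  from the TSS, each realised as an RNAPII loop with 1-3 kb anchors (the
  anchor scale implied by ±2 kb promoter windows) joining the enhancer to
  the TSS window.  Enhancer states are drawn 0.7/0.2/0.1
  active/intermediate/poised.  Expression scales with enhancer count, so
  the enhancer-count effect is a planted monotone signal.
* 10 promoter-promoter pairs per state between genome-adjacent specific
  genes, co-expressed across the 20-cell panel through a shared latent
  profile (and shared "on" cells), while unpaired specific genes get
  independent narrow profiles — breadth ~0.15, below the cell-specific
  cutoff.
* State-specific CTCF sites (~500 bp) at specific-gene TSSs, absent in the
  other state; shared genes carry equal-intensity constitutive sites.  A
  29-cell occupancy panel realises breadth 1 for specific sites and full
  breadth for constitutive ones.
* A 219 bp motif window centred on each CTCF site holds 11 CpGs at ~20 bp
  spacing, coverage 30, planted beta 0.1 when bound and 0.9 when unbound
  (`methylInverseCoupling`); counts are binomial draws by default and
  exact rounded counts in noiseless mode.  Background CpGs sit at beta 0.5
  in both states.
* Lead SNPs inside the first enhancer of every specific gene
  (cancer-related for state A, normal-function for state B) with three LD
  satellites whose r² decays exponentially at 0.1 per kb, plus 50
  background variants.
* Spurious loops at `loopNoiseRate` (default 0.1) of the planted count,
  with uniformly random anchors.

One RNG sub-stream per file type is derived from the master seed, so
adding a file type never perturbs the others, and a given seed yields
byte-identical bundles.  Territory isolation makes the planted truth
exact: each gene's loops form their own domain component (merged only by
planted P-P pairs), enhancers never collide with neighbouring promoter
windows, and at zero noise the emitted files contain exactly the planted
entities.

What the generator does **not** emulate — and what green tests therefore
do not show about real data: read-level noise and mapping artefacts,
realistic genome sequence composition, overlapping or nested regulatory
territories, inter-chromosomal structure, copy-number and batch effects,
and peak callers' boundary uncertainty.  The generator validates the
pipeline's logic, not the biology of any particular dataset.

## Numerical choices and degenerate inputs

* Uncovered bases in signal tracks score 0 (bedGraph sparsity), so a
  window outside the covered region has mean 0, not NA.
* Pseudocounts: 0.1 on abundances before fold change, 0.1 pseudo-signal
  in the promoter ratio, 0.1 pseudo-intensity in the CTCF MA transform.
  Each keeps a legitimate zero observation finite without drowning small
  signals.
* `mergeGap` maps to an anchor separation strictly below the gap
  (`maxgap = mergeGap - 1` in IRanges terms); 0 means true overlap.
* Degenerate statistics are defined, logged and non-fatal: pooled
  proportion 0 or 1 gives z = 0, p = 1; all-tied rank-sum input gives
  p = 1; zero-variance genes are excluded from correlation fractions; an
  empty stratum yields NA p-values without aborting.
* The rewired null rejects and redraws per permutation (cap 1000 tries)
  and errors when rematching is genuinely infeasible rather than
  silently relaxing the constraint.

## Problem sizes used in validation

The test-suite and acceptance-script runs use the generator's reference
conditions (200 genes, ~400 loops per state, 20-cell panel, ~3,500 CpGs):
single datasets for exactness checks, 10 seeds for the noisy-recovery,
co-transcription and compartment checks, 2000 null replicates for size
calibration of the rank-sum and two-proportion kernels, 1000 permutations
per rewired null and 200 independent runs for its size check.  These sizes
give the stochastic checks comfortable margins (binomial SEs of 1-2
percentage points) while a full validation run stays in the minutes range
on one core.

## Known limitations

* The DE caller is threshold-based; count-level models (and their
  dispersion handling) are out of scope because inputs are TPM/RPKM.
* Domain calling is a declared definition, not a reimplementation of any
  published RAID/CCD caller; with `mergeGap = 0` nested but non-touching
  structures stay separate.
* The compartment caller assumes a single chromosome per matrix and a
  roughly uniform bin coverage; translocated or highly sparse maps need
  upstream filtering.
* PWM scanning is provided for motif placement within CTCF analyses; de
  novo motif discovery is out of scope.
* `fisher.test`'s two-sided summation convention is inherited knowingly;
  alternatives (doubling the smaller tail) differ on asymmetric margins.
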