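---
title: "enhancermap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{enhancermap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`enhancermap` analyses single-cell histone-modification profiles of the kind
produced by combinatorial-barcoding ChIP-seq or CUT&Tag protocols applied to
H3K27ac, the canonical mark of active enhancers. The motivating application
is a heterogeneous immune population — cardiac mononuclear phagocytes
profiled across regenerative (P1) and non-regenerative (P10) neonatal mouse
hearts after myocardial infarction — but nothing in the implementation is
specific to that system. The pipeline runs from per-cell genomic fragments
to: a binary peak-by-cell detection matrix, an LSI embedding and clustering,
cluster-specific enhancer peaks, enhancer-based gene-activity proxies, GWAS
variant enrichment, cis-co-accessibility networks (CCRNs), motif deviation
scores and TF-target networks, neighbourhood differential abundance between
stages, and an MA-style fate-bias contrast between two monocyte-derived
fates.

Because per-cell histone signals are near-binary (a locus is either marked
or not detected at ~10^3-10^4 unique fragments per cell), the whole pipeline
treats peak detection, not coverage depth, as the per-cell signal.

## Fragments, QC, and the binary matrix

Coordinates are 0-based half-open (BED) everywhere; two intervals overlap
when they share at least one base. "Unique reads" means deduplicated
fragment records per cell; FRiP is the fraction of those fragments
overlapping any peak of the merged universe. The QC gate is strict on both
sides: a cell passes only with more than 1,500 unique fragments *and* FRiP
above 10%. Cells at exactly the threshold fail.

The peak universe is built by pooling fragments per aggregate sample,
calling maximal intervals with pooled coverage at or above a threshold
(default 5) and width of at least 200 bp, and merging the per-sample calls
(overlap of at least 1 bp merges; book-ended intervals stay separate). This
caller exists to make the multi-sample merge path executable end to end on
synthetic aggregates; for real data a dedicated peak caller should feed the
same merge step.

## Embedding, alignment, and clustering

The binary matrix is normalised by TF-IDF (per-cell term frequency, per-peak
inverse document frequency `log(1 + n_cells/detection_count)`, then
`log1p(1e4 * tf * idf)`) and reduced by truncated SVD, computed through the
cell-space Gram matrix since peaks outnumber cells. The first component is
dropped when its absolute correlation with per-cell detection depth exceeds
0.9, the usual LSI depth artefact. Eigenvector signs are fixed
deterministically.

Replicate alignment is a gated local centroid matching: a global pass plus
k-means partitions (fixed seed) in which each batch is translated onto the
local centroid, but only when the shift exceeds a noise gate of three times
the expected null centroid displacement (`sigma * sqrt(d/n_batch)`). The
gate makes the operation provably inert on batch-free data (the
null-displacement and structure-preservation tests), while a constant
offset between batches is removed exactly by the global pass.

Clustering sweeps a Leiden (modularity objective, fixed seed) resolution
grid of 0.2-2.0 in steps of 0.2 on a shared-nearest-neighbour graph
(k = 20, Jaccard weights, prune below 1/15). The sweep carries a labelling
forward when a higher resolution would produce fewer communities, making
cluster counts weakly monotone by construction. Stability of a resolution
is the mean, over its clusters, of the largest fraction of a cluster that
stays together at the next grid point.

Resolution selection takes the lowest resolution with stability at or above
0.9 and an unchanged cluster count at the next grid point. Two amendments
proved necessary in practice. First, single-cluster partitions are excluded
unless every resolution yields one: the trivial partition is perfectly
stable by construction and carries no information. Second, when no
resolution qualifies, the fallback maximises unscaled graph modularity
rather than raw stability: on sweeps without a cluster-count plateau,
stability alone cannot distinguish the true partition from over-fragmented
ones, whereas modularity at unit resolution is maximised by well-separated
communities.

Cluster-specific peaks use a two-sided Fisher exact test on the per-peak
2x2 detection table (in-cluster vs out), a log2 detection-fraction ratio
with pseudocount `1/n_cells` on both fractions, and Benjamini-Hochberg
correction within cluster; rows are kept at log2 fold change above 0.25 and
adjusted p below 0.05. The Fisher p-value is computed by vectorised
hypergeometric summation and is tested against `fisher.test` to 1e-12.
Genomic-feature annotation of markers (at detection fold change above 2)
classifies with precedence promoter (TSS +/- 2 kb) > exon > intron > distal
intergenic; with single-exon gene models the intron class is structurally
empty.

## Gene activity, gene sets, and fate bias

A gene's regulatory window runs 50 kb upstream to 30 kb downstream of the
gene body, strand-aware and clipped to the chromosome. Gene activity per
cell is the sum of detections (or fragment counts) over peaks overlapping
the window; per-cell normalisation scales to 10^4 and applies `log1p`.
Gene-set scores are means over set genes of per-gene z-scores taken across
group means with the population SD (zero-SD genes score 0).

The fate-bias contrast pseudobulks window fragment counts per cluster,
normalises to counts per million, adds a pseudocount of 1, and reports
`M = log2(a/b)` and `A = (log2 a + log2 b)/2`. A gene is biased when
`|M| > 1` and `A` exceeds its 25th percentile; neither threshold is printed
in the source figure, so both are package defaults exposed as arguments.
`M` is exactly antisymmetric under swapping the clusters.

## GWAS enrichment

The background for variant enrichment is the merged peak universe, not the
genome: SNP catalogs in this setting are pre-filtered to assayable
regulatory space, and a length-ratio null (`p0` = cluster marker length /
universe length) is then exact. The test is the one-sided upper binomial
tail `P(X >= x)` with BH correction across the cluster-by-trait grid. SNPs
in peaks shared by several clusters count for each. Exact binomial tails
are discrete; calibration assessments therefore use catalog sizes at which
the attainable tail probabilities are dense near 0.05 (about 2,000 SNPs per
trait at `p0` near 0.05), and the power assessment plants a 5-fold
enrichment at 200 SNPs per trait.

## Meta-cells and co-accessibility

Cells are aggregated into non-overlapping meta-cells by greedy kNN grouping
on the embedding (default 50 cells per meta-cell; each cell belongs to at
most one). Co-accessibility is estimated within half-overlapping 500 kb
windows per chromosome: meta-cell counts are depth-normalised, residualised
against the meta-cell totals and their squares, standardised, and the
correlation matrix is shrunk towards the identity with the analytic
Schafer-Strimmer intensity before inversion to partial correlations. Each
pair's partial correlation is soft-thresholded by a distance-scaled penalty
(`0.2 * distance/window`), and a pair's score is its mean over covering
windows. Edges at or above 0.1 form networks (connected components with at
least two peaks); both constants are the published defaults of the
distance-penalised co-accessibility family of methods.

Two numerical choices matter here. The totals-residualisation removes a
common depth/FRiP factor: detection probability responds nonlinearly to
per-cell depth, so depth scaling alone leaves correlated residuals between
unrelated peaks. The per-window shrinkage adapts automatically: windows
containing no co-varying peaks shrink essentially to the identity and emit
nothing, while windows holding a genuine module retain it.

A network is cluster-specific when no network from any other cluster's
meta-cell graph shares a peak-set Jaccard index of 0.5 or more with it.

The planted-module recovery benchmark runs on a dedicated configuration:
3,000 cells at depth 4,000, marker effect set to its null value of 1, and
meta-cells of 10 (300 meta-cells). The null marker effect is deliberate:
with cluster marker boosts active, same-cluster markers co-vary across
meta-cells — genuine, cluster-driven co-accessibility — and would be
counted as false positives against the planted-module truth. The pipeline
default `k_agg = 50` is retained for analysis use.

## Motif deviations and TF-target networks

Motif scoring follows the deviation-z design: for motif m and cell c,
`raw = observed/expected - 1`, with `expected` the dataset-wide detection
share of the motif's peaks times the cell's depth. Background sets are
within-bin permutations of peaks matched on accessibility deciles (50
iterations); z-scores standardise raw deviations by the background mean and
SD, and a motif's variability is the SD of its z over cells. A motif
covering every peak has raw deviation identically zero — a useful
saturation identity that the tests assert. Sequence-level motif scanning is
out of scope: the motif-by-peak annotation is an input.

A TF is "crucial" in a cluster when its mean z there is maximal across
clusters and above the 0.9 quantile of all motif-cluster means, and at
least 3 of its database targets are cluster-enriched by gene activity
(Wilcoxon rank-sum in-vs-out with log2FC above 0.25 and BH-adjusted p below
0.05). The two-condition rule is a concrete reading of "specifically
enriched and actively regulating"; both thresholds are arguments. Stage
comparisons label TF-target pairs shared or stage-unique by exact pair
identity.

## Differential abundance

Neighbourhoods are kNN balls around sampled index cells, greedily refined
so no index falls inside an earlier accepted neighbourhood; the kth-NN
distance is kept as a density proxy. Counts per (condition, replicate)
sample are tested with Poisson regression against condition, with log
size-factor offsets; size factors come from median-of-ratios across
neighbourhoods rather than raw totals, so a genuinely shifted subpopulation
does not drag the majority of neighbourhoods away from zero (composition
robustness). Dispersion is pooled across neighbourhoods (each has too few
samples to estimate its own), and p-values use a moderated t reference with
the neighbourhood's residual df plus a prior df of 2: the pooled estimate
does not license the full summed df because dispersions are heterogeneous,
and the heavier tails keep the weighted-BH step-up at permissive FDR
thresholds from flooding null neighbourhoods. With fewer than two
replicates per condition the test falls back to an exact binomial against
the global proportion. The spatial FDR is weighted BH with weights
proportional to the reciprocal kth-NN distance.

The display threshold mirrors the bee-swarm convention of reporting
neighbourhoods at FDR 50%; 0.05 is the sensible choice for inference. The
abundance benchmark uses six clusters of 200 cells, two replicates — the
profiled system's replicate structure — an 80/20 stage-shifted cluster, and
k = 70 neighbourhoods; the test family was calibrated on 200 simulation
seeds (full power, null flag rate about 7-8% at FDR 50%) before the
acceptance checks were frozen.

Stage-differential peaks within clusters reuse the Fisher detection test
between stages with BH within cluster and directional counts at
`|log2FC| > 0.25`, adjusted p below 0.05.

## The synthetic-data generator

The generator emulates the profiled system's data structure with planted
ground truth. Defaults are the study conditions: six clusters of 200 cells
(~1,200 cells total, matching the profiled population's scale), 24
aggregate samples, negative-binomial per-cell depth with mean 7,290 unique
fragments (the deep-coverage average of the motivating dataset) and size 8,
per-cell FRiP drawn from 0.2-0.5, and 10% planted low-quality cells
(deflated depth of 200-1,400, or FRiP of 1-5%, leaving clear margins around
the strict QC gate). The genome is 8 chromosomes of 50 Mb carrying 6,000
non-overlapping peaks of 300-700 bp on a slot grid; background peaks get
Gamma(0.5) sampling weights.

Markers are 120 peaks per cluster: 40 sit in runs of four around ten
"program genes" (common peaks whose in-cluster fragment rate is
`marker_effect`-fold higher; these drive gene-set and fate-bias truth) and
80 are "loose" markers with a low base rate, rare outside their cluster —
the regime in which TF-IDF separates cell types in real binary chromatin
data. The 120-per-cluster default is the source dataset's
cluster-specific-peak fraction (roughly 1.5k of 54k) scaled to the 6k-peak
universe. Stage-differential peaks are drawn from the loose markers with an
extra favoured-stage factor of 1.6 on top of the marker effect, so
program-gene signal stays stage-stable. Co-accessibility modules are runs
of four consecutive peaks within 250 kb driven by a shared per-cell on/off
latent (detection ~0.9 when on, ~0.02 when off); the first half of the
modules is active in all clusters, the second half only in a home cluster.
Trait SNPs are placed over the peak universe with the target cluster's
markers upweighted by `snp_enrichment_fold`; motif annotations plant one
motif per cluster on its markers plus 5% random peaks; the TF-target
database links each planted TF to its cluster's program genes plus noise
edges and decoy TFs. Stage fractions default to 80/20 shifts in the last
two clusters (towards P1 and P10 respectively), mirroring the reparative
and inflammatory fates of the motivating system.

The generator does **not** emulate: sequence content (no FASTQ, no PWM
scanning), copy-number or chromatin-state confounders, doublets, barcode
errors, batch effects between replicates, LD structure among SNPs, or
overlap between marker programs. Passing tests therefore demonstrate the
correctness and calibration of the machinery under the planted model, not
robustness to every artefact of real data.

Truth for the QC gate is bookkept from the realised fragments (the
generator labels each fragment in- or out-of-peak at draw time and records
the post-deduplication counts), so gate exactness is checked against
realised, not merely intended, cell quality.

## Problem sizes and determinism

The test-suite and acceptance problem sizes are: the default ~1,200-cell
bundle for QC, clustering, markers, motifs, and fate bias; 3,000 cells for
co-accessibility; 100 seeded replicates for GWAS power and for abundance
testing; 1,000+ rows for GWAS null calibration; and oracle fixtures of up
to 100 peaks x 200 cells and 30 genes. All randomness flows from a single
integer seed per entry point (bundles are byte-identical given a
configuration; the pipeline writes byte-identical outputs given a seed).

## Known limitations

* The simple coverage-threshold caller is for synthetic aggregates; real
  data should use a dedicated caller upstream of the merge.
* Batch alignment is rigid (translation-only within local neighbourhoods);
  scale or rotation differences between batches are out of scope.
* Co-accessibility scores are correlation-based; they do not imply physical
  enhancer contacts, and CCRN identity (connected components above a score
  threshold) is one of several reasonable definitions.
* The spatial FDR uses the kth-NN-distance weighting approximation, not a
  full neighbourhood-overlap graph correction.
* Gene-activity windows ignore strand-specific enhancer-promoter logic
  beyond the asymmetric window itself.
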