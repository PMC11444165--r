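# enhancermap

Single-cell histone-mark enhancer maps: QC, clustering, and regulatory
network inference for per-cell H3K27ac (CUT&Tag / combinatorial-barcoding
ChIP-seq) profiles.

## The problem

Single-cell profiles of H3K27ac — the chromatin mark of active enhancers —
are near-binary: at a few thousand unique fragments per cell, a peak is
either detected or it is not. Working from that detection signal,
`enhancermap` reconstructs how enhancer usage defines cell states in a
heterogeneous population (the motivating system is cardiac mononuclear
phagocytes in regenerative vs non-regenerative neonatal hearts after
infarction) and asks the downstream questions that make such an atlas
useful:

* which cells are usable (`unique fragments > 1,500`, `FRiP > 10%`), and
  what is the binary peak-by-cell matrix over the merged peak universe;
* what cell populations exist (TF-IDF/LSI embedding, replicate alignment,
  Leiden clustering over a resolution tree) and which enhancer peaks are
  specific to each (`log2FC > 0.25`, BH `p_adj < 0.05`, Fisher exact);
* how active is each gene, scored as enhancer signal in the window from
  50 kb upstream to 30 kb downstream of the gene body;
* do disease-associated GWAS variants concentrate in a cell type's
  enhancers (exact binomial tail against a peak-length null,
  `P(X >= x), X ~ Bin(n_trait, p0)`);
* which enhancers co-vary in cis (distance-bounded partial correlations
  over meta-cells; networks = connected components, with cluster
  specificity by peak-set Jaccard);
* which transcription factors drive each population (motif deviation
  z-scores against accessibility-matched backgrounds; TF-target networks
  requiring both motif enrichment and regulated targets);
* which populations change in abundance between conditions (kNN
  neighbourhoods, quasi-likelihood counts model, spatial FDR), and which
  genes are biased between two alternative fates (pseudobulk MA contrast,
  `M = log2(a/b)`).

Every stage is exercised end to end by a seedable synthetic-data generator
(`generate_dataset()`) that plants ground truth for each question: marker
peaks, motif programs, SNP enrichments, co-accessible modules, stage
shifts, and fate-biased genes.

## A worked example

```r
library(enhancermap)

bundle <- generate_dataset(synth_config(seed = 1))
bundle
#> synthetic_bundle: 1200 cells, 6000 peaks, 300 genes, 1200 SNPs

qc <- compute_cell_qc(bundle$fragments, bundle$peaks_true)
sum(qc$pass); round(mean(qc$unique_reads[qc$pass]))
#> [1] 1080
#> [1] 7172

cm  <- build_binary_matrix(bundle$fragments, bundle$peaks_true, qc,
                           bundle$cell_metadata)
emb <- tfidf_lsi(cm, d = 30)
sel <- select_resolution(cluster_resolution_tree(emb, seed = 0))
table(sel$cluster)
#>   0   1   2   3   4   5
#> 179 177 180 178 183 183

mk <- find_cluster_peaks(cm, sel)
nrow(mk)
#> [1] 746

snps <- snps_in_universe(bundle$snps, bundle$peaks_true)
en <- binomial_enrichment(snps, mk, bundle$peaks_true)
head(en[en$p_adj < 0.05][order(p_adj)], 2)
#>    cluster        trait n_trait     x         p0     fold            p
#> 1:       1 Hypertension     200    26 0.02062103 6.304245 1.392417e-13
#> 2:       2 HeartFailure     200    23 0.02299211 5.001716 3.549683e-10
```

1,080 of 1,200 cells pass the gate (10% low-quality cells are planted), the
six planted populations are recovered at near-equal sizes, ~750
cluster-specific enhancer peaks are called (720 are planted), and the
traits with planted 5-fold variant enrichments top the GWAS table. The
numbers above are what the code prints for seed 1; exact values vary with
the seed.

`run_pipeline(bundle, outdir, seed)` executes the whole chain (including
co-accessibility, motif/TF networks, differential abundance, and fate bias)
and writes TSV tables; outputs are byte-identical for a fixed seed.

A thin command-line wrapper is installed at `inst/exec/enhancermap` with
subcommands `simulate`, `qc`, `pipeline`, and `gwas` for shell use.

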