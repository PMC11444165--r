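#' Run the full enhancer-map pipeline on a bundle
#'
#' Executes the end-to-end analysis on an in-memory bundle (or a directory
#' written by [write_bundle()]): per-sample simple peak calling and merging,
#' per-cell QC and the binary matrix, TF-IDF/LSI embedding with replicate
#' alignment, resolution-tree clustering, cluster-specific marker peaks and
#' genomic-feature annotation, gene activity and gene-set scores, GWAS SNP
#' enrichment, co-accessibility networks with cluster specificity, motif
#' deviations and TF-target networks, stage differential abundance and
#' stage-differential peaks, and the fate-bias MA table for the two most
#' MI-induced clusters. All stochastic steps derive their seeds from
#' `seed`. When `outdir` is given, tables are written as TSV files.
#'
#' @param bundle A `synthetic_bundle` or a directory path for
#'   [read_bundle()].
#' @param outdir Optional output directory for TSV results.
#' @param seed Integer master seed. Default 0.
#' @param d Embedding dimensions. Default 30.
#' @param resolutions Clustering resolution grid.
#' @param k_agg Meta-cell size for co-accessibility. Default 50.
#' @param da_fdr Spatial-FDR display threshold for flagged neighbourhoods.
#'   Default 0.5.
#' @return A list with all intermediate and final results.
#' @export
run_pipeline <- function(bundle, outdir = NULL, seed = 0L, d = 30L,
                         resolutions = seq(0.2, 2, 0.2), k_agg = 50L,
                         da_fdr = 0.5) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  fs <- bundle$fragments
  md <- as.data.table(bundle$cell_metadata)
  chrom_sizes <- fs$chrom_sizes

  ## peak universe from per-sample aggregates
  groups <- setNames(md$sample_id, md$barcode)
  called <- suppressWarnings(call_peaks_simple(fs, groups,
                                               min_coverage = 5L,
                                               min_width = 200L))
  universe <- merge_peak_sets(called)

  qc <- compute_cell_qc(fs, universe)
  cm <- build_binary_matrix(fs, universe, qc, metadata = md)

  emb <- tfidf_lsi(cm, d = d)
  if (length(unique(cm$metadata$replicate)) > 1L)
    emb <- align_batches(emb, cm$metadata$replicate, seed = seed + 1L)

  tree <- cluster_resolution_tree(emb, resolutions = resolutions,
                                  seed = seed + 2L)
  clusters <- suppressWarnings(select_resolution(tree))
  markers <- suppressWarnings(find_cluster_peaks(cm, clusters))
  features <- annotate_peak_features(universe, markers, bundle$genes)

  activity <- compute_gene_activity(cm, bundle$genes, chrom_sizes,
                                    mode = "binary-sum")
  lab <- as.character(clusters$cluster[colnames(cm$binary)])
  set_scores <- if (length(bundle$gene_sets))
    suppressWarnings(score_gene_sets(activity, lab, bundle$gene_sets))
  else NULL

  snps_u <- snps_in_universe(bundle$snps, universe)
  gwas <- if (nrow(markers)) binomial_enrichment(snps_u, markers, universe)
  else NULL

  meta_all <- aggregate_metacells(cm, emb, k_agg = k_agg, seed = seed + 3L)
  edges <- coaccessibility_scores(meta_all)
  ccrns <- build_ccrns(edges, universe)
  gene_counts <- gene_ccrn_counts(ccrns, bundle$genes, universe, chrom_sizes)

  dev <- motif_deviations(cm, remap_motifs(bundle$motif_annotation, universe,
                                           bundle$peaks_true),
                          seed = seed + 4L)
  var_tab <- variable_motifs(dev, top_n = nrow(dev$z))
  tftg <- build_tf_tg_network(dev, lab, activity, bundle$tftg_db)

  stage <- setNames(cm$metadata$stage, cm$metadata$barcode)
  repl <- setNames(cm$metadata$replicate, cm$metadata$barcode)
  nbhd <- make_neighborhoods(emb, seed = seed + 5L)
  da <- test_neighborhoods(nbhd, stage[colnames(cm$binary)],
                           repl[colnames(cm$binary)],
                           clusters = setNames(lab, colnames(cm$binary)))
  sd_peaks <- stage_differential_peaks(cm, clusters, stage)

  ## fate-bias MA between the two largest MI-shifted clusters if known,
  ## else the two largest clusters
  cl_sizes <- sort(table(lab), decreasing = TRUE)
  pair <- names(cl_sizes)[seq_len(min(2L, length(cl_sizes)))]
  fate <- if (length(pair) == 2L)
    fate_bias_ma(fs, setNames(lab, colnames(cm$binary)), pair[1L], pair[2L],
                 bundle$genes)
  else NULL

  res <- list(universe = universe, qc = qc, matrix = cm, embedding = emb,
              tree = tree, clusters = clusters, markers = markers,
              features = features, activity = activity,
              set_scores = set_scores, gwas = gwas, ccrn_edges = edges,
              ccrns = ccrns, gene_ccrn = gene_counts, deviations = dev,
              variable_motifs = var_tab, tftg = tftg, da = da,
              stage_peaks = sd_peaks, fate = fate)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir, da_fdr)
  res
}

## motif annotation is defined on the true peak universe; carry each motif's
## membership onto the called universe by peak overlap
remap_motifs <- function(motifs, universe, peaks_true) {
  hits <- GenomicRanges::findOverlaps(peaks_true, universe, minoverlap = 1L)
  map <- sparseMatrix(i = S4Vectors::queryHits(hits),
                      j = S4Vectors::subjectHits(hits), x = 1,
                      dims = c(length(peaks_true), length(universe)))
  out <- motifs %*% map
  out@x <- rep(1, length(out@x))
  dimnames(out) <- list(rownames(motifs), names(universe))
  out
}

write_pipeline_outputs <- function(res, outdir, da_fdr = 0.5) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  fwrite(res$qc, p("qc.tsv"), sep = "\t")
  fwrite(peaks_bed(res$universe), p("universe.bed"), sep = "\t")
  emb_tab <- data.table(barcode = rownames(res$embedding$coords),
                        res$embedding$coords)
  fwrite(emb_tab, p("embedding.tsv"), sep = "\t")
  fwrite(data.table(barcode = names(res$clusters$cluster),
                    cluster = res$clusters$cluster),
         p("clusters.tsv"), sep = "\t")
  fwrite(res$markers, p("markers.tsv"), sep = "\t")
  fwrite(res$features$peaks, p("peak_features.tsv"), sep = "\t")
  if (!is.null(res$set_scores))
    fwrite(res$set_scores, p("gene_set_scores.tsv"), sep = "\t")
  if (!is.null(res$gwas)) fwrite(res$gwas, p("gwas.tsv"), sep = "\t")
  fwrite(res$ccrn_edges, p("ccrn_edges.tsv"), sep = "\t")
  fwrite(res$ccrns$edges, p("ccrn_networks.tsv"), sep = "\t")
  fwrite(res$gene_ccrn, p("gene_ccrn_counts.tsv"), sep = "\t")
  fwrite(res$variable_motifs, p("motif_variability.tsv"), sep = "\t")
  fwrite(res$tftg$edges, p("tftg_edges.tsv"), sep = "\t")
  da <- data.table::copy(res$da)
  da[, flagged := spatial_fdr < da_fdr]
  fwrite(da, p("diff_abundance.tsv"), sep = "\t")
  fwrite(res$stage_peaks$peaks, p("stage_diff_peaks.tsv"), sep = "\t")
  if (!is.null(res$fate)) fwrite(res$fate, p("fate_bias.tsv"), sep = "\t")
  invisible(outdir)
}
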