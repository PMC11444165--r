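#' Strand-aware gene window
#'
#' The enhancer-signal window of a gene runs from `up` bp upstream (5' side)
#' of the gene body to `down` bp downstream (3' side), clipped to the
#' chromosome. Defaults follow the -50 kb / +30 kb convention used for
#' enhancer-based gene-activity proxies.
#'
#' @param genes A [gene_model()] (or one row of it).
#' @param up Upstream extension (bp). Default 50000.
#' @param down Downstream extension (bp). Default 30000.
#' @param chrom_sizes Named chromosome sizes for clipping.
#' @return data.table with gene_id, chrom, start, end (0-based half-open).
#' @export
gene_window <- function(genes, up = 50000L, down = 30000L, chrom_sizes) {
  g <- as.data.table(genes)
  plus <- g$strand == "+"
  w_start <- ifelse(plus, g$start - up, g$start - down)
  w_end <- ifelse(plus, g$end + down, g$end + up)
  sz <- as.numeric(chrom_sizes[g$chrom])
  if (anyNA(sz)) stop2("gene chromosome missing from chrom_sizes")
  data.table(gene_id = g$gene_id, chrom = g$chrom,
             start = as.integer(pmax(w_start, 0)),
             end = as.integer(pmin(w_end, sz)))
}

## sparse gene x peak indicator: peak overlaps (>=1 bp) the gene window
gene_peak_overlap <- function(genes, peaks, chrom_sizes, up = 50000L,
                              down = 30000L) {
  win <- gene_window(genes, up, down, chrom_sizes)
  wgr <- GenomicRanges::GRanges(win$chrom,
                                IRanges::IRanges(win$start + 1L, win$end))
  hits <- GenomicRanges::findOverlaps(wgr, peaks, minoverlap = 1L)
  sparseMatrix(i = S4Vectors::queryHits(hits),
               j = S4Vectors::subjectHits(hits), x = 1,
               dims = c(nrow(win), length(peaks)),
               dimnames = list(win$gene_id, names(peaks)))
}

#' Gene-activity proxies from enhancer signal in gene windows
#'
#' Per cell, a gene's score is the sum over peaks overlapping its
#' -`up`/+`down` window of either the binary detections (`binary-sum`) or
#' the per-cell fragment counts in those peaks (`fragment-count`). With
#' `normalize = TRUE` each cell is scaled to a total of 1e4 and `log1p`
#' transformed.
#'
#' @param cm A `cell_matrix`.
#' @param genes A [gene_model()].
#' @param chrom_sizes Named chromosome sizes.
#' @param mode `"binary-sum"` or `"fragment-count"`.
#' @param normalize Depth-normalise per cell to 1e4 and log1p.
#' @param up,down Window extensions (bp).
#' @return List of class `gene_activity`: `scores` (genes x cells),
#'   `mode`, `normalized`.
#' @export
compute_gene_activity <- function(cm, genes, chrom_sizes,
                                  mode = c("binary-sum", "fragment-count"),
                                  normalize = TRUE,
                                  up = 50000L, down = 30000L) {
  mode <- match.arg(mode)
  A <- gene_peak_overlap(genes, cm$peaks, chrom_sizes, up, down)
  X <- if (mode == "binary-sum") cm$binary else cm$counts
  GA <- as(A %*% X, "CsparseMatrix")
  if (normalize) {
    tot <- colSums(X)
    tot[tot == 0] <- 1
    GA <- GA %*% Diagonal(x = 1e4 / tot)
    GA@x <- log1p(GA@x)
  }
  structure(list(scores = GA, mode = mode, normalized = normalize),
            class = "gene_activity")
}

#' Gene-set enhancer scores per group
#'
#' Per gene, computes group means of activity, z-scores them across groups
#' (sample SD over groups; a zero-SD gene scores 0 in every group), and
#' averages the z-scores over the genes of each set.
#'
#' @param activity A `gene_activity`.
#' @param groups Group label per cell (cluster, or cluster x stage).
#' @param sets Named list of gene-id vectors.
#' @return data.table with columns group, gene_set, score, mean_detected
#'   (mean fraction of the set's genes with nonzero activity in the group).
#' @export
score_gene_sets <- function(activity, groups, sets) {
  GA <- activity$scores
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(GA))
  glev <- sort(unique(groups))
  ## gene x group mean matrices (robust to single-gene inputs)
  M <- do.call(cbind, lapply(glev, function(g)
    rowMeans(GA[, groups == g, drop = FALSE])))
  D <- do.call(cbind, lapply(glev, function(g)
    rowMeans(GA[, groups == g, drop = FALSE] > 0)))
  colnames(M) <- colnames(D) <- glev
  mu <- rowMeans(M)
  sdev <- sqrt(rowSums((M - mu)^2) / max(ncol(M) - 1L, 1L))
  Z <- (M - mu) / ifelse(sdev > 0, sdev, Inf)   # zero-SD genes -> 0
  out <- list()
  for (s in names(sets)) {
    genes_s <- intersect(sets[[s]], rownames(GA))
    if (!length(genes_s)) stop2("gene set '", s, "' matches no genes")
    if (length(genes_s) < length(sets[[s]]))
      warning("gene set '", s, "': ",
              length(sets[[s]]) - length(genes_s), " genes not found, dropped")
    out[[s]] <- data.table(group = glev, gene_set = s,
                           score = colMeans(Z[genes_s, , drop = FALSE]),
                           mean_detected = colMeans(D[genes_s, , drop = FALSE]))
  }
  rbindlist(out)
}

#' MA-style fate-bias analysis between two clusters
#'
#' Pseudobulks per-gene window fragment counts for each cluster, normalises
#' to counts per million, adds a pseudocount of 1, and reports
#' `M = log2(a/b)` and `A = (log2 a + log2 b) / 2`. A gene is called biased
#' towards a cluster when `|M| > m_min` and `A` exceeds the `a_min` quantile
#' of all A values.
#'
#' @param fragments A [fragment_set()].
#' @param clusters Named cluster labels (barcode -> cluster) or a
#'   `cluster_assignment`.
#' @param cluster_a,cluster_b The two cluster labels to compare.
#' @param genes A [gene_model()].
#' @param m_min Minimum |M|. Default 1.
#' @param a_min Quantile of A below which genes are never called.
#'   Default 0.25.
#' @param up,down Window extensions (bp).
#' @return data.table with gene_id, A, M, biased_to (`cluster_a`,
#'   `cluster_b`, or "none").
#' @export
fate_bias_ma <- function(fragments, clusters, cluster_a, cluster_b, genes,
                         m_min = 1.0, a_min = 0.25,
                         up = 50000L, down = 30000L) {
  lab <- if (is(clusters, "cluster_assignment")) clusters$cluster else clusters
  lab <- setNames(as.character(lab), names(lab))
  win <- gene_window(genes, up, down, fragments$chrom_sizes)
  wgr <- GenomicRanges::GRanges(win$chrom,
                                IRanges::IRanges(win$start + 1L, win$end))
  pseudo_counts <- function(cl) {
    bcs <- names(lab)[lab == cl]
    fr <- fragments$fragments[fragments$fragments$barcode %in% bcs]
    if (!nrow(fr)) stop2("cluster ", cl, " has zero fragments")
    gr <- GenomicRanges::GRanges(fr$chrom,
                                 IRanges::IRanges(fr$start + 1L, fr$end))
    hits <- GenomicRanges::findOverlaps(gr, wgr, minoverlap = 1L)
    cnt <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(win))
    list(counts = cnt, depth = nrow(fr))
  }
  a <- pseudo_counts(cluster_a)
  b <- pseudo_counts(cluster_b)
  cpm_a <- a$counts / a$depth * 1e6 + 1
  cpm_b <- b$counts / b$depth * 1e6 + 1
  M <- log2(cpm_a / cpm_b)
  A <- (log2(cpm_a) + log2(cpm_b)) / 2
  a_floor <- quantile(A, a_min)
  biased <- ifelse(abs(M) > m_min & A > a_floor,
                   ifelse(M > 0, as.character(cluster_a),
                          as.character(cluster_b)), "none")
  data.table(gene_id = win$gene_id, A = A, M = M, biased_to = biased)
}
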