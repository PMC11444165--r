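## shared-nearest-neighbour graph from an embedding
snn_graph <- function(coords, k_nn = 20L, prune = 1 / 15) {
  n <- nrow(coords)
  if (k_nn >= n) stop2("k_nn must be smaller than the number of cells")
  D <- as.matrix(dist(coords))
  nn <- t(apply(D, 1L, function(r) order(r)[seq_len(k_nn + 1L)]))
  ## includes self; keep it, as in standard SNN constructions
  A <- sparseMatrix(i = rep(seq_len(n), each = k_nn + 1L),
                    j = as.integer(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  jac <- shared
  jac@x <- jac@x / (2 * (k_nn + 1L) - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- rownames(coords)
  g
}

#' Cluster cells across a resolution grid and build the cluster tree
#'
#' Builds a shared-nearest-neighbour graph on the embedding and runs Leiden
#' community detection (modularity objective, fixed seed) at each resolution
#' of an ascending grid. Consecutive labelings are linked by child-parent
#' cell-overlap weights; the stability of a resolution is the mean, over its
#' clusters, of the largest fraction of a cluster's cells staying together
#' at the next resolution. The sweep enforces weakly non-decreasing cluster
#' counts by carrying a labeling forward when a higher resolution would
#' produce fewer communities.
#'
#' @param embedding An `embedding`.
#' @param resolutions Ascending numeric grid. Default `seq(0.2, 2, 0.2)`.
#' @param k_nn Neighbours for the SNN graph. Default 20.
#' @param seed Seed for community detection. Default 0.
#' @return A list of class `cluster_tree`: per-resolution `memberships`
#'   (0-based integer labels), `n_clusters`, `stability`, `overlap`
#'   (row-normalised child-by-parent overlap matrices), `resolutions`.
#' @export
cluster_resolution_tree <- function(embedding, resolutions = seq(0.2, 2, 0.2),
                                    k_nn = 20L, seed = 0L) {
  stopifnot(is(embedding, "embedding"))
  if (!length(resolutions)) stop2("resolution grid is empty")
  if (is.unsorted(resolutions)) stop2("resolutions must be ascending")
  g <- snn_graph(embedding$coords, k_nn = k_nn)
  memberships <- list()
  for (i in seq_along(resolutions)) {
    cl <- local_seed(seed, igraph::cluster_leiden(
      g, objective_function = "modularity",
      resolution = resolutions[i], weights = igraph::E(g)$weight,
      n_iterations = 5L))
    mem <- igraph::membership(cl)
    mem <- as.integer(factor(mem, levels = unique(mem))) - 1L
    if (i > 1L && length(unique(mem)) < length(unique(memberships[[i - 1L]]))) {
      mem <- memberships[[i - 1L]]   # enforce weak monotonicity of the sweep
    }
    memberships[[i]] <- mem
  }
  m <- length(resolutions)
  stability <- numeric(m)
  modularity <- numeric(m)
  overlap <- vector("list", m)
  for (i in seq_len(m)) {
    modularity[i] <- igraph::modularity(g, memberships[[i]] + 1L,
                                        weights = igraph::E(g)$weight)
    if (i == m) {
      ## no child labeling to compare against: inherit the previous value
      stability[i] <- if (m > 1L) stability[m - 1L] else 1
      overlap[[i]] <- NULL
      next
    }
    tab <- table(parent = memberships[[i]], child = memberships[[i + 1L]])
    frac <- tab / rowSums(tab)
    stability[i] <- mean(apply(frac, 1L, max))
    overlap[[i]] <- prop.table(t(tab), margin = 1L)  # child x parent rows

  }
  structure(list(memberships = memberships,
                 n_clusters = vapply(memberships, function(x)
                   length(unique(x)), integer(1)),
                 stability = stability,
                 modularity = modularity,
                 overlap = overlap,
                 resolutions = resolutions,
                 barcodes = rownames(embedding$coords)),
            class = "cluster_tree")
}

#' Select a clustering resolution from the cluster tree
#'
#' Picks the lowest resolution whose stability is at least `min_stability`
#' and whose cluster count is unchanged at the next grid point; ties go to
#' the lower resolution. Trivial single-cluster partitions are excluded
#' unless every resolution yields one (they are perfectly stable by
#' construction and carry no information). If no resolution qualifies, the
#' resolution maximising the unscaled graph modularity of its partition is
#' returned with a warning; modularity rather than raw stability is used as
#' the fallback because stability alone does not separate the true
#' partition from over-fragmented ones when the sweep has no cluster-count
#' plateau.
#'
#' @param tree A `cluster_tree`.
#' @param min_stability Stability threshold. Default 0.9.
#' @return A list of class `cluster_assignment`: `cluster` (0-based integer
#'   labels named by barcode), `resolution`, `sizes`.
#' @export
select_resolution <- function(tree, min_stability = 0.9) {
  stopifnot(is(tree, "cluster_tree"))
  m <- length(tree$resolutions)
  nontrivial <- tree$n_clusters > 1L
  if (!any(nontrivial)) nontrivial <- rep(TRUE, m)
  count_stable <- c(tree$n_clusters[-m] == tree$n_clusters[-1L], TRUE)
  ok <- nontrivial & count_stable & tree$stability >= min_stability
  if (any(ok)) {
    i <- which(ok)[1L]
  } else {
    i <- which(nontrivial)[which.max(tree$modularity[nontrivial])]
    warning("no resolution reached stability ", min_stability,
            "; returning the maximum-modularity resolution")
  }
  mem <- tree$memberships[[i]]
  names(mem) <- tree$barcodes
  structure(list(cluster = mem, resolution = tree$resolutions[i],
                 sizes = table(mem)),
            class = "cluster_assignment")
}

#' Cluster-specific enhancer peaks by binary-detection Fisher test
#'
#' For each cluster and peak, compares detection fractions inside vs outside
#' the cluster with a two-sided Fisher exact test, computes the log2
#' detection-fraction ratio (pseudocount 1/n_cells on both fractions), and
#' applies Benjamini-Hochberg correction within cluster. Rows are retained
#' when `log2fc > log2fc_min` and `p_adj < padj_max`.
#'
#' @param cm A `cell_matrix`.
#' @param clusters A `cluster_assignment` or a label vector aligned with the
#'   matrix columns.
#' @param log2fc_min Log2 fold-change threshold. Default 0.25.
#' @param padj_max Adjusted-p threshold. Default 0.05.
#' @param min_cluster_size Clusters smaller than this are skipped with a
#'   warning. Default 3.
#' @return data.table of class `marker_peak_table` with columns cluster,
#'   peak_id, log2fc, p, p_adj, frac_in, frac_out (retained rows only).
#' @export
find_cluster_peaks <- function(cm, clusters, log2fc_min = 0.25,
                               padj_max = 0.05, min_cluster_size = 3L) {
  X <- cm$binary
  lab <- cluster_labels(clusters, colnames(X))
  if (length(unique(lab)) < 2L) stop2("need at least two clusters")
  n <- ncol(X)
  pseudo <- 1 / n
  tot <- rowSums(X)
  out <- list()
  for (cl in sort(unique(lab))) {
    idx <- which(lab == cl)
    n_in <- length(idx); n_out <- n - n_in
    if (n_in < min_cluster_size) {
      warning("cluster ", cl, " has fewer than ", min_cluster_size,
              " cells; skipped")
      next
    }
    k_in <- rowSums(X[, idx, drop = FALSE])
    k_out <- tot - k_in
    l2fc <- log2_frac_ratio(k_in, n_in, k_out, n_out, pseudo)
    p <- fisher_p_two_sided(as.integer(k_in), n_in, as.integer(k_out), n_out)
    p_adj <- p.adjust(p, method = "BH")
    keep <- which(l2fc > log2fc_min & p_adj < padj_max)
    if (length(keep))
      out[[as.character(cl)]] <- data.table(
        cluster = cl, peak_id = rownames(X)[keep],
        log2fc = l2fc[keep], p = p[keep], p_adj = p_adj[keep],
        frac_in = (k_in / n_in)[keep], frac_out = (k_out / n_out)[keep])
  }
  res <- if (length(out)) rbindlist(out) else
    data.table(cluster = character(0), peak_id = character(0),
               log2fc = numeric(0), p = numeric(0), p_adj = numeric(0),
               frac_in = numeric(0), frac_out = numeric(0))
  setattr(res, "class", c("marker_peak_table", class(res)))
  res[]
}

## accept either a cluster_assignment or a plain label vector
cluster_labels <- function(clusters, barcodes) {
  if (is(clusters, "cluster_assignment")) {
    lab <- clusters$cluster[barcodes]
    if (anyNA(lab)) stop2("cluster assignment does not cover all cells")
    as.character(lab)
  } else {
    stopifnot(length(clusters) == length(barcodes))
    lab <- as.character(clusters)
    if (!is.null(names(lab))) lab <- lab[barcodes]
    lab
  }
}

#' Genomic-feature annotation of cluster-specific peaks
#'
#' Classifies each retained marker peak (detection-fraction fold change
#' above `fc_min`) by precedence promoter (TSS +/- `promoter_bp`) >
#' exon overlap > intron (gene body outside exons) > distal intergenic,
#' and reports per-cluster class fractions.
#'
#' @param peaks Peak `GRanges` (the universe carrying the marker ids).
#' @param markers A `marker_peak_table`.
#' @param genes A [gene_model()]; may carry a list column `exons` of
#'   data.frames (start, end); absent exon structure treats the gene body
#'   as a single exon.
#' @param fc_min Detection fold-change threshold (frac_in/frac_out).
#'   Default 2.
#' @param promoter_bp Promoter half-width around the TSS. Default 2000.
#' @return List with `peaks` (per-peak class table) and `fractions`
#'   (cluster x class fractions, rows summing to 1).
#' @export
annotate_peak_features <- function(peaks, markers, genes, fc_min = 2,
                                   promoter_bp = 2000L) {
  if (any(!genes$strand %in% c("+", "-"))) stop2("gene strand required")
  mk <- markers[markers$frac_in / pmax(markers$frac_out, 1e-12) > fc_min]
  if (!nrow(mk))
    return(list(peaks = data.table(cluster = character(0),
                                   peak_id = character(0),
                                   feature = character(0)),
                fractions = NULL))
  pk <- peaks[mk$peak_id]
  tss0 <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  prom <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(
    pmax(tss0 - promoter_bp, 0L) + 1L, tss0 + promoter_bp))
  body <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L, genes$end))
  exons <- if ("exons" %in% names(genes)) {
    ex <- rbindlist(lapply(seq_len(nrow(genes)), function(i) {
      e <- genes$exons[[i]]
      if (is.null(e)) data.table(chrom = genes$chrom[i],
                                 start = genes$start[i], end = genes$end[i])
      else data.table(chrom = genes$chrom[i], start = e$start, end = e$end)
    }))
    GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end))
  } else body
  ov <- function(target) {
    S4Vectors::queryHits(GenomicRanges::findOverlaps(pk, target,
                                                     minoverlap = 1L))
  }
  feature <- rep("distal_intergenic", length(pk))
  feature[ov(body)] <- "intron"
  feature[ov(exons)] <- "exon"
  feature[ov(prom)] <- "promoter"
  tab <- data.table(cluster = mk$cluster, peak_id = mk$peak_id,
                    feature = feature)
  frac <- as.data.frame.matrix(
    prop.table(table(tab$cluster, tab$feature), margin = 1L))
  list(peaks = tab, fractions = frac)
}
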