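#' Aggregate cells into non-overlapping meta-cells by greedy kNN grouping
#'
#' Repeatedly seeds an unassigned cell (seeded random order) and groups it
#' with its `k_agg - 1` nearest unassigned neighbours in the embedding;
#' meta-cell counts are the sums of the binary detections over members.
#'
#' @param cm A `cell_matrix`.
#' @param embedding An `embedding` covering the matrix cells.
#' @param k_agg Cells per meta-cell. Default 50.
#' @param cells Optional barcode subset (e.g. one cluster).
#' @param seed Seed for the grouping order. Default 0.
#' @return List of class `metacell_matrix`: `counts` (peaks x meta-cells),
#'   `members` (list of barcode vectors), `peaks`, `subset`.
#' @export
aggregate_metacells <- function(cm, embedding, k_agg = 50L, cells = NULL,
                                seed = 0L) {
  bcs <- colnames(cm$binary)
  if (!is.null(cells)) bcs <- intersect(bcs, cells)
  if (!length(bcs)) stop2("no cells selected")
  E <- embedding$coords[bcs, , drop = FALSE]
  n <- length(bcs)
  if (n < k_agg) {
    warning("subset smaller than k_agg; returning a single meta-cell")
    groups <- list(seq_len(n))
  } else {
    D <- as.matrix(dist(E))
    diag(D) <- 0
    unassigned <- rep(TRUE, n)
    order_seed <- local_seed(seed, sample.int(n))
    groups <- list()
    for (s in order_seed) {
      if (!unassigned[s]) next
      cand <- which(unassigned)
      if (length(cand) < k_agg) break
      nb <- cand[order(D[s, cand])][seq_len(k_agg)]
      unassigned[nb] <- FALSE
      groups[[length(groups) + 1L]] <- nb
    }
    rest <- which(unassigned)           # fewer than k_agg left over
    if (length(rest) && length(groups))
      groups[[length(groups)]] <- c(groups[[length(groups)]], rest)
    else if (length(rest)) groups <- list(rest)
  }
  counts <- vapply(groups, function(g)
    rowSums(cm$binary[, bcs[g], drop = FALSE]), numeric(nrow(cm$binary)))
  colnames(counts) <- paste0("meta", seq_along(groups))
  structure(list(counts = counts,
                 members = lapply(groups, function(g) bcs[g]),
                 peaks = cm$peaks,
                 subset = if (is.null(cells)) "all" else "subset"),
            class = "metacell_matrix")
}

## Schafer-Strimmer shrinkage intensity for a correlation matrix
## (columns of Y standardised; returns lambda in [0, 1])
shrinkage_intensity <- function(Ys, R) {
  m <- nrow(Ys)
  if (m < 3L) return(1)
  ## var-hat of r_ij via the empirical variance of the products
  W1 <- crossprod(Ys) / m                       # mean of products
  W2 <- crossprod(Ys^2) / m                     # mean of squared products
  var_r <- (m^2 / (m - 1)^3) * (W2 - W1^2)
  off <- upper.tri(R)
  denom <- sum(R[off]^2)
  if (denom <= 0) return(1)
  min(1, max(0, sum(var_r[off]) / denom))
}

#' Distance-bounded co-accessibility scores from meta-cell counts
#'
#' Slides half-overlapping genomic windows of width `window_bp` along each
#' chromosome. Within a window, meta-cell counts are depth-normalised and
#' standardised, the correlation matrix is regularised by analytic
#' (Schafer-Strimmer) shrinkage towards the identity, inverted to partial
#' correlations, and each pair's partial correlation is soft-thresholded by
#' a distance-scaled penalty `penalty_scale * distance / window_bp`. A
#' pair's score is the mean over the windows containing it; only pairs at
#' distance <= `window_bp` are emitted, in canonical order (peak_i before
#' peak_j by coordinate).
#'
#' @param meta A `metacell_matrix` with at least `min_metacells` columns.
#' @param window_bp Sliding-window width / distance bound (bp).
#'   Default 500000.
#' @param penalty_scale Distance-penalty scale. Default 0.2.
#' @param min_metacells Minimum meta-cells required. Default 10.
#' @return data.table with peak_i, peak_j, distance, score.
#' @export
coaccessibility_scores <- function(meta, window_bp = 500000,
                                   penalty_scale = 0.2,
                                   min_metacells = 10L) {
  Y0 <- meta$counts
  if (ncol(Y0) < min_metacells)
    stop2("need at least ", min_metacells, " meta-cells")
  ## depth-normalise meta-cells to the mean total, then residualise each
  ## peak against the totals: detection responds nonlinearly to depth, so
  ## scaling alone leaves a common depth factor that would induce spurious
  ## co-accessibility between unrelated peaks
  tot <- colSums(Y0)
  tot[tot == 0] <- 1
  Y0 <- Y0 %*% diag(mean(tot) / tot)
  zt <- scale(cbind(tot, tot^2))
  qrz <- qr(cbind(1, zt))
  Y0 <- t(qr.resid(qrz, t(Y0)))
  pk <- peaks_bed(meta$peaks)
  pk[, mid := (start + end) / 2]
  pk[, idx := seq_len(.N)]
  parts <- list()
  for (ch in unique(pk$chrom)) {
    sub <- pk[chrom == ch]
    if (nrow(sub) < 2L) next
    lo <- min(sub$mid); hi <- max(sub$mid)
    starts <- seq(lo - window_bp / 2, hi, by = window_bp / 2)
    for (ws in starts) {
      inw <- sub[mid >= ws & mid < ws + window_bp]
      if (nrow(inw) < 2L) next
      Y <- t(Y0[inw$idx, , drop = FALSE])
      sds <- apply(Y, 2L, sd)
      ok <- sds > 0
      if (sum(ok) < 2L) next
      Y <- Y[, ok, drop = FALSE]
      iw <- inw$idx[ok]; mids <- inw$mid[ok]
      m <- nrow(Y)
      Ys <- scale(Y) * sqrt(m / (m - 1))     # population-SD standardisation
      R <- crossprod(Ys) / m
      lam <- shrinkage_intensity(Ys, R)
      Rs <- (1 - lam) * R
      diag(Rs) <- 1
      Theta <- NULL
      ridge <- 0
      repeat {
        Theta <- tryCatch(solve(Rs + diag(ridge, nrow(Rs))),
                          error = function(e) NULL)
        if (!is.null(Theta)) break
        ridge <- if (ridge == 0) 0.01 else ridge * 10
        warning("singular covariance in window; ridge raised to ", ridge)
        if (ridge > 10) stop2("covariance irreparably singular")
      }
      dth <- sqrt(diag(Theta))
      P <- -Theta / tcrossprod(dth)
      ut <- which(upper.tri(P), arr.ind = TRUE)
      d_ij <- abs(mids[ut[, 2L]] - mids[ut[, 1L]])
      keep <- d_ij <= window_bp
      if (!any(keep)) next
      pc <- P[ut][keep]
      pen <- penalty_scale * d_ij[keep] / window_bp
      sc <- sign(pc) * pmax(0, abs(pc) - pen)
      parts[[length(parts) + 1L]] <- data.table(
        i = iw[ut[keep, 1L]], j = iw[ut[keep, 2L]], s = sc)
    }
  }
  if (!length(parts))
    return(data.table(peak_i = character(0), peak_j = character(0),
                      distance = numeric(0), score = numeric(0)))
  ed <- rbindlist(parts)[, .(score = mean(s)), by = .(i, j)]
  ed[, distance := abs(pk$mid[j] - pk$mid[i])]
  ed <- ed[distance <= window_bp]
  res <- data.table(peak_i = pk$peak_id[ed$i], peak_j = pk$peak_id[ed$j],
                    distance = ed$distance, score = ed$score)
  setorder(res, peak_i, peak_j)
  res[]
}

#' Build cis-correlation networks from scored edges
#'
#' Keeps edges with score at or above `threshold` and reports connected
#' components with at least two peaks; component ids are assigned in order
#' of the smallest member-peak coordinate.
#'
#' @param edges Output of [coaccessibility_scores()].
#' @param peaks Peak `GRanges` (for deterministic component ordering).
#' @param threshold Minimum co-accessibility score. Default 0.1.
#' @return List of class `ccrn_graph`: `networks` (named list of peak-id
#'   vectors), `edges` (retained edges with network ids).
#' @export
build_ccrns <- function(edges, peaks, threshold = 0.1) {
  keep <- edges[edges$score >= threshold]
  if (!nrow(keep))
    return(structure(list(networks = list(),
                          edges = cbind(keep, network = character(0))),
                     class = "ccrn_graph"))
  g <- igraph::graph_from_data_frame(
    keep[, .(peak_i, peak_j)], directed = FALSE)
  comp <- igraph::components(g)
  pkstart <- setNames(GenomicRanges::start(peaks), names(peaks))
  pkchrom <- setNames(as.character(GenomicRanges::seqnames(peaks)),
                      names(peaks))
  nets <- split(names(comp$membership), comp$membership)
  nets <- nets[vapply(nets, length, integer(1)) >= 2L]
  ord <- order(vapply(nets, function(p) min(pkstart[p]), numeric(1)))
  ord <- ord[order(vapply(nets[ord], function(p) pkchrom[p][1L], character(1)),
                   vapply(nets[ord], function(p) min(pkstart[p]), numeric(1)))]
  nets <- nets[ord]
  names(nets) <- sprintf("CCRN_%05d", seq_along(nets))
  memb <- setNames(rep(names(nets), vapply(nets, length, integer(1))),
                   unlist(nets))
  keep[, network := memb[peak_i]]
  structure(list(networks = nets, edges = keep[]), class = "ccrn_graph")
}

#' Cluster specificity of CCRNs
#'
#' A network found in one cluster is specific when no network of any other
#' cluster shares a peak-set Jaccard index of at least `jaccard_max` with
#' it; otherwise it is shared.
#'
#' @param per_cluster_graphs Named list mapping cluster to `ccrn_graph`
#'   built on that cluster's meta-cells.
#' @param jaccard_max Jaccard threshold for calling two networks the same.
#'   Default 0.5.
#' @return data.table with columns cluster, network, n_peaks, specific.
#' @export
ccrn_specificity <- function(per_cluster_graphs, jaccard_max = 0.5) {
  rows <- list()
  for (cl in names(per_cluster_graphs)) {
    nets <- per_cluster_graphs[[cl]]$networks
    others <- unlist(lapply(
      per_cluster_graphs[setdiff(names(per_cluster_graphs), cl)],
      function(g) g$networks), recursive = FALSE)
    for (nm in names(nets)) {
      p <- nets[[nm]]
      jmax <- 0
      for (q in others) {
        j <- length(intersect(p, q)) / length(union(p, q))
        if (j > jmax) jmax <- j
      }
      rows[[length(rows) + 1L]] <- data.table(
        cluster = cl, network = nm, n_peaks = length(p),
        specific = jmax < jaccard_max)
    }
  }
  if (!length(rows))
    return(data.table(cluster = character(0), network = character(0),
                      n_peaks = integer(0), specific = logical(0)))
  rbindlist(rows)
}

#' Number of CCRNs represented near each gene
#'
#' Counts, per gene, the networks containing at least one peak overlapping
#' the gene's -`up`/+`down` window.
#'
#' @param graph A `ccrn_graph`.
#' @param genes A [gene_model()].
#' @param peaks Peak `GRanges`.
#' @param chrom_sizes Named chromosome sizes.
#' @param up,down Window extensions (bp).
#' @return data.table with gene_id and n_networks.
#' @export
gene_ccrn_counts <- function(graph, genes, peaks, chrom_sizes,
                             up = 50000L, down = 30000L) {
  A <- gene_peak_overlap(genes, peaks, chrom_sizes, up, down)
  n_net <- integer(nrow(A))
  for (nm in names(graph$networks)) {
    idx <- match(graph$networks[[nm]], colnames(A))
    idx <- idx[!is.na(idx)]
    if (!length(idx)) next
    hit <- rowSums(A[, idx, drop = FALSE]) > 0
    n_net <- n_net + as.integer(hit)
  }
  data.table(gene_id = rownames(A), n_networks = n_net)
}
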