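#' Per-cell motif deviation scores with matched background peaks
#'
#' Bias-corrected deviation scoring of motif-bearing peak sets. For motif m
#' and cell c the raw deviation is `(observed - expected) / expected`, where
#' `observed` is the cell's detection count over the motif's peaks and
#' `expected` is the dataset-wide detection share of those peaks times the
#' cell's depth. Background peak sets match the motif's peaks on
#' accessibility (dataset-wide detection expectation) decile bins; z-scores
#' are raw deviations standardised by the background mean and SD, and a
#' motif's variability is the SD of its z-scores over cells.
#'
#' @param cm A `cell_matrix`.
#' @param motifs Sparse binary motif x peak matrix (colnames = peak ids).
#' @param n_background Background iterations. Default 50.
#' @param n_bins Accessibility bins for matching. Default 10.
#' @param seed Seed for background sampling. Default 0.
#' @return List of class `deviation_matrix`: `raw`, `z` (motif x cell),
#'   `variability` (named, SD of z per motif).
#' @export
motif_deviations <- function(cm, motifs, n_background = 50L, n_bins = 10L,
                             seed = 0L) {
  X <- cm$binary
  stopifnot(identical(colnames(motifs), rownames(X)))
  B <- as(motifs, "CsparseMatrix")
  tot_p <- rowSums(X)
  grand <- sum(tot_p)
  e <- tot_p / grand
  depth <- colSums(X)
  exp_share <- as.numeric(B %*% e)
  drop <- exp_share == 0
  if (any(drop)) {
    warning(sum(drop), " motif(s) with zero expected signal dropped")
    B <- B[!drop, , drop = FALSE]
    exp_share <- exp_share[!drop]
  }
  raw_dev <- function(Bm, share) {
    obs <- as.matrix(Bm %*% X)
    expd <- share %o% depth
    obs / expd - 1
  }
  raw <- raw_dev(B, exp_share)
  ## accessibility-matched backgrounds: within-bin permutations of peaks
  bins <- cut(rank(e, ties.method = "first"), breaks = n_bins, labels = FALSE)
  bin_members <- split(seq_along(e), bins)
  s1 <- matrix(0, nrow(raw), ncol(raw))
  s2 <- matrix(0, nrow(raw), ncol(raw))
  n_valid <- numeric(nrow(raw))
  local_seed(seed, {
    for (b in seq_len(n_background)) {
      perm <- integer(length(e))
      for (mb in bin_members) perm[mb] <- mb[sample.int(length(mb))]
      Bb <- B[, perm, drop = FALSE]
      share_b <- as.numeric(Bb %*% e)
      valid <- share_b > 0
      share_b[!valid] <- 1          # placeholder; rows zeroed below
      rb <- raw_dev(Bb, share_b)
      rb[!valid, ] <- 0
      n_valid <- n_valid + valid
      s1 <- s1 + rb
      s2 <- s2 + rb^2
    }
  })
  nv <- pmax(n_valid, 1)
  mu_bg <- s1 / nv
  sd_bg <- sqrt(pmax(s2 / nv - mu_bg^2, 0) * nv / pmax(nv - 1, 1))
  z <- (raw - mu_bg) / sd_bg
  z[!is.finite(z)] <- 0
  dimnames(raw) <- dimnames(z) <- list(rownames(B), colnames(X))
  variability <- apply(z, 1L, sd)
  structure(list(raw = raw, z = z, variability = variability),
            class = "deviation_matrix")
}

#' Most variable motifs
#'
#' @param dev A `deviation_matrix`.
#' @param top_n Number of motifs to return (all if larger than available).
#' @return data.table with motif and variability, sorted by decreasing
#'   variability (ties broken by motif name).
#' @export
variable_motifs <- function(dev, top_n) {
  v <- dev$variability
  ord <- order(-v, names(v))
  n <- min(top_n, length(v))
  data.table(motif = names(v)[ord][seq_len(n)],
             variability = unname(v[ord][seq_len(n)]))
}

## per-cluster gene enrichment: Wilcoxon rank-sum (normal approximation
## with tie correction) in-vs-out on activity rows, plus log2FC of means
cluster_enriched_genes <- function(activity, lab, log2fc_min = 0.25,
                                   padj_max = 0.05) {
  GA <- as.matrix(activity$scores)
  n <- ncol(GA)
  ranks <- t(apply(GA, 1L, rank))
  res <- list()
  for (cl in sort(unique(lab))) {
    idx <- lab == cl
    n1 <- sum(idx); n2 <- n - n1
    R1 <- rowSums(ranks[, idx, drop = FALSE])
    U <- R1 - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    ## tie correction per gene
    tie_term <- apply(GA, 1L, function(r) {
      tt <- table(r); sum(tt^3 - tt)
    })
    sig <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1))))
    zst <- (U - mu) / ifelse(sig > 0, sig, Inf)
    p <- 2 * pnorm(-abs(zst))
    mean_in <- rowMeans(GA[, idx, drop = FALSE])
    mean_out <- rowMeans(GA[, !idx, drop = FALSE])
    l2fc <- log2((mean_in + 1e-9) / (mean_out + 1e-9))
    p_adj <- p.adjust(p, "BH")
    res[[as.character(cl)]] <-
      rownames(GA)[l2fc > log2fc_min & p_adj < padj_max]
  }
  res
}

#' Cluster-specific TF to target-gene networks
#'
#' A TF is retained in a cluster when (a) its mean motif-deviation z-score
#' in the cluster is the maximum across clusters and exceeds the
#' `z_quantile` quantile of all (motif, cluster) means, and (b) at least
#' `min_targets` of its database targets are cluster-enriched genes
#' (Wilcoxon rank-sum on gene activity in-vs-out, log2FC > 0.25,
#' BH p_adj < 0.05). Edges connect each retained TF to its enriched
#' targets.
#'
#' @param dev A `deviation_matrix` whose motif names are TF names.
#' @param clusters Cluster labels (vector aligned with cells, or a
#'   `cluster_assignment`).
#' @param activity A `gene_activity` over the same cells.
#' @param db data.table with columns tf, target.
#' @param z_quantile Quantile gate on mean z. Default 0.9.
#' @param min_targets Minimum enriched targets. Default 3.
#' @return List of class `tftg_network`: `tfs` (per-cluster TF vectors),
#'   `edges` (cluster, tf, target), `mean_z` (motif x cluster matrix).
#' @export
build_tf_tg_network <- function(dev, clusters, activity, db,
                                z_quantile = 0.9, min_targets = 3L) {
  if (!nrow(db)) stop2("TF-target database is empty")
  lab <- if (is(clusters, "cluster_assignment"))
    as.character(clusters$cluster[colnames(dev$z)]) else as.character(clusters)
  stopifnot(length(lab) == ncol(dev$z))
  clevels <- sort(unique(lab))
  mean_z <- vapply(clevels, function(cl)
    rowMeans(dev$z[, lab == cl, drop = FALSE]), numeric(nrow(dev$z)))
  thr <- quantile(mean_z, z_quantile)
  enriched <- cluster_enriched_genes(activity, lab)
  edges <- list()
  tfs <- setNames(vector("list", length(clevels)), clevels)
  for (ci in seq_along(clevels)) {
    cl <- clevels[ci]
    best <- max.col(mean_z, ties.method = "first") == ci
    cand <- rownames(dev$z)[best & mean_z[, ci] > thr]
    for (tf in cand) {
      targets <- unique(db$target[db$tf == tf])
      hits <- intersect(targets, enriched[[cl]])
      if (length(hits) >= min_targets) {
        tfs[[cl]] <- c(tfs[[cl]], tf)
        edges[[length(edges) + 1L]] <- data.table(cluster = cl, tf = tf,
                                                  target = hits)
      }
    }
  }
  edge_tab <- if (length(edges)) rbindlist(edges) else
    data.table(cluster = character(0), tf = character(0),
               target = character(0))
  structure(list(tfs = tfs, edges = edge_tab, mean_z = mean_z),
            class = "tftg_network")
}

#' Shared and stage-unique TF-target pairs between two stage networks
#'
#' @param net_a,net_b `tftg_network` objects built on the two stage subsets
#'   of the same cluster(s).
#' @param label_a,label_b Stage labels used in the output. Defaults "P1",
#'   "P10".
#' @return List with `edges` (cluster, tf, target, label) partitioning the
#'   union of pairs into shared / `label_a`-unique / `label_b`-unique, and
#'   `summary` counts per label.
#' @export
compare_stage_networks <- function(net_a, net_b, label_a = "P1",
                                   label_b = "P10") {
  key <- function(e) paste(e$cluster, e$tf, e$target, sep = "\r")
  ea <- net_a$edges; eb <- net_b$edges
  ka <- key(ea); kb <- key(eb)
  all_e <- unique(rbind(ea, eb))
  kk <- key(all_e)
  lab <- ifelse(kk %in% ka & kk %in% kb, "shared",
                ifelse(kk %in% ka, paste0(label_a, "-unique"),
                       paste0(label_b, "-unique")))
  all_e[, label := lab]
  list(edges = all_e[], summary = table(factor(
    lab, levels = c("shared", paste0(label_a, "-unique"),
                    paste0(label_b, "-unique")))))
}
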