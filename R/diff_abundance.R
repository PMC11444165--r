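#' Sample and refine kNN neighbourhoods on an embedding
#'
#' Samples index cells uniformly (seeded), defines each neighbourhood as the
#' index cell plus its `k` nearest neighbours, and greedily refines the
#' index set so that no retained index cell lies inside an earlier retained
#' neighbourhood.
#'
#' @param embedding An `embedding` (aligned if batches are present).
#' @param k Neighbours per index cell. Default 20.
#' @param sampling_fraction Fraction of cells considered as index cells.
#'   Default 0.1.
#' @param seed Sampling seed. Default 0.
#' @return List of class `neighborhood_set`: `index` (barcodes), `members`
#'   (list of barcode vectors, each of size k+1), `kth_dist` (distance to
#'   the kth neighbour).
#' @export
make_neighborhoods <- function(embedding, k = 20L, sampling_fraction = 0.1,
                               seed = 0L) {
  E <- embedding$coords
  n <- nrow(E)
  if (n < k + 1L) stop2("fewer cells than k + 1")
  D <- as.matrix(dist(E))
  n_idx <- max(1L, ceiling(sampling_fraction * n))
  cand <- local_seed(seed, sample.int(n, n_idx))
  taken <- rep(FALSE, n)    # cells covered by an accepted neighbourhood
  index <- integer(0)
  members <- list()
  kth <- numeric(0)
  for (s in cand) {
    if (taken[s]) next
    nb <- order(D[s, ])[seq_len(k + 1L)]   # includes s itself
    index <- c(index, s)
    members[[length(members) + 1L]] <- nb
    kth <- c(kth, D[s, nb[k + 1L]])
    taken[nb] <- TRUE
  }
  bcs <- rownames(E)
  structure(list(index = bcs[index],
                 members = lapply(members, function(i) bcs[i]),
                 kth_dist = kth),
            class = "neighborhood_set")
}

## weighted Benjamini-Hochberg ("spatial FDR"): weights proportional to the
## reciprocal kth-NN distance, i.e. dense neighbourhoods count more
weighted_bh <- function(p, w) {
  ok <- !is.na(p)
  adj <- rep(NA_real_, length(p))
  p0 <- p[ok]; w0 <- w[ok]
  o <- order(p0)
  a <- sum(w0) * p0[o] / cumsum(w0[o])
  a <- rev(cummin(rev(a)))
  adj[ok][o] <- pmin(a, 1)
  adj
}

#' Neighbourhood differential abundance between two conditions
#'
#' Counts each neighbourhood's cells per (condition, replicate) sample and
#' tests condition dependence with a quasi-Poisson count model using
#' log sample totals as offsets; with fewer than two replicates in either
#' condition it falls back to an exact binomial test of the neighbourhood's
#' condition split against the global proportion. Multiplicity is controlled
#' by weighted Benjamini-Hochberg with weights proportional to the
#' reciprocal kth-neighbour distance (spatial FDR).
#'
#' @param nbhd A `neighborhood_set`.
#' @param condition Named (by barcode) two-level condition labels.
#' @param replicate Named replicate labels.
#' @param clusters Optional named cluster labels for the majority-cluster
#'   column.
#' @param prior_df Prior degrees of freedom added to each neighbourhood's
#'   residual df for the moderated-t reference. Default 3.
#' @return data.table with neighborhood, n_cells, logFC (log2, positive =
#'   enriched for the second condition level), p, spatial_fdr,
#'   majority_cluster.
#' @export
test_neighborhoods <- function(nbhd, condition, replicate, clusters = NULL,
                               prior_df = 3) {
  cond <- factor(condition)
  names(cond) <- names(condition)
  if (nlevels(cond) != 2L) stop2("condition must have exactly two levels")
  lev <- levels(cond)
  repl <- as.character(replicate)
  samp <- setNames(paste(as.character(cond), repl, sep = "|"), names(cond))
  totals <- table(samp)
  samp_cond <- factor(vapply(strsplit(names(totals), "|", fixed = TRUE),
                             `[`, character(1), 1L), levels = lev)
  use_glm <- all(table(samp_cond) >= 2L)
  global_p2 <- mean(cond == lev[2L])
  ## neighbourhood x sample count matrix; sample size factors are estimated
  ## median-of-ratios across neighbourhoods rather than from raw totals, so
  ## a genuinely shifted subpopulation does not bias the majority of
  ## neighbourhoods away from zero (composition effect)
  Y <- do.call(rbind, lapply(nbhd$members, function(mem)
    as.integer(table(factor(samp[mem], levels = names(totals))))))
  size_fac <- as.numeric(totals)
  if (use_glm && nrow(Y) >= 5L) {
    ref <- exp(rowMeans(log(Y + 0.5)))
    f <- apply((Y + 0.5) / ref, 2L, median)
    if (all(is.finite(f)) && all(f > 0)) size_fac <- f / mean(f) * mean(totals)
  }
  rows <- list()
  fits <- list()
  for (i in seq_along(nbhd$members)) {
    mem <- nbhd$members[[i]]
    cs <- cond[mem]; ss <- samp[mem]
    n_cells <- length(mem)
    if (n_cells == 0L) next
    if (use_glm) {
      y <- Y[i, ]
      df <- data.frame(y = y, cond = samp_cond, off = log(size_fac))
      fit <- suppressWarnings(glm(y ~ cond + offset(off), data = df,
                                  family = stats::poisson()))
      sm <- summary(fit)$coefficients
      logFC <- coef(fit)[[2L]] / log(2)
      se <- if (nrow(sm) >= 2L) sm[2L, 2L] else NA_real_
      ## Pearson residual dispersion, pooled across neighbourhoods below
      pearson <- sum(stats::residuals(fit, type = "pearson")^2)
      fits[[length(fits) + 1L]] <- c(beta = coef(fit)[[2L]], se = se,
                                     x2 = pearson, df = fit$df.residual)
      p <- NA_real_
    } else {
      x2 <- sum(cs == lev[2L])
      bt <- binom.test(x2, n_cells, p = global_p2)
      p <- bt$p.value
      f2 <- (x2 + 0.5) / (n_cells + 1)
      logFC <- log2((f2 / (1 - f2)) / (global_p2 / (1 - global_p2)))
    }
    rows[[length(rows) + 1L]] <- data.table(
      neighborhood = i, index = nbhd$index[i], n_cells = n_cells,
      logFC = logFC, p = p)
  }
  res <- rbindlist(rows)
  if (use_glm && length(fits)) {
    ## quasi-likelihood with dispersion pooled over neighbourhoods (single
    ## neighbourhoods have too few samples to estimate their own), but a
    ## moderated-t reference: the pooled estimate does not license the full
    ## summed df because dispersions are heterogeneous between
    ## neighbourhoods, so each test uses its residual df plus a prior df
    fm <- do.call(rbind, fits)
    df_tot <- sum(fm[, "df"])
    phi <- max(1, sum(fm[, "x2"]) / max(df_tot, 1))
    tstat <- fm[, "beta"] / (fm[, "se"] * sqrt(phi))
    df_mod <- prior_df + fm[, "df"]
    res[, p := 2 * stats::pt(-abs(tstat), df = pmax(df_mod, 1))]
  }
  res[, spatial_fdr := weighted_bh(p, 1 / pmax(nbhd$kth_dist[neighborhood],
                                               1e-12))]
  if (!is.null(clusters)) {
    res[, majority_cluster := vapply(neighborhood, function(i) {
      names(which.max(table(clusters[nbhd$members[[i]]])))
    }, character(1))]
  } else res[, majority_cluster := NA_character_]
  res[]
}

#' Stage-differential peaks within each cluster
#'
#' Within each cluster containing both stages, tests per-peak detection
#' differences between the stages with a two-sided Fisher exact test,
#' computes the log2 detection-fraction ratio (pseudocount 1/n cells in the
#' cluster), applies BH correction within cluster, and counts peaks
#' enriched towards each stage at `|log2fc| > log2fc_min` and
#' `p_adj < padj_max`.
#'
#' @param cm A `cell_matrix`.
#' @param clusters Cluster labels (vector or `cluster_assignment`).
#' @param stage Named two-level stage labels (e.g. P1/P10).
#' @param log2fc_min,padj_max Retention thresholds. Defaults 0.25, 0.05.
#' @return List with `counts` (cluster x stage table of differential peak
#'   numbers) and `peaks` (per-peak statistics of retained rows).
#' @export
stage_differential_peaks <- function(cm, clusters, stage,
                                     log2fc_min = 0.25, padj_max = 0.05) {
  X <- cm$binary
  lab <- cluster_labels(clusters, colnames(X))
  st <- factor(stage[colnames(X)])
  if (nlevels(st) != 2L) stop2("stage must have exactly two levels")
  lev <- levels(st)
  rows <- list()
  for (cl in sort(unique(lab))) {
    idx <- which(lab == cl)
    s1 <- idx[st[idx] == lev[1L]]
    s2 <- idx[st[idx] == lev[2L]]
    if (length(s1) < 3L || length(s2) < 3L) next
    k1 <- rowSums(X[, s1, drop = FALSE])
    k2 <- rowSums(X[, s2, drop = FALSE])
    pseudo <- 1 / length(idx)
    l2fc <- log2_frac_ratio(k1, length(s1), k2, length(s2), pseudo)
    p <- fisher_p_two_sided(as.integer(k1), length(s1),
                            as.integer(k2), length(s2))
    p_adj <- p.adjust(p, "BH")
    keep <- which(abs(l2fc) > log2fc_min & p_adj < padj_max)
    if (length(keep))
      rows[[length(rows) + 1L]] <- data.table(
        cluster = cl, peak_id = rownames(X)[keep],
        enriched_in = ifelse(l2fc[keep] > 0, lev[1L], lev[2L]),
        log2fc = l2fc[keep], p = p[keep], p_adj = p_adj[keep])
  }
  pk <- if (length(rows)) rbindlist(rows) else
    data.table(cluster = character(0), peak_id = character(0),
               enriched_in = character(0), log2fc = numeric(0),
               p = numeric(0), p_adj = numeric(0))
  counts <- table(factor(pk$cluster, levels = sort(unique(lab))),
                  factor(pk$enriched_in, levels = lev))
  list(counts = counts, peaks = pk)
}
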