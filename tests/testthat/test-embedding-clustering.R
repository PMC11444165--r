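test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(21)
  for (i in 1:10) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(letters[1:3], 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 6)), 1)
})

test_that("tfidf_lsi embeds identical cells identically and weights idf sensibly", {
  set.seed(1)
  X <- Matrix::rsparsematrix(80, 40, density = 0.3, rand.x = function(n) rep(1, n))
  X[, 2] <- X[, 1]                      # duplicate cell
  X[5, ] <- 1                           # peak detected in every cell
  X <- as(X, "CsparseMatrix")
  dimnames(X) <- list(sprintf("p%02d", 1:80), sprintf("c%02d", 1:40))
  emb <- tfidf_lsi(X, d = 5)
  expect_equal(emb$coords["c01", ], emb$coords["c02", ], tolerance = 1e-9)
  ## idf monotonicity: the everywhere-detected peak has the minimal idf
  det <- Matrix::rowSums(X > 0)
  idf <- log(1 + ncol(X) / det)
  expect_equal(as.integer(which.min(idf)), 5L)
  expect_error(tfidf_lsi(X, d = 40), "smaller")
})

test_that("planted clusters are well separated in the LSI embedding", {
  cfg <- synth_config(n_chromosomes = 2L, chrom_length_bp = 10e6,
                      n_peaks = 2000L, n_genes = 30L, n_clusters = 3L,
                      cells_per_cluster = 60L, depth_mean = 2000,
                      frac_low_quality_cells = 0,
                      marker_peaks_per_cluster = 200L, marker_effect = 8,
                      stage_diff_peaks_per_cluster = 0L,
                      n_coaccess_modules = 1L, module_span_bp = 1e5,
                      seed = 17)
  b <- generate_dataset(cfg)
  qc <- compute_cell_qc(b$fragments, b$peaks_true)
  cm <- build_binary_matrix(b$fragments, b$peaks_true, qc, b$cell_metadata)
  emb <- tfidf_lsi(cm, d = 6)
  lab <- truth_labels(b, cm)
  ## average silhouette on the embedding
  D <- as.matrix(dist(emb$coords))
  sil <- vapply(seq_len(nrow(D)), function(i) {
    a <- mean(D[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    bmin <- min(vapply(setdiff(unique(lab), lab[i]), function(cl)
      mean(D[i, lab == cl]), numeric(1)))
    (bmin - a) / max(a, bmin)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("align_batches removes a constant offset exactly and is inert on null batches", {
  set.seed(2)
  n <- 300
  cl <- rep(1:3, each = 100)
  centers <- matrix(rnorm(15, sd = 6), 3, 5)
  E <- centers[cl, ] + matrix(rnorm(n * 5), n, 5)
  rownames(E) <- paste0("c", seq_len(n))
  batch <- rep(c("a", "b"), length.out = n)
  off <- c(4, -3, 2, 0, 1)
  E_off <- E
  E_off[batch == "b", ] <- sweep(E_off[batch == "b", ], 2, off, "+")
  al <- align_batches(as_embedding(E_off), batch)
  cd <- sqrt(sum((colMeans(al$coords[batch == "a", ]) -
                    colMeans(al$coords[batch == "b", ]))^2))
  expect_lt(cd, 1e-6)
  ## random batch labels on batch-free data: embedding essentially unchanged
  al0 <- align_batches(as_embedding(E), sample(batch))
  disp <- sqrt(rowSums((al0$coords - E)^2))
  expect_lt(median(disp), 1e-3)
  ## cluster structure preserved
  km_before <- kmeans(E, 3, nstart = 10)$cluster
  km_after <- kmeans(al0$coords, 3, nstart = 10)$cluster
  expect_gte(adjusted_rand_index(km_before, km_after), 0.95)
  ## single batch -> identity
  expect_identical(align_batches(as_embedding(E), rep("a", n))$coords, E)
})

test_that("cluster tree handles one obvious cluster and recovers planted structure", {
  set.seed(3)
  E1 <- matrix(rnorm(150 * 4), 150, 4)
  rownames(E1) <- paste0("c", 1:150)
  tr1 <- cluster_resolution_tree(as_embedding(E1),
                                 resolutions = c(0.2, 0.5, 0.8), k_nn = 15)
  ## a single Gaussian blob should not fragment at low resolutions
  expect_equal(tr1$n_clusters[1], 1L)
  ## counts are weakly monotone in resolution
  b <- small_bundle()
  cm <- small_matrix()
  emb <- tfidf_lsi(cm, d = 15)
  tree <- cluster_resolution_tree(emb, seed = 0)
  expect_true(all(diff(tree$n_clusters) >= 0))
  ## some resolution recovers the planted 6 clusters
  lab <- truth_labels(b, cm)
  aris <- vapply(tree$memberships, function(m)
    adjusted_rand_index(m, lab), numeric(1))
  hit <- which(tree$n_clusters == 6L & aris >= 0.9)
  expect_gt(length(hit), 0L)
  ## the selected resolution also recovers them
  sel <- suppressWarnings(select_resolution(tree))
  expect_equal(length(unique(sel$cluster)), 6L)
  expect_gte(adjusted_rand_index(sel$cluster, lab[names(sel$cluster)]), 0.9)
  ## overlap weights row-normalise to 1
  expect_true(all(abs(rowSums(tree$overlap[[1]]) - 1) < 1e-12))
})

test_that("select_resolution applies the stability rule and its fallback", {
  fake_tree <- function(stab, counts) {
    structure(list(memberships = lapply(counts, function(k)
      rep(seq_len(k) - 1L, length.out = 60)),
      n_clusters = counts, stability = stab,
      modularity = rep(0.5, length(stab)),
      overlap = vector("list", length(stab)),
      resolutions = seq_along(stab) / 10,
      barcodes = paste0("c", 1:60)), class = "cluster_tree")
  }
  t1 <- fake_tree(c(0.95, 0.95, 0.7), c(3L, 3L, 5L))
  expect_equal(select_resolution(t1)$resolution, 0.1)
  ## no resolution stable -> fallback with warning
  t2 <- fake_tree(c(0.7, 0.8, 0.6), c(2L, 3L, 4L))
  t2$modularity <- c(0.2, 0.6, 0.3)
  expect_warning(s2 <- select_resolution(t2), "stability")
  expect_equal(s2$resolution, 0.2)
})

test_that("Fisher p-values match fisher.test to 1e-12 and markers are recovered", {
  set.seed(4)
  for (i in 1:50) {
    n_in <- sample(5:200, 1); n_out <- sample(5:1800, 1)
    k_in <- rbinom(1, n_in, runif(1)); k_out <- rbinom(1, n_out, runif(1))
    p_vec <- enhancermap:::fisher_p_two_sided(k_in, n_in, k_out, n_out)
    p_ref <- fisher.test(matrix(c(k_in, n_in - k_in, k_out, n_out - k_out),
                                2))$p.value
    expect_lt(abs(p_vec - p_ref), 1e-12)
  }
  ## frac_in 0.8 vs 0.1 at n 200/1000 is retained with log2fc about 3
  p <- enhancermap:::fisher_p_two_sided(160L, 200L, 100L, 1000L)
  expect_lt(p, 1e-12)
  b <- small_bundle()
  cm <- small_matrix()
  lab <- truth_labels(b, cm)
  mk <- find_cluster_peaks(cm, lab)
  rec <- prec <- numeric(0)
  for (cl in names(b$truth$marker_peaks)) {
    found <- mk$peak_id[mk$cluster == cl]
    tr <- b$truth$marker_peaks[[cl]]
    rec <- c(rec, mean(tr %in% found))
    prec <- c(prec, mean(found %in% tr))
  }
  expect_gte(mean(rec), 0.9)
  expect_gte(mean(prec), 0.9)
  ## retained rows satisfy the thresholds
  expect_true(all(mk$log2fc > 0.25 & mk$p_adj < 0.05))
  expect_true(all(mk$p_adj >= mk$p))
})

test_that("marker calling is invariant to cell order and label permutation", {
  b <- small_bundle()
  cm <- small_matrix()
  lab <- truth_labels(b, cm)
  mk1 <- find_cluster_peaks(cm, lab)
  ## permute cells
  perm <- sample(ncol(cm$binary))
  cm2 <- cm
  cm2$binary <- cm$binary[, perm]
  cm2$counts <- cm$counts[, perm]
  cm2$metadata <- cm$metadata[perm]
  mk2 <- find_cluster_peaks(cm2, lab[colnames(cm2$binary)])
  data.table::setorder(mk1, cluster, peak_id)
  data.table::setorder(mk2, cluster, peak_id)
  expect_equal(mk1, mk2)
  ## relabel clusters: results identical up to the label map
  relab <- setNames(paste0("X", 1:6), paste0("C", 1:6))
  mk3 <- find_cluster_peaks(cm, setNames(relab[lab], names(lab)))
  expect_equal(nrow(mk3), nrow(mk1))
  expect_setequal(paste(relab[mk1$cluster], mk1$peak_id),
                  paste(mk3$cluster, mk3$peak_id))
  ## identical detection fractions give log2fc 0 and are not retained
  expect_equal(enhancermap:::log2_frac_ratio(10, 50, 40, 200, 0.01), 0)
})

test_that("peak feature annotation follows the precedence rules", {
  genes <- gene_model(c("g1", "g2"), c("chr1", "chr1"),
                      c(50000L, 200000L), c(60000L, 240000L), c("+", "-"))
  peaks <- peak_set("chr1", c(49500, 55000, 500000), c(50500, 55400, 500400))
  markers <- data.table::data.table(
    cluster = "C1", peak_id = names(peaks), log2fc = 2, p = 1e-6,
    p_adj = 1e-5, frac_in = 0.8, frac_out = 0.1)
  ann <- annotate_peak_features(peaks, markers, genes, fc_min = 2)
  got <- setNames(ann$peaks$feature, ann$peaks$peak_id)
  expect_identical(unname(got["chr1:49500-50500"]), "promoter")   # covers TSS
  expect_identical(unname(got["chr1:55000-55400"]), "exon")       # gene body
  expect_identical(unname(got["chr1:500000-500400"]), "distal_intergenic")
  expect_true(all(abs(rowSums(ann$fractions) - 1) < 1e-12))
  ## peaks below the fold-change gate are not annotated
  markers$frac_out <- 0.5
  ann2 <- annotate_peak_features(peaks, markers, genes, fc_min = 2)
  expect_equal(nrow(ann2$peaks), 0L)
})
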